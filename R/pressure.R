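#' Pressure-mat grid
#'
#' A calibrated pressure-sensor matrix in kPa with its sensor pitch and
#' orientation. Row index increases rear-to-front (fore-aft axis); the native
#' mats are 48 x 48 at 12.7 mm pitch, but any size is accepted.
#'
#' @param values Numeric matrix of pressures (kPa), all finite and `>= 0`.
#' @param pitch_mm Sensor spacing in mm (default 12.7).
#' @param surface Surface tag, `"SP"` (seat pan) or `"SB"` (seat back).
#' @return A `pressure_grid` object.
#' @export
pressure_grid <- function(values, pitch_mm = 12.7, surface = "SP") {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)) || any(values < 0))
    stop("pressure values must be finite and >= 0 (kPa)")
  if (!is.numeric(pitch_mm) || pitch_mm <= 0)
    stop("`pitch_mm` must be positive")
  surface <- match.arg(surface, c("SP", "SB"))
  structure(list(values = values, pitch_mm = pitch_mm,
                 row_axis = "fore-aft", surface = surface),
            class = "pressure_grid")
}

#' @export
print.pressure_grid <- function(x, ...) {
  cat(sprintf("<pressure_grid %s>  %d x %d sensors @ %.1f mm, total %.1f N\n",
              x$surface, nrow(x$values), ncol(x$values), x$pitch_mm,
              grid_integral_N(x)))
  invisible(x)
}

# integral of the map: sum p_ij [kPa] * pitch^2 [mm^2] * 1e-3 -> N
grid_integral_N <- function(grid) {
  sum(grid$values) * grid$pitch_mm^2 * 1e-3
}

#' Trial-specific pressure correction factor
#'
#' The multiplicative factor that makes the pressure-map integral equal the
#' normal force measured by the load cells on the same surface:
#' `fcorr = F / (sum(p_ij) * pitch^2 * 1e-3)` with pressures in kPa, areas in
#' mm^2 and force in N. Multiplying the grid by `fcorr` makes its integral
#' equal `normal_force_N` exactly.
#'
#' @param grid A [pressure_grid()].
#' @param normal_force_N Load-cell normal force magnitude on the surface (N).
#' @return The scalar correction factor.
#' @export
correction_factor <- function(grid, normal_force_N) {
  stopifnot(inherits(grid, "pressure_grid"))
  if (!is.finite(normal_force_N) || normal_force_N <= 0)
    stop("`normal_force_N` must be > 0")
  integ <- grid_integral_N(grid)
  if (integ <= 0) stop("zero-pressure grid: correction factor undefined")
  abs(normal_force_N) / integ
}

#' Apply a correction factor to a grid
#' @param grid A [pressure_grid()].
#' @param fcorr Multiplicative factor, `> 0`.
#' @return The rescaled `pressure_grid`.
#' @export
apply_correction <- function(grid, fcorr) {
  stopifnot(inherits(grid, "pressure_grid"), is.finite(fcorr), fcorr > 0)
  grid$values <- grid$values * fcorr
  grid
}

#' Contact area, peak and mean pressure of a corrected map
#'
#' Corrects the grid to match the load-cell normal force, then computes
#' contact area `CA` (number of cells above the contact threshold times the
#' cell area), peak pressure `PP` (maximum corrected cell) and mean pressure
#' `MP` (corrected load carried by active cells divided by `CA`; when all
#' load lies on active cells this equals normal force / CA).
#'
#' @param grid A [pressure_grid()].
#' @param threshold_kpa Contact threshold in kPa (default 0.1, below the
#'   mat's rated floor but above numerical noise), applied to corrected
#'   pressures.
#' @param normal_force_N Load-cell normal force (N); `NULL` skips correction
#'   (`fcorr = 1`).
#' @return A list `ca_mm2`, `pp_kpa`, `mp_kpa`, `fcorr` (class
#'   `pressure_summary`). `mp_kpa` is `NA` (flagged) when no cell is active.
#' @export
summarize_pressure <- function(grid, threshold_kpa = 0.1, normal_force_N = NULL) {
  stopifnot(inherits(grid, "pressure_grid"))
  if (threshold_kpa < 0) stop("`threshold_kpa` must be >= 0")
  fcorr <- if (is.null(normal_force_N)) 1 else correction_factor(grid, normal_force_N)
  p <- grid$values * fcorr
  active <- p > threshold_kpa
  cell_mm2 <- grid$pitch_mm^2
  ca <- sum(active) * cell_mm2
  pp <- if (length(p)) max(p) else 0
  mp <- if (ca > 0) sum(p[active]) * cell_mm2 * 1e-3 / ca * 1e3 else NA_real_
  structure(list(ca_mm2 = ca, pp_kpa = pp, mp_kpa = mp, fcorr = fcorr),
            class = "pressure_summary")
}

#' @export
print.pressure_summary <- function(x, ...) {
  cat(sprintf("<pressure_summary>  CA %.0f mm^2, PP %.2f kPa, MP %s kPa, fcorr %.3f\n",
              x$ca_mm2, x$pp_kpa,
              if (is.na(x$mp_kpa)) "NA" else sprintf("%.2f", x$mp_kpa), x$fcorr))
  invisible(x)
}

#' Mean pressure from a normal force and contact area
#'
#' The defining identity `MP = F / CA` (force in N, area in mm^2, result in
#' kPa): when the corrected map's load lies entirely on active cells,
#' [summarize_pressure()]'s `mp_kpa` equals this ratio.
#'
#' @param force_N Normal force magnitude (N).
#' @param ca_mm2 Contact area (mm^2, `> 0`).
#' @return Mean pressure in kPa.
#' @export
mean_pressure_kpa <- function(force_N, ca_mm2) {
  stopifnot(all(ca_mm2 > 0))
  abs(force_N) / ca_mm2 * 1e3
}

#' Lateral and frontal pressure profiles
#'
#' `soc[r]` sums row `r` across columns (lateral profile, drawn in the
#' sagittal plane along the fore-aft axis); `sor[c]` sums column `c` across
#' rows (frontal profile). Both conserve the grid total.
#'
#' @param grid A [pressure_grid()].
#' @return A list with numeric vectors `soc` and `sor` (kPa-cells).
#' @export
pressure_profiles <- function(grid) {
  stopifnot(inherits(grid, "pressure_grid"))
  list(soc = rowSums(grid$values), sor = colSums(grid$values))
}

#' Four-region fore-aft partition of the seat-pan lateral profile
#'
#' Splits the active fore-aft span of the lateral profile `soc` into four
#' regions: `x_beg` is the first active row (rear, under the buttocks),
#' `x_end` the last active row (front, thigh end), `x_max` the row of the
#' profile peak (rear-most on ties), `x_mid1` the midpoint of `(x_max,
#' x_end)` and `x_mid2` the midpoint of `(x_mid1, x_end)` (midpoints rounded
#' to the nearest row, half-way ties toward `x_end`). Regions are the
#' half-open row ranges I = [x_beg, x_max), II = [x_max, x_mid1),
#' III = [x_mid1, x_mid2), IV = [x_mid2, x_end]; each carries the percentage
#' of the total span load. Zero-width regions contribute 0% and are flagged.
#'
#' @param soc Numeric lateral profile (per-row sums).
#' @param threshold Activity threshold on `soc` (default 0).
#' @return A list with integer row indices `x_beg, x_max, x_mid1, x_mid2,
#'   x_end`, percentages `p_i ... p_iv` (summing to 100), and
#'   `degenerate`, a logical vector flagging zero-width regions.
#' @export
partition_regions <- function(soc, threshold = 0) {
  stopifnot(is.numeric(soc))
  active <- which(soc > threshold)
  if (!length(active)) stop("no row of the profile exceeds the threshold")
  x_beg <- min(active); x_end <- max(active)
  span <- x_beg:x_end
  x_max <- span[which.max(soc[span])]  # first (rear-most) maximal row

  # midpoint rounded to nearest integer row, exact halves toward x_end
  mid_toward_end <- function(a, b) {
    m <- (a + b) / 2
    lo <- floor(m)
    if (m - lo == 0.5) if (b >= a) lo + 1L else lo else as.integer(round(m))
  }
  x_mid1 <- mid_toward_end(x_max, x_end)
  x_mid2 <- mid_toward_end(x_mid1, x_end)

  bounds <- list(i   = c(x_beg,  x_max  - 1L),
                 ii  = c(x_max,  x_mid1 - 1L),
                 iii = c(x_mid1, x_mid2 - 1L),
                 iv  = c(x_mid2, x_end))
  total <- sum(soc[span])
  sums <- vapply(bounds, function(b)
    if (b[2] < b[1]) 0 else sum(soc[b[1]:b[2]]), numeric(1))
  degenerate <- vapply(bounds, function(b) b[2] < b[1], logical(1))
  p <- 100 * sums / total
  list(x_beg = x_beg, x_max = x_max, x_mid1 = x_mid1, x_mid2 = x_mid2,
       x_end = x_end,
       p_i = p[["i"]], p_ii = p[["ii"]], p_iii = p[["iii"]], p_iv = p[["iv"]],
       degenerate = degenerate)
}

#' Read a pressure grid from a headerless CSV matrix
#'
#' @param path CSV path; values in kPa, row 1 = rear edge. An optional YAML
#'   sidecar `<path>.yml` may carry `pitch_mm` and `surface`.
#' @param pitch_mm,surface Defaults when no sidecar is present.
#' @return A [pressure_grid()].
#' @export
read_pressure_grid <- function(path, pitch_mm = 12.7, surface = "SP") {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  sidecar <- paste0(path, ".yml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (!is.null(meta$pitch_mm)) pitch_mm <- meta$pitch_mm
    if (!is.null(meta$surface)) surface <- meta$surface
  }
  pressure_grid(m, pitch_mm = pitch_mm, surface = surface)
}

#' Write a pressure grid as a headerless CSV matrix (+ YAML sidecar)
#' @param grid A [pressure_grid()].
#' @param path Output CSV path; metadata goes to `<path>.yml`.
#' @export
write_pressure_grid <- function(grid, path) {
  stopifnot(inherits(grid, "pressure_grid"))
  utils::write.table(grid$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  yaml::write_yaml(list(pitch_mm = grid$pitch_mm, surface = grid$surface,
                        units = "kPa", row_axis = grid$row_axis),
                   paste0(path, ".yml"))
  invisible(path)
}
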