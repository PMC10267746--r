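#' Planar contact force
#'
#' A sagittal-plane contact force on one rig surface, expressed either in the
#' global frame (x forward-horizontal, z upward, right-handed with y lateral)
#' or in the surface-local frame (global frame rotated about y by the surface
#' tilt, so shear and normal components separate).
#'
#' @param fx,fz Force components in newtons (finite).
#' @param surface Surface tag: `"SB"`, `"SP"` or `"FS"`.
#' @param frame `"global"` or `"local"`.
#' @return A `planar_force` object.
#' @examples
#' f <- planar_force(88.4, -689.2, "SP")
#' rotate_global_to_local(f, 5)
#' @export
planar_force <- function(fx, fz, surface, frame = "global") {
  stopifnot(is.numeric(fx), length(fx) == 1, is.finite(fx),
            is.numeric(fz), length(fz) == 1, is.finite(fz))
  if (!surface %in% surface_tags)
    stop("unknown surface tag ", deparse(surface))
  frame <- match.arg(frame, c("global", "local"))
  structure(list(fx = fx, fz = fz, surface = surface, frame = frame),
            class = "planar_force")
}

#' @export
print.planar_force <- function(x, ...) {
  cat(sprintf("<planar_force %s/%s>  fx = %.2f N, fz = %.2f N\n",
              x$surface, x$frame, x$fx, x$fz))
  invisible(x)
}

#' Rotate a global-frame force into a surface-local frame
#'
#' Rotation about the lateral y-axis by `angle_deg` (the surface tilt):
#' `fx_L = fx_G cos(a) + fz_G sin(a)`, `fz_L = -fx_G sin(a) + fz_G cos(a)`.
#' The Euclidean norm is preserved.
#'
#' @param f A [planar_force()] in the global frame.
#' @param angle_deg Rotation angle in degrees (typically
#'   [surface_tilt_angle()]).
#' @return A `planar_force` in the local frame.
#' @export
rotate_global_to_local <- function(f, angle_deg) {
  stopifnot(inherits(f, "planar_force"))
  if (f$frame != "global")
    stop("input force is already in the local frame")
  a <- angle_deg * pi / 180
  planar_force(fx =  f$fx * cos(a) + f$fz * sin(a),
               fz = -f$fx * sin(a) + f$fz * cos(a),
               surface = f$surface, frame = "local")
}

#' Rotate a surface-local force back to the global frame
#'
#' Inverse of [rotate_global_to_local()].
#' @inheritParams rotate_global_to_local
#' @export
rotate_local_to_global <- function(f, angle_deg) {
  stopifnot(inherits(f, "planar_force"))
  if (f$frame != "local")
    stop("input force is already in the global frame")
  a <- angle_deg * pi / 180
  planar_force(fx = f$fx * cos(a) - f$fz * sin(a),
               fz = f$fx * sin(a) + f$fz * cos(a),
               surface = f$surface, frame = "global")
}

#' Static force balance of a seated configuration
#'
#' Sums the global-frame contact forces over the three surfaces and adds the
#' body weight. Reaction forces supporting the sitter point along negative z
#' in the measurement convention, so the weight enters with positive sign:
#' `sum_fz = sum(fz) + W`. Both sums vanish for a statically admissible set.
#'
#' @param forces List of three [planar_force()] objects in the global frame,
#'   one per surface (SB, SP, FS).
#' @param config A [seat_config()]; supplies the body weight.
#' @return A list with signed residuals `sum_fx`, `sum_fz` and their
#'   magnitudes `abs_fx`, `abs_fz` (all N).
#' @export
force_balance <- function(forces, config) {
  stopifnot(inherits(config, "seat_config"), is.list(forces))
  surfs <- vapply(forces, function(f) {
    stopifnot(inherits(f, "planar_force"))
    if (f$frame != "global") stop("force_balance requires global-frame forces")
    f$surface
  }, character(1))
  missing <- setdiff(surface_tags, surfs)
  if (length(missing) || length(forces) != 3L)
    stop("need exactly one global force per surface; missing/duplicated: ",
         paste(c(missing, surfs[duplicated(surfs)]), collapse = ", "))
  sum_fx <- sum(vapply(forces, `[[`, numeric(1), "fx"))
  sum_fz <- sum(vapply(forces, `[[`, numeric(1), "fz")) + config$body_weight_N
  list(sum_fx = sum_fx, sum_fz = sum_fz,
       abs_fx = abs(sum_fx), abs_fz = abs(sum_fz))
}

#' Sim-vs-Exp comparison statistics for condition-wise tables
#'
#' Given simulated and experimental tables with matching condition labels and
#' numeric quantity columns, computes per-condition differences
#' `D = Sim - Exp`, the relative difference `D% = 100 (Sim - Exp) / |Exp|`
#' (flagged `NA` where `|Exp|` is numerically zero), and per-quantity means
#' over conditions (the "All" row, with `D%` evaluated at the means).
#'
#' @param sim,exp Data frames with a `condition` column and identical numeric
#'   quantity columns, one row per condition.
#' @return A list of tibbles: `d` (per-condition differences), `d_pct`
#'   (per-condition relative differences, %), and `all` (per-quantity Exp/Sim
#'   means, mean D and D% of the means).
#' @export
compare_conditions <- function(sim, exp) {
  sim <- tibble::as_tibble(sim); exp <- tibble::as_tibble(exp)
  if (!("condition" %in% names(sim)) || !("condition" %in% names(exp)))
    stop("both tables need a `condition` column")
  if (!identical(sim$condition, exp$condition))
    stop("condition labels differ: sim = [",
         paste(sim$condition, collapse = ", "), "] vs exp = [",
         paste(exp$condition, collapse = ", "), "]")
  qcols <- setdiff(names(sim), "condition")
  if (!identical(sort(qcols), sort(setdiff(names(exp), "condition"))))
    stop("quantity columns differ between sim and exp tables")
  exp <- exp[, names(sim)]

  d <- sim
  d[qcols] <- sim[qcols] - exp[qcols]
  d_pct <- sim
  for (q in qcols) {
    den <- abs(exp[[q]])
    d_pct[[q]] <- ifelse(den < 1e-9, NA_real_, 100 * (sim[[q]] - exp[[q]]) / den)
  }
  all_row <- tibble::tibble(
    quantity = qcols,
    exp_mean = vapply(qcols, function(q) mean(exp[[q]]), numeric(1), USE.NAMES = FALSE),
    sim_mean = vapply(qcols, function(q) mean(sim[[q]]), numeric(1), USE.NAMES = FALSE),
    mean_d   = vapply(qcols, function(q) mean(d[[q]]), numeric(1), USE.NAMES = FALSE))
  all_row$d_pct <- ifelse(abs(all_row$exp_mean) < 1e-9, NA_real_,
                          100 * all_row$mean_d / abs(all_row$exp_mean))
  list(d = d, d_pct = d_pct, all = all_row)
}

#' Read a contact-force table from CSV
#'
#' Expected columns: `condition, surface, frame, fx, fz` (forces in N).
#' Unicode minus signs are normalised to ASCII on read.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_force_table <- function(path) {
  raw <- readLines(path, encoding = "UTF-8")
  raw <- gsub("−", "-", raw)
  df <- utils::read.csv(text = raw, stringsAsFactors = FALSE)
  need <- c("condition", "surface", "frame", "fx", "fz")
  if (!all(need %in% names(df)))
    stop("force table must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$surface), surface_tags)
  if (length(bad)) stop("unknown surface tag(s): ", paste(bad, collapse = ", "))
  tibble::as_tibble(df)
}

#' Write a contact-force table to CSV
#' @param tab Tibble as produced by the generators or [read_force_table()].
#' @param path Output path.
#' @export
write_force_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
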