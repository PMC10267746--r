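# Seeded generators emulating the measurement chain: pressure-mat maps with
# calibration error and sensor noise, statically admissible contact-force
# sets, and pre/post tissue-column mesh pairs with optional sliding.
# All generators are pure functions of (parameters, seed).

# fold (seed, offset) into a valid 32-bit seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483647)
}

with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(code)
}

#' Recipe for a synthetic seat-pan pressure map
#'
#' Describes a Gaussian-blob pressure pattern: two ischial-tuberosity peaks,
#' an elongated thigh ridge, a target normal force, a multiplicative
#' calibration error (what the trial correction factor must recover), and
#' multiplicative sensor noise.
#'
#' @param it_peaks Two-row data frame/matrix with columns `row, col,
#'   amplitude_kpa, spread_mm` (blob centres in grid indices, rear = low
#'   rows).
#' @param thigh_ridge List with `rows` (index span), `col_centre`,
#'   `amplitude_kpa`, `spread_mm`; amplitude 0 disables the ridge.
#' @param target_force_N True integral of the map before calibration error.
#' @param calibration_error Multiplicative factor the mat under-reports by;
#'   the recorded map is the true map divided by this.
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   sensor noise (default 0.05, in line with a mat rated at about +/-10% of
#'   scale).
#' @param seed Integer seed.
#' @return A `map_recipe` object.
#' @export
map_recipe <- function(it_peaks = default_it_peaks(),
                       thigh_ridge = default_thigh_ridge(),
                       target_force_N = 660, calibration_error = 1.5,
                       noise_cv = 0.05, seed = 1L) {
  it_peaks <- as.data.frame(it_peaks)
  stopifnot(all(c("row", "col", "amplitude_kpa", "spread_mm") %in% names(it_peaks)),
            nrow(it_peaks) == 2, all(it_peaks$amplitude_kpa > 0),
            target_force_N > 0, calibration_error > 0, noise_cv >= 0)
  structure(list(it_peaks = it_peaks, thigh_ridge = thigh_ridge,
                 target_force_N = target_force_N,
                 calibration_error = calibration_error,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "map_recipe")
}

#' @rdname map_recipe
#' @export
default_it_peaks <- function() {
  data.frame(row = c(14, 14), col = c(19, 30),
             amplitude_kpa = c(9, 9), spread_mm = c(35, 35))
}

#' @rdname map_recipe
#' @export
default_thigh_ridge <- function() {
  list(rows = c(18, 40), col_centre = c(17, 32), amplitude_kpa = 2.2,
       spread_mm = 45)
}

#' Generate a synthetic seat-pan pressure map
#'
#' Sums anisotropic Gaussian blobs (two IT peaks, a thigh ridge along the
#' fore-aft axis) on the native 48 x 48, 12.7 mm grid, rescales so the true
#' integral equals `target_force_N`, divides by the calibration error (so
#' [correction_factor()] recovers it) and applies multiplicative log-normal
#' sensor noise. Deterministic per seed.
#'
#' @param recipe A [map_recipe()].
#' @param nrow,ncol Grid size (default 48 x 48).
#' @param pitch_mm Sensor pitch (default 12.7).
#' @param threshold_kpa Activity threshold used for the ground-truth contact
#'   area (default 0.1).
#' @return A list: `grid` (the recorded [pressure_grid()]), and `truth`
#'   with the noise-free calibrated map and its `ca_mm2`, `pp_kpa`,
#'   `peak_row`, `calibration_error`, `target_force_N`, `seed`.
#' @export
gen_pressure_map <- function(recipe, nrow = 48, ncol = 48, pitch_mm = 12.7,
                             threshold_kpa = 0.1) {
  stopifnot(inherits(recipe, "map_recipe"))
  rows <- matrix(seq_len(nrow), nrow, ncol)
  cols <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  p <- matrix(0, nrow, ncol)
  for (k in seq_len(2)) {
    b <- recipe$it_peaks[k, ]
    s_cells <- b$spread_mm / pitch_mm
    p <- p + b$amplitude_kpa *
      exp(-((rows - b$row)^2 + (cols - b$col)^2) / (2 * s_cells^2))
  }
  tr <- recipe$thigh_ridge
  if (!is.null(tr) && tr$amplitude_kpa > 0) {
    s_cells <- tr$spread_mm / pitch_mm
    rmid <- mean(tr$rows)
    rhalf <- diff(range(tr$rows)) / 2
    along <- exp(-(pmax(abs(rows - rmid) - rhalf, 0)^2) / (2 * (s_cells / 3)^2))
    across <- exp(-((cols - tr$col_centre[1])^2) / (2 * (s_cells / 2)^2)) +
      exp(-((cols - tr$col_centre[2])^2) / (2 * (s_cells / 2)^2))
    p <- p + tr$amplitude_kpa * along * across
  }
  p[p < 1e-4] <- 0  # sensor floor: far tails read as zero
  integ <- sum(p) * pitch_mm^2 * 1e-3
  p <- p * recipe$target_force_N / integ  # true calibrated field, kPa

  truth_grid <- pressure_grid(p, pitch_mm = pitch_mm, surface = "SP")
  truth <- list(
    grid = truth_grid,
    ca_mm2 = sum(p > threshold_kpa) * pitch_mm^2,
    pp_kpa = max(p),
    peak_row = which.max(rowSums(p)),
    calibration_error = recipe$calibration_error,
    target_force_N = recipe$target_force_N,
    seed = recipe$seed)

  recorded <- p / recipe$calibration_error
  if (recipe$noise_cv > 0) {
    sdlog <- sqrt(log(1 + recipe$noise_cv^2))
    noise <- with_local_seed(recipe$seed,
      matrix(stats::rlnorm(nrow * ncol, meanlog = -sdlog^2 / 2, sdlog = sdlog),
             nrow, ncol))
    recorded <- recorded * noise
  }
  list(grid = pressure_grid(recorded, pitch_mm = pitch_mm, surface = "SP"),
       truth = truth)
}

#' Generate a statically admissible contact-force set
#'
#' Constructs global-frame forces on the three surfaces that satisfy
#' `sum(Fx) = 0` and `sum(Fz) + W = 0` exactly: vertical loads follow
#' `load_split`, horizontal loads follow the surface tilts plus a
#' friction-like shear parameter, and the foot-support shear closes the
#' horizontal balance. Seeded Gaussian noise then emulates measurement error
#' (an "Exp-like" draw) and a second draw with a small systematic bias
#' emulates a model output ("Sim-like").
#'
#' @param config A [seat_config()].
#' @param load_split Named fractions over `SB`, `SP`, `FS` summing to 1
#'   (vertical load shares).
#' @param noise_sd_N Gaussian noise s.d. per component (N).
#' @param seed Integer seed.
#' @param sim_bias Multiplicative bias of the Sim-like draw (default 1.1 on
#'   horizontal components, mirroring a model that overpredicts shear).
#' @return A list of tibbles `noiseless`, `exp`, `sim` with columns
#'   `condition, source, surface, frame, fx, fz`.
#' @export
gen_force_set <- function(config, load_split = c(SB = 0.12, SP = 0.78, FS = 0.10),
                          noise_sd_N = 5, seed = 1L, sim_bias = 1.1) {
  stopifnot(inherits(config, "seat_config"))
  if (!all(c("SB", "SP", "FS") %in% names(load_split)))
    stop("`load_split` needs named fractions SB, SP, FS")
  load_split <- load_split[c("SB", "SP", "FS")]
  if (any(load_split < 0) || abs(sum(load_split) - 1) > 1e-9)
    stop("infeasible `load_split`: fractions must be >= 0 and sum to 1")
  W <- config$body_weight_N
  fz <- -load_split * W
  tilt <- c(SB = surface_tilt_angle(config, "SB"),
            SP = surface_tilt_angle(config, "SP"), FS = 0) * pi / 180
  # backrest pushes the sitter forward (negative x), seat pan resists the
  # forward slide (positive x); foot support closes the balance
  fx_sb <- -load_split[["SB"]] * W * (tan(tilt[["SB"]]) + config$cof_seat)
  fx_sp <-  load_split[["SP"]] * W *
    (sin(tilt[["SP"]]) + config$cof_seat * cos(tilt[["SP"]]))
  fx_fs <- -(fx_sb + fx_sp)
  base <- tibble::tibble(
    condition = config$label, source = "truth",
    surface = c("SB", "SP", "FS"), frame = "global",
    fx = c(fx_sb, fx_sp, fx_fs), fz = as.numeric(fz))

  draws <- with_local_seed(seed, {
    e <- stats::rnorm(6, sd = noise_sd_N)
    s <- stats::rnorm(6, sd = noise_sd_N)
    list(e = e, s = s)
  })
  exp_tab <- base; exp_tab$source <- "Exp"
  exp_tab$fx <- base$fx + draws$e[1:3]; exp_tab$fz <- base$fz + draws$e[4:6]
  sim_tab <- base; sim_tab$source <- "Sim"
  sim_tab$fx <- base$fx * sim_bias + draws$s[1:3]
  sim_tab$fz <- base$fz + draws$s[4:6]
  list(noiseless = base, exp = exp_tab, sim = sim_tab)
}

#' Series flesh-over-foam column model
#'
#' Parameters of the idealised under-IT tissue column used by
#' [gen_tissue_pair()]: flesh (Ogden/neo-Hookean) of given thickness over a
#' foam cushion, an applied nominal compressive stress, and the fraction of
#' kinematic lateral sliding.
#'
#' @param flesh An [ogden_params()].
#' @param flesh_thickness_mm Unloaded flesh-column thickness (default 40).
#' @param foam A [foam_params()].
#' @param foam_thickness_mm Cushion thickness (default 50).
#' @param applied_stress_kpa Nominal compressive stress on the column.
#' @param sliding_fraction In `[0, 1]`: 0 = pure axial compression, larger
#'   values divert more material laterally out of the under-IT column.
#' @return A `column_model` object.
#' @export
column_model <- function(flesh = ogden_params(mu = 3, alpha = 2),
                         flesh_thickness_mm = 40,
                         foam = foam_params(synthetic_foam_curve(),
                                            hu = 0.65, shape = 8, scale = 1.15),
                         foam_thickness_mm = 50,
                         applied_stress_kpa = 8.5,
                         sliding_fraction = 0) {
  stopifnot(inherits(flesh, "ogden_params"), inherits(foam, "foam_params"),
            flesh_thickness_mm > 0, foam_thickness_mm > 0,
            applied_stress_kpa >= 0,
            sliding_fraction >= 0, sliding_fraction <= 1)
  structure(list(flesh = flesh, flesh_thickness_mm = flesh_thickness_mm,
                 foam = foam, foam_thickness_mm = foam_thickness_mm,
                 applied_stress_kpa = applied_stress_kpa,
                 sliding_fraction = sliding_fraction),
            class = "column_model")
}

#' Equilibrium stretches of the series flesh/foam column
#'
#' Both layers carry the same nominal stress. The flesh stretch solves the
#' incompressible uniaxial law via bisection; the foam strain inverts the
#' (scaled) loading curve.
#'
#' @param model A [column_model()].
#' @return List `lambda_flesh` (stretch, `<= 1`), `foam_strain`.
#' @export
column_equilibrium <- function(model) {
  stopifnot(inherits(model, "column_model"))
  s <- model$applied_stress_kpa
  if (s == 0) return(list(lambda_flesh = 1, foam_strain = 0))
  f <- function(l) ogden_uniaxial_stress(model$flesh, l) + s  # compression: sigma = -s
  lo <- 1e-3
  if (f(lo) > 0 || f(1) < 0)
    stop("non-convergent column equilibrium: applied stress ", s,
         " kPa outside the resolvable range of the flesh law")
  lam <- stats::uniroot(f, lower = lo, upper = 1, tol = 1e-12)$root
  list(lambda_flesh = lam,
       foam_strain = foam_equilibrium_strain(model$foam, s))
}

#' Generate an unloaded/loaded tissue-column mesh pair
#'
#' The unloaded state is a hexahedral flesh block (square footprint, height
#' equal to the flesh thickness) capped by a hemispherical bone boundary
#' resting flat-face-down on its top face; the ischium landmark is the bone
#' point closest to the seat (the centre of the flat face). The loaded state
#' applies, to the same connectivity, an axial compression to the stretch
#' solving the series flesh/foam equilibrium; with `sliding_fraction > 0` the
#' axial stretch deepens toward the column axis (a smooth radial profile) and
#' a volume-motivated outward radial flow carries the displaced material away
#' from the under-IT column, emulating gluteal tissue sliding. Deterministic
#' per seed (the generator itself draws no random numbers; the seed is
#' recorded in the output for provenance).
#'
#' @param model A [column_model()].
#' @param mesh_density_mm Target element size; must be at most a quarter of
#'   the flesh thickness (default 5).
#' @param seed Integer seed recorded in the output.
#' @param footprint_mm Block footprint edge (default 140, wide enough for the
#'   50 mm ROI plus outflow).
#' @param bone_radius_mm Hemisphere radius (default 35).
#' @param sliding_extent_mm Radius over which the sliding profile acts
#'   (default 60).
#' @return A list `pre`, `post` ([soft_tissue_mesh()]), `ischium_point`
#'   (unloaded landmark), `lambda`, `foam_strain`, `seed`.
#' @export
gen_tissue_pair <- function(model, mesh_density_mm = 5, seed = 1L,
                            footprint_mm = 140, bone_radius_mm = 35,
                            sliding_extent_mm = 60) {
  stopifnot(inherits(model, "column_model"))
  t_flesh <- model$flesh_thickness_mm
  if (mesh_density_mm > t_flesh / 4)
    stop("`mesh_density_mm` must be <= flesh thickness / 4")
  eq <- column_equilibrium(model)
  lam <- eq$lambda_flesh
  s_frac <- model$sliding_fraction

  block <- hex_block_mesh(footprint_mm, footprint_mm, t_flesh, h = mesh_density_mm)
  bone <- hemisphere_surface(bone_radius_mm, base_z = t_flesh)
  n0 <- nrow(block$nodes)
  nodes <- rbind(block$nodes, bone$nodes)
  pre <- soft_tissue_mesh(nodes, block$cells, skin = block$skin,
                          bone = bone$tris + n0, check_volumes = FALSE)
  ischium <- c(0, 0, t_flesh)

  # axial stretch profile: lambda(rho) = lam * (1 - s * cos^2(pi rho / 2 rho_s))
  rho_s <- sliding_extent_mm
  lam_of_rho <- function(rho) {
    prof <- ifelse(rho < rho_s, cos(pi * rho / (2 * rho_s))^2, 0)
    lam * (1 - s_frac * 0.35 * prof)
  }
  # outward radial flow conserving the displaced material (kinematic):
  # u_r grows inside rho_s and decays smoothly beyond it
  u_r_of_rho <- function(rho) {
    s_frac * 0.35 * lam * t_flesh / 2 *
      ifelse(rho < rho_s, sin(pi * rho / rho_s)^2,
             exp(-(rho - rho_s) / (0.3 * rho_s)))
  }
  deform <- function(p) {
    rho <- sqrt(p[, 1]^2 + p[, 2]^2)
    l <- lam_of_rho(rho)
    z <- p[, 3] * l
    ur <- u_r_of_rho(rho) * (p[, 3] / t_flesh)  # no slip at the seat face
    scale_r <- ifelse(rho > 1e-9, (rho + ur) / rho, 1)
    cbind(p[, 1] * scale_r, p[, 2] * scale_r, z)
  }
  post <- transform_mesh(pre, deform)
  list(pre = pre, post = post, ischium_point = ischium,
       lambda = lam, foam_strain = eq$foam_strain, seed = as.integer(seed))
}
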