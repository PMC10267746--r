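# Bundled validation dataset: contact-force, pressure-parameter and
# soft-tissue tables from a single-subject experiment on a reconfigurable
# seat (four configurations, SPA 0/5/10/15 deg, SP2BA fixed at 100 deg,
# subject weight force 784.8 N), together with the matching full-body-model
# simulation outputs. Values are kept at their published precision
# (0.1 N / 0.1 kPa / 1 mm^2 / 0.1 mm / 0.1 %).

#' Reference seat conditions of the validation study
#'
#' The four seat configurations of the bundled validation dataset: seat-pan
#' angle 0-15 degrees in 5-degree steps, seat-pan-to-backrest angle 100
#' degrees, subject weight force 784.8 N, friction coefficients 0.1
#' (seat/backrest) and 0.4 (foot support).
#'
#' @return A named list of [seat_config()] objects (`SPA0` ... `SPA15`).
#' @export
reference_conditions <- function() {
  cfgs <- lapply(c(0, 5, 10, 15), function(a)
    seat_config(spa_deg = a, sp2ba_deg = 100, body_weight_N = 784.8,
                cof_seat = 0.1, cof_foot = 0.4))
  names(cfgs) <- vapply(cfgs, `[[`, character(1), "label")
  cfgs
}

#' Reference contact-force table (global frame)
#'
#' Measured (`Exp`) and simulated (`Sim`) global-frame contact forces on the
#' seat back (SB), seat pan (SP) and foot support (FS) for the four reference
#' conditions, in newtons.
#'
#' @return A tibble with columns `condition, source, surface, frame, fx, fz`.
#' @export
reference_forces_global <- function() {
  rows <- list(
    # condition, source,  Fx_SB,  Fz_SB,  Fx_SP,   Fz_SP, Fx_FS, Fz_FS
    list("SPA0",  "Exp",  -73.5,  -32.0,   59.2,  -697.0,   7.6, -66.0),
    list("SPA0",  "Sim",  -76.8,  -16.2,   67.8,  -705.2,   9.0, -64.1),
    list("SPA5",  "Exp",  -98.8,  -37.3,   88.4,  -689.2,   8.2, -68.1),
    list("SPA5",  "Sim", -118.7,  -29.6,  111.3,  -694.8,   9.1, -60.9),
    list("SPA10", "Exp", -126.2,  -72.8,  113.9,  -643.0,   9.8, -73.5),
    list("SPA10", "Sim", -157.7,  -52.4,  140.3,  -661.1,  19.6, -73.9),
    list("SPA15", "Exp", -167.8, -109.4,  150.5,  -578.2,  17.3, -97.7),
    list("SPA15", "Sim", -202.4,  -87.1,  174.7,  -608.4,  30.4, -94.4))
  do.call(rbind, lapply(rows, function(r)
    tibble::tibble(condition = r[[1]], source = r[[2]],
                   surface = c("SB", "SP", "FS"), frame = "global",
                   fx = c(r[[3]], r[[5]], r[[7]]),
                   fz = c(r[[4]], r[[6]], r[[8]]))))
}

#' Reference contact-force table (surface-local frame, published values)
#'
#' Published local-frame forces for the seat back and seat pan; used as the
#' cross-check target for [rotate_global_to_local()] applied to
#' [reference_forces_global()].
#'
#' @return A tibble with columns `condition, source, surface, frame, fx, fz`.
#' @export
reference_forces_local <- function() {
  rows <- list(
    # condition, source, Fx_SB_L, Fz_SB_L, Fx_SP_L, Fz_SP_L
    list("SPA0",  "Exp",  -78.0, -18.7,  59.2, -697.0),
    list("SPA0",  "Sim",  -78.5,  -2.6,  67.8, -705.2),
    list("SPA5",  "Exp", -105.1, -10.5,  28.0, -694.3),
    list("SPA5",  "Sim", -122.3,   2.2,  50.3, -701.9),
    list("SPA10", "Exp", -143.5, -25.2,   0.5, -653.0),
    list("SPA10", "Sim", -166.1,   4.7,  23.3, -675.4),
    list("SPA15", "Exp", -198.3, -28.2,  -4.3, -597.4),
    list("SPA15", "Sim", -220.3,   6.6,  11.2, -632.9))
  do.call(rbind, lapply(rows, function(r)
    tibble::tibble(condition = r[[1]], source = r[[2]],
                   surface = c("SB", "SP"), frame = "local",
                   fx = c(r[[3]], r[[5]]),
                   fz = c(r[[4]], r[[6]]))))
}

#' Reference pressure-parameter table
#'
#' Measured and simulated pressure parameters per condition: contact area
#' (mm^2), peak and mean pressure (kPa) on seat back and seat pan, the
#' four-region seat-pan pressure proportions (%), and the trial correction
#' factors (experimental trials only).
#'
#' @return A tibble, one row per condition x source.
#' @export
reference_pressure_params <- function() {
  tb <- tibble::tribble(
    ~condition, ~source, ~ca_sb, ~pp_sb, ~mp_sb, ~ca_sp, ~pp_sp, ~mp_sp,
    ~p_i, ~p_ii, ~p_iii, ~p_iv, ~fcorr_sb, ~fcorr_sp,
    "SPA0",  "Exp",  40968, 3.2, 1.9, 168225, 13.4, 4.1, 36.7, 42.4, 13.4, 7.5, 1.76, 1.38,
    "SPA0",  "Sim",  46935, 4.9, 1.9, 176774, 13.1, 4.2, 39.2, 42.7, 11.3, 6.7, NA,   NA,
    "SPA5",  "Exp",  49355, 3.5, 2.1, 165484, 14.1, 4.2, 40.4, 40.9, 12.1, 6.5, 1.69, 1.48,
    "SPA5",  "Sim",  65968, 5.4, 2.1, 174354, 13.2, 4.2, 39.1, 42.4, 11.5, 6.9, NA,   NA,
    "SPA10", "Exp",  71451, 3.3, 2.0, 165967, 14.7, 3.9, 37.2, 43.1, 13.8, 6.0, 1.81, 1.54,
    "SPA10", "Sim",  78387, 5.8, 2.3, 176451, 12.2, 4.0, 42.2, 39.8, 11.4, 6.7, NA,   NA,
    "SPA15", "Exp",  80806, 3.8, 2.5, 158871, 12.1, 3.8, 40.9, 42.5, 11.5, 5.1, 1.67, 1.64,
    "SPA15", "Sim", 100322, 6.2, 2.4, 168871, 12.2, 3.9, 43.5, 41.8, 10.4, 4.3, NA,   NA)
  tb
}

#' Reference soft-tissue thickness/volume-reduction table
#'
#' Simulated mean soft-tissue thickness under the ischial tuberosity before
#' and after loading (mm) and volume reduction R (%) in the 20 mm and 50 mm
#' cylinder ROIs, with (`Y`) and without (`N`) tissue sliding.
#'
#' @return A tibble, one row per condition x sliding flag x ROI.
#' @export
reference_tissue_table <- function() {
  tibble::tribble(
    ~condition, ~sliding, ~roi_mm, ~t_preload, ~t_loaded, ~r_pct,
    "SPA0",  "Y", 20, 38.8, 14.1, 60.8,
    "SPA0",  "Y", 50, 41.0, 19.3, 50.8,
    "SPA0",  "N", 20, 38.9, 16.8, 51.8,
    "SPA0",  "N", 50, 41.2, 22.1, 42.4,
    "SPA5",  "Y", 20, 38.8, 15.4, 58.5,
    "SPA5",  "Y", 50, 41.1, 20.5, 49.1,
    "SPA5",  "N", 20, 38.8, 17.7, 51.5,
    "SPA5",  "N", 50, 41.0, 23.1, 42.4,
    "SPA10", "Y", 20, 38.8, 16.0, 56.1,
    "SPA10", "Y", 50, 41.1, 21.1, 46.3,
    "SPA10", "N", 20, 38.9, 18.2, 47.3,
    "SPA10", "N", 50, 41.2, 23.4, 37.8,
    "SPA15", "Y", 20, 38.8, 16.0, 54.8,
    "SPA15", "Y", 50, 41.1, 21.0, 45.3,
    "SPA15", "N", 20, 38.9, 18.0, 47.5,
    "SPA15", "N", 50, 41.2, 23.3, 38.5)
}

#' Reference material parameter sets
#'
#' Material parameters of the validation model: rigid bone metadata,
#' neo-Hookean soft tissue (shear modulus Mu1 = 3e-6 GPa, Alpha1 = 2,
#' Poisson 0.499), elastic skin metadata, and the two low-density-foam
#' cushions (seat pan HU = 0.65 / SHAPE = 8, backrest HU = 0.65 / SHAPE = 5,
#' loading-curve scale factor 1.15).
#'
#' @return A named list with elements `tissue` ([ogden_params()]),
#'   `seat_foam`, `backrest_foam` ([foam_params()]), and `metadata` (a tibble
#'   of the remaining published constants).
#' @export
reference_materials <- function() {
  list(
    tissue = ogden_params(mu = 3e-6, alpha = 2, poisson = 0.499,
                          density = 9.0e-7, unit = "GPa"),
    seat_foam = foam_params(loading_curve = synthetic_foam_curve(),
                            e_tensile_gpa = 1.04e-4, hu = 0.65, shape = 8,
                            beta = 0, scale = 1.15, density = 5.0e-8),
    backrest_foam = foam_params(loading_curve = synthetic_foam_curve(),
                                e_tensile_gpa = 8.75e-5, hu = 0.65, shape = 5,
                                beta = 0, scale = 1.15, density = 4.9e-8),
    metadata = tibble::tribble(
      ~material, ~property, ~value, ~unit,
      "bone", "density",          1.7e-6, "kg/mm^3",
      "bone", "youngs_modulus",   6,      "GPa",
      "bone", "poisson",          0.3,    "",
      "skin", "density",          1.0e-6, "kg/mm^3",
      "skin", "youngs_modulus",   2.5e-3, "GPa",
      "skin", "poisson",          0.45,   ""))
}
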