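#' Ogden hyperelastic parameters (incompressible uniaxial form)
#'
#' One or more Ogden terms `(mu_i, alpha_i)`. The single-term case with
#' `alpha = 2` is the neo-Hookean material used for lumped flesh. The uniaxial
#' laws here use the incompressible limit; `poisson` and `density` are carried
#' as metadata.
#'
#' @param mu Shear moduli, one per term. Interpreted in `unit` and stored in
#'   kPa.
#' @param alpha Exponents, one per term (dimensionless).
#' @param poisson Poisson's ratio metadata, in `(0, 0.5)`.
#' @param density Density metadata (kg/mm^3).
#' @param unit Unit of `mu`: `"kPa"` (default) or `"GPa"`.
#' @return An `ogden_params` object with `mu_kpa`, `alpha`, `poisson`,
#'   `density`.
#' @examples
#' flesh <- ogden_params(mu = 3e-6, alpha = 2, unit = "GPa")  # 3 kPa shear
#' ogden_uniaxial_stress(flesh, 0.5)
#' @export
ogden_params <- function(mu, alpha, poisson = 0.499, density = 9e-7,
                         unit = c("kPa", "GPa")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(mu), is.numeric(alpha), length(mu) == length(alpha),
            length(mu) >= 1, all(is.finite(mu)), all(is.finite(alpha)))
  mu_kpa <- if (unit == "GPa") mu * 1e6 else mu
  if (sum(mu_kpa * alpha) <= 0)
    stop("need sum(mu_i * alpha_i) > 0 for a positive ground-state modulus")
  if (poisson <= 0 || poisson >= 0.5)
    stop("`poisson` must lie in (0, 0.5)")
  structure(list(mu_kpa = mu_kpa, alpha = alpha, poisson = poisson,
                 density = density),
            class = "ogden_params")
}

#' Uniaxial nominal stress of an incompressible Ogden material
#'
#' For stretch `lambda` the nominal (first Piola-Kirchhoff) stress is
#' `sigma = sum_i mu_i (lambda^(alpha_i - 1) - lambda^(-alpha_i/2 - 1))` (kPa).
#' For a single term with `alpha = 2` this reduces to the neo-Hookean
#' `mu (lambda - lambda^-2)`. Compression gives negative stress.
#'
#' @param p An [ogden_params()].
#' @param stretch Stretch ratio `lambda > 0` (vectorised).
#' @return Nominal stress in kPa.
#' @export
ogden_uniaxial_stress <- function(p, stretch) {
  stopifnot(inherits(p, "ogden_params"))
  if (any(!is.finite(stretch)) || any(stretch <= 0))
    stop("`stretch` must be positive")
  vapply(stretch, function(l)
    sum(p$mu_kpa * (l^(p$alpha - 1) - l^(-p$alpha / 2 - 1))), numeric(1))
}

#' Uniaxial strain energy of an incompressible Ogden material
#'
#' `W(lambda) = sum_i (mu_i / alpha_i) (lambda^alpha_i + 2 lambda^(-alpha_i/2) - 3)`
#' (kPa = mJ/mm^3); its derivative is [ogden_uniaxial_stress()].
#'
#' @inheritParams ogden_uniaxial_stress
#' @return Energy density in kPa.
#' @export
ogden_strain_energy <- function(p, stretch) {
  stopifnot(inherits(p, "ogden_params"))
  if (any(!is.finite(stretch)) || any(stretch <= 0))
    stop("`stretch` must be positive")
  vapply(stretch, function(l)
    sum(p$mu_kpa / p$alpha * (l^p$alpha + 2 * l^(-p$alpha / 2) - 3)),
    numeric(1))
}

#' Low-density foam parameters
#'
#' Tabulated uniaxial loading curve (nominal strain vs nominal stress, kPa,
#' compression positive) with hysteretic unloading controlled by the
#' unloading factor `HU` and shape factor `SHAPE`, a reloading decay constant
#' `BETA` (0 = reloading follows the loading curve), a loading-curve scale
#' factor, tensile Young's modulus and density metadata.
#'
#' @param loading_curve Two-column matrix/data frame `(strain, stress_kpa)`
#'   with strictly increasing strain starting at `(0, 0)` and non-decreasing
#'   stress.
#' @param e_tensile_gpa Tensile Young's modulus metadata (GPa).
#' @param hu Hysteretic unloading factor in `(0, 1]`.
#' @param shape Unloading shape factor, `> 0`.
#' @param beta Reloading decay constant (default 0).
#' @param scale Multiplicative scale applied to the loading-curve stresses
#'   (default 1).
#' @param density Density metadata (kg/mm^3).
#' @return A `foam_params` object.
#' @export
foam_params <- function(loading_curve, e_tensile_gpa = NA_real_, hu = 1,
                        shape = 1, beta = 0, scale = 1, density = NA_real_) {
  lc <- as.matrix(loading_curve)
  if (ncol(lc) != 2) stop("`loading_curve` must have two columns (strain, stress)")
  colnames(lc) <- c("strain", "stress_kpa")
  if (any(!is.finite(lc))) stop("loading curve must be finite")
  if (any(diff(lc[, 1]) <= 0)) stop("loading-curve strains must be strictly increasing")
  if (abs(lc[1, 1]) > 1e-12 || abs(lc[1, 2]) > 1e-12)
    stop("loading curve must pass through (0, 0)")
  if (any(diff(lc[, 2]) < 0)) stop("loading-curve stress must be non-decreasing")
  if (!(hu > 0 && hu <= 1)) stop("`hu` must lie in (0, 1]")
  if (shape <= 0) stop("`shape` must be > 0")
  if (scale <= 0) stop("`scale` must be > 0")
  structure(list(loading_curve = lc, e_tensile_gpa = e_tensile_gpa, hu = hu,
                 shape = shape, beta = beta, scale = scale, density = density),
            class = "foam_params")
}

#' @export
print.foam_params <- function(x, ...) {
  cat(sprintf(
    "<foam_params>  %d-point curve to strain %.2f (scale %.2f), HU %.2f, SHAPE %.2f, BETA %.2f\n",
    nrow(x$loading_curve), max(x$loading_curve[, 1]), x$scale, x$hu, x$shape,
    x$beta))
  invisible(x)
}

#' Synthetic flexible-foam compression curve
#'
#' A synthetic seat-cushion-shaped loading curve (initial elastic rise,
#' buckling plateau around 4-6 kPa, densification past ~60% strain) used as
#' the default tabulated curve where no measured one is supplied. It is a
#' constructed stand-in, not a measured dataset.
#'
#' @param max_strain Last knot (default 0.8, the compression-test stop).
#' @return A two-column matrix `(strain, stress_kpa)`.
#' @export
synthetic_foam_curve <- function(max_strain = 0.8) {
  strain <- seq(0, max_strain, by = 0.05)
  # elastic toe + plateau + exponential densification, in kPa
  stress <- 3.5 * (1 - exp(-strain / 0.04)) + 1.2 * strain +
    0.9 * (exp(pmax(strain - 0.55, 0) / 0.075) - 1)
  stress[1] <- 0
  cbind(strain = strain, stress_kpa = stress)
}

# piecewise-linear loading stress at arbitrary strain (scale applied)
foam_stress_interp <- function(p, strain) {
  lc <- p$loading_curve
  if (any(strain < 0) || any(strain > max(lc[, 1]) + 1e-12))
    stop("strain outside the tabulated range [0, ", max(lc[, 1]),
         "]; no extrapolation")
  strain <- pmin(strain, max(lc[, 1]))
  p$scale * stats::approx(lc[, 1], lc[, 2], xout = strain, method = "linear",
                          ties = "ordered")$y
}

#' Nominal loading stress of the foam
#'
#' Piecewise-linear interpolation of the tabulated loading curve multiplied
#' by the scale factor; strains beyond the last knot are rejected (no
#' extrapolation).
#'
#' @param p A [foam_params()].
#' @param strain Nominal compressive strain(s) in `[0, max curve strain]`.
#' @return Nominal stress in kPa (compression positive).
#' @export
foam_loading_stress <- function(p, strain) {
  stopifnot(inherits(p, "foam_params"))
  foam_stress_interp(p, strain)
}

#' Strain energy absorbed along the loading curve
#'
#' `W(strain) = integral_0^strain sigma_L de`, evaluated exactly on the
#' piecewise-linear (scaled) curve.
#'
#' @inheritParams foam_loading_stress
#' @return Energy density in kPa.
#' @export
foam_loading_energy <- function(p, strain) {
  stopifnot(inherits(p, "foam_params"))
  lc <- p$loading_curve
  if (any(strain < 0) || any(strain > max(lc[, 1]) + 1e-12))
    stop("strain outside the tabulated range; no extrapolation")
  strain <- pmin(strain, max(lc[, 1]))
  s <- lc[, 1]; v <- p$scale * lc[, 2]
  cumW <- c(0, cumsum(diff(s) * (utils::head(v, -1) + utils::tail(v, -1)) / 2))
  vapply(strain, function(e) {
    k <- findInterval(e, s)
    if (k >= length(s)) return(cumW[length(s)])
    # partial trapezoid within segment k
    sig_e <- v[k] + (v[k + 1] - v[k]) * (e - s[k]) / (s[k + 1] - s[k])
    cumW[k] + (e - s[k]) * (v[k] + sig_e) / 2
  }, numeric(1))
}

#' Hysteretic unloading stress of the foam
#'
#' Unloading from a cycle peak at `strain_max` follows
#' `sigma_U(e) = sigma_L(e) * [HU + (1 - HU) * (W(e) / W(e_max))^SHAPE]`
#' with `W` the loading-curve energy ([foam_loading_energy()]). The branch is
#' continuous with the loading curve at `strain_max`, lies at or below it
#' everywhere, recovers the elastic limit at `HU = 1`, and dissipates more
#' energy for larger `SHAPE`. This energy-ratio interpolation is this
#' package's definition of the HU/SHAPE unloading law; it satisfies the
#' qualitative behaviours attributed to those factors without claiming
#' numerical identity with any particular FE solver's internal equations.
#'
#' @inheritParams foam_loading_stress
#' @param strain_max Strain at the start of unloading (cycle peak).
#' @return Nominal stress in kPa.
#' @export
foam_unloading_stress <- function(p, strain, strain_max) {
  stopifnot(inherits(p, "foam_params"))
  if (any(strain < -1e-12) || any(strain > strain_max + 1e-12))
    stop("unloading strain must lie in [0, strain_max]")
  strain <- pmin(pmax(strain, 0), strain_max)
  wmax <- foam_loading_energy(p, strain_max)
  if (wmax <= 0) return(foam_stress_interp(p, strain) * 0)
  w <- foam_loading_energy(p, strain)
  foam_stress_interp(p, strain) * (p$hu + (1 - p$hu) * (w / wmax)^p$shape)
}

#' Quasi-static virtual compression test
#'
#' Simulates the standard uniaxial compression test of a foam cube (50 mm
#' side by default): load at constant nominal strain rate to `max_strain`
#' (default 0.8, the 80%-compression stop of the standard test), then unload
#' to zero. The response is rate-independent (`beta = 0`), so only the strain
#' path matters.
#'
#' @param p A [foam_params()].
#' @param sample_mm Cube edge lengths, mm (metadata; default `c(50, 50, 50)`).
#' @param max_strain Peak nominal strain (default 0.8).
#' @param strain_step Sampling step (default 0.01).
#' @return A list of two tibbles `loading` and `unloading`, each with
#'   `strain` and `stress_kpa`, plus `dissipated_kpa`, the cycle energy loss
#'   per unit volume (trapezoid loop integral).
#' @export
simulate_compression_test <- function(p, sample_mm = c(50, 50, 50),
                                      max_strain = 0.8, strain_step = 0.01) {
  stopifnot(inherits(p, "foam_params"))
  if (max_strain > max(p$loading_curve[, 1]) + 1e-12)
    stop("`max_strain` exceeds the tabulated curve")
  e <- seq(0, max_strain, by = strain_step)
  if (utils::tail(e, 1) < max_strain) e <- c(e, max_strain)
  load <- tibble::tibble(strain = e, stress_kpa = foam_loading_stress(p, e),
                         mode = "loading")
  unload <- tibble::tibble(strain = rev(e),
                           stress_kpa = foam_unloading_stress(p, rev(e), max_strain),
                           mode = "unloading")
  trap <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  dissipated <- trap(load$strain, load$stress_kpa) +
    trap(unload$strain, unload$stress_kpa)  # unload strains descend: negative
  list(loading = load, unloading = unload,
       dissipated_kpa = dissipated, sample_mm = sample_mm)
}

#' Equilibrium strain of the foam under a static stress
#'
#' Inverts the (scaled) loading curve: finds the nominal strain at which
#' `sigma_L(strain) = stress_kpa`, e.g. for a mass resting on a foam sample.
#'
#' @param p A [foam_params()].
#' @param stress_kpa Applied nominal compressive stress (kPa, `>= 0`).
#' @param tol Root tolerance (strain units).
#' @return Equilibrium nominal strain.
#' @export
foam_equilibrium_strain <- function(p, stress_kpa, tol = 1e-9) {
  stopifnot(inherits(p, "foam_params"), stress_kpa >= 0)
  emax <- max(p$loading_curve[, 1])
  if (stress_kpa > foam_loading_stress(p, emax))
    stop("applied stress exceeds the tabulated curve: no equilibrium below ",
         emax, " strain")
  if (stress_kpa == 0) return(0)
  stats::uniroot(function(e) foam_loading_stress(p, e) - stress_kpa,
                 lower = 0, upper = emax, tol = tol)$root
}

#' Identify HU and SHAPE from a measured unloading branch
#'
#' Least-squares fit of the hysteretic unloading law to measured unloading
#' stresses, given the (scaled) loading curve: a coarse grid over
#' `HU in (0, 1]` x `SHAPE in (0, 15]` seeds a Nelder-Mead refinement. When
#' the fitted `HU` is at (or numerically at) 1 the unloading branch is
#' elastic and `SHAPE` has no influence; it is then flagged unidentifiable.
#'
#' @param loading_curve Two-column `(strain, stress_kpa)` loading table (may
#'   also be a [foam_params()], whose curve and scale are reused).
#' @param measured_unloading Two-column `(strain, stress_kpa)` unloading
#'   measurements, at least 3 points; the largest strain is taken as the
#'   cycle peak.
#' @param scale Loading-curve scale factor (ignored when `loading_curve` is a
#'   `foam_params`).
#' @return A list `hu`, `shape`, `fit_rmse` (kPa), `shape_identifiable`.
#' @export
identify_unloading_params <- function(loading_curve, measured_unloading,
                                      scale = 1) {
  base <- if (inherits(loading_curve, "foam_params")) loading_curve
          else foam_params(loading_curve, scale = scale)
  mu <- as.matrix(measured_unloading)
  if (ncol(mu) != 2 || nrow(mu) < 3)
    stop("`measured_unloading` needs >= 3 (strain, stress) points")
  if (all(abs(mu[, 2]) < 1e-12))
    stop("degenerate unloading curve (all-zero stresses)")
  emax <- max(mu[, 1])
  pred <- function(hu, shape) {
    q <- base; q$hu <- hu; q$shape <- shape
    foam_unloading_stress(q, mu[, 1], emax)
  }
  sse <- function(hu, shape) sum((pred(hu, shape) - mu[, 2])^2)
  grid <- expand.grid(hu = seq(0.05, 1, by = 0.05),
                      shape = c(seq(0.5, 10, by = 0.5), 12, 15))
  g_sse <- mapply(sse, grid$hu, grid$shape)
  best <- grid[which.min(g_sse), ]
  # refine on a transformed scale keeping hu in (0,1], shape > 0
  obj <- function(par) {
    hu <- stats::plogis(par[1]); shape <- exp(par[2])
    sse(hu, shape)
  }
  start <- c(stats::qlogis(min(max(best$hu, 1e-3), 1 - 1e-6)), log(best$shape))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  hu <- stats::plogis(opt$par[1]); shape <- exp(opt$par[2])
  # elastic limit: prefer the boundary when it fits as well
  if (sse(1, 1) <= opt$value + 1e-12) { hu <- 1; shape <- NA_real_ }
  rmse <- sqrt((if (is.na(shape)) sse(1, 1) else sse(hu, shape)) / nrow(mu))
  list(hu = hu, shape = shape, fit_rmse = rmse,
       shape_identifiable = !(is.na(shape) || hu > 1 - 1e-4))
}

#' Read / write stress-strain curves as 2-column CSV
#'
#' @param path CSV with columns `strain, stress_kpa`.
#' @return A two-column matrix.
#' @export
read_stress_strain_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("strain", "stress_kpa") %in% names(df)))
    stop("expected columns `strain`, `stress_kpa`")
  as.matrix(df[, c("strain", "stress_kpa")])
}

#' @rdname read_stress_strain_csv
#' @param curve Two-column `(strain, stress_kpa)` matrix or data frame.
#' @export
write_stress_strain_csv <- function(curve, path) {
  m <- as.matrix(curve); colnames(m) <- c("strain", "stress_kpa")
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}
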