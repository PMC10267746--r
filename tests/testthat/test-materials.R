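test_that("Ogden uniaxial stress matches its closed form and energy derivative", {
  p <- ogden_params(mu = 3, alpha = 2)
  expect_equal(ogden_uniaxial_stress(p, 1), 0)
  expect_equal(ogden_uniaxial_stress(p, 0.5), 3 * (0.5 - 4))  # -10.5 kPa
  # numeric dW/dlambda (central difference) vs closed form, incl. a 2-term law
  p2 <- ogden_params(mu = c(2, 0.5), alpha = c(2, -1.5))
  for (pp in list(p, p2)) for (l in c(0.3, 0.5, 0.8, 1.1, 1.6)) {
    h <- 1e-6
    dW <- (ogden_strain_energy(pp, l + h) - ogden_strain_energy(pp, l - h)) / (2 * h)
    expect_equal(ogden_uniaxial_stress(pp, l), dW, tolerance = 1e-8)
  }
  # small-strain stiffness: dsigma/dlambda at 1 equals 3*mu for alpha = 2
  h <- 1e-7
  slope <- (ogden_uniaxial_stress(p, 1 + h) - ogden_uniaxial_stress(p, 1 - h)) / (2 * h)
  expect_equal(slope, 3 * 3, tolerance = 1e-6)
  expect_error(ogden_uniaxial_stress(p, -0.1), "positive")
  expect_error(ogden_params(mu = 3, alpha = 2, poisson = 0.5), "poisson")
})

test_that("foam loading stress interpolates the scaled curve with no extrapolation", {
  curve <- cbind(c(0, 0.2, 0.5, 0.8), c(0, 2, 4, 10))
  p <- foam_params(curve, scale = 1.15)
  expect_equal(foam_loading_stress(p, 0), 0)
  expect_equal(foam_loading_stress(p, 0.5), 1.15 * 4)     # knot, exact
  expect_equal(foam_loading_stress(p, 0.35), 1.15 * 3)    # midpoint of segment
  p1 <- foam_params(curve, scale = 1)
  strains <- seq(0, 0.8, by = 0.05)
  expect_equal(foam_loading_stress(p, strains),
               1.15 * foam_loading_stress(p1, strains))
  expect_error(foam_loading_stress(p, 0.9), "extrapolation")
  expect_error(foam_params(cbind(c(0.1, 0.5), c(0, 1))), "\\(0, 0\\)")
  expect_error(foam_params(cbind(c(0, 0.5), c(0, -1))), "non-decreasing")
})

test_that("loading energy equals the trapezoid integral of the curve", {
  p <- foam_params(synthetic_foam_curve(), scale = 1.15)
  for (e in c(0.13, 0.4, 0.62, 0.8)) {
    xs <- seq(0, e, length.out = 4001)
    expect_equal(foam_loading_energy(p, e),
                 oracle_trapz(xs, foam_loading_stress(p, xs)),
                 tolerance = 1e-6)
  }
})

test_that("hysteretic unloading stays below loading, is continuous at the peak, and is elastic at HU = 1", {
  p <- foam_params(synthetic_foam_curve(), hu = 0.65, shape = 8)
  emax <- 0.7
  es <- seq(0, emax, by = 0.01)
  s_l <- foam_loading_stress(p, es)
  s_u <- foam_unloading_stress(p, es, emax)
  expect_true(all(s_u <= s_l + 1e-12))
  expect_equal(s_u[length(es)], s_l[length(es)], tolerance = 1e-12)
  p_el <- foam_params(synthetic_foam_curve(), hu = 1, shape = 8)
  expect_equal(foam_unloading_stress(p_el, es, emax),
               foam_loading_stress(p_el, es))
  expect_error(foam_unloading_stress(p, 0.8, 0.7), "strain_max")
})

test_that("compression-cycle dissipation is the loop integral, positive iff HU < 1", {
  p <- foam_params(synthetic_foam_curve(), hu = 0.65, shape = 8, scale = 1.15)
  ct <- simulate_compression_test(p, max_strain = 0.8, strain_step = 0.005)
  # loop integral with the independent trapezoid oracle
  diss <- oracle_trapz(ct$loading$strain, ct$loading$stress_kpa) -
    oracle_trapz(rev(ct$unloading$strain), rev(ct$unloading$stress_kpa))
  expect_equal(ct$dissipated_kpa, diss, tolerance = 1e-9)
  expect_gt(ct$dissipated_kpa, 0)
  p_el <- foam_params(synthetic_foam_curve(), hu = 1, shape = 8)
  expect_equal(simulate_compression_test(p_el)$dissipated_kpa, 0, tolerance = 1e-12)
  # branches equal the point-wise laws
  expect_equal(ct$loading$stress_kpa, foam_loading_stress(p, ct$loading$strain))
  expect_equal(ct$unloading$stress_kpa,
               foam_unloading_stress(p, ct$unloading$strain, 0.8))
})

test_that("static mass-on-foam equilibrium matches an independent bisection", {
  p <- foam_params(synthetic_foam_curve(), scale = 1.15)
  for (mass_kg in c(2, 4, 7)) {
    stress <- mass_kg * 9.81 / (50 * 50) * 1e3  # N/mm^2 -> kPa
    e <- foam_equilibrium_strain(p, stress)
    e_or <- oracle_bisect(function(x) foam_loading_stress(p, x) - stress, 0, 0.8)
    expect_equal(e, e_or, tolerance = 1e-6)
    expect_equal(foam_loading_stress(p, e), stress, tolerance = 1e-6)
  }
  # scaling the curve by 1.15 scales the stress at fixed strain by exactly 1.15
  p1 <- foam_params(synthetic_foam_curve(), scale = 1)
  e1 <- foam_equilibrium_strain(p1, 3)
  e115 <- foam_equilibrium_strain(p, 3 * 1.15)
  expect_equal(e1, e115, tolerance = 1e-8)
  expect_error(foam_equilibrium_strain(p, 1e5), "exceeds")
})

test_that("HU/SHAPE identification recovers the generating pairs on clean data", {
  curve <- synthetic_foam_curve()
  for (truth in list(c(0.65, 8), c(0.65, 5))) {
    gen <- foam_params(curve, hu = truth[1], shape = truth[2], scale = 1.15)
    es <- seq(0, 0.8, by = 0.02)
    meas <- cbind(es, foam_unloading_stress(gen, es, 0.8))
    fit <- identify_unloading_params(foam_params(curve, scale = 1.15), meas)
    expect_equal(fit$hu, truth[1], tolerance = 0.01 * truth[1])
    expect_equal(fit$shape, truth[2], tolerance = 0.01 * truth[2])
    expect_lt(fit$fit_rmse, 1e-4)
    expect_true(fit$shape_identifiable)
  }
})

test_that("identification flags SHAPE as unidentifiable for elastic (HU = 1) data", {
  curve <- synthetic_foam_curve()
  gen <- foam_params(curve, hu = 1, shape = 8)
  es <- seq(0, 0.8, by = 0.02)
  meas <- cbind(es, foam_unloading_stress(gen, es, 0.8))
  fit <- identify_unloading_params(foam_params(curve), meas)
  expect_equal(fit$hu, 1, tolerance = 1e-6)
  expect_false(fit$shape_identifiable)
  expect_error(identify_unloading_params(curve, cbind(es, 0 * es)), "degenerate")
})

test_that("identification tolerates multiplicative measurement noise", {
  curve <- synthetic_foam_curve()
  gen <- foam_params(curve, hu = 0.65, shape = 8, scale = 1.15)
  es <- seq(0.02, 0.8, by = 0.02)
  clean <- foam_unloading_stress(gen, es, 0.8)
  set.seed(99)
  noisy <- clean * (1 + stats::rnorm(length(es), sd = 0.02))
  fit <- identify_unloading_params(foam_params(curve, scale = 1.15),
                                   cbind(es, noisy))
  expect_equal(fit$hu, 0.65, tolerance = 0.10 * 0.65)
  expect_equal(fit$shape, 8, tolerance = 0.10 * 8)
})

test_that("stress-strain CSV round-trips", {
  tf <- tempfile(fileext = ".csv")
  write_stress_strain_csv(synthetic_foam_curve(), tf)
  back <- read_stress_strain_csv(tf)
  expect_equal(unname(back), unname(synthetic_foam_curve()), tolerance = 1e-12)
})
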