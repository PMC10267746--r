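test_that("correction factor scales and round-trips", {
  m <- matrix(2, 4, 4)  # integral = 2 * 16 * 100 * 1e-3 = 3.2 N at 10 mm pitch
  g <- pressure_grid(m, pitch_mm = 10)
  expect_equal(correction_factor(g, 3.2), 1.0)
  expect_equal(correction_factor(g, 4.8), 1.5)
  # idempotence: after applying fcorr the factor is 1
  g2 <- apply_correction(g, correction_factor(g, 4.8))
  expect_equal(correction_factor(g2, 4.8), 1.0, tolerance = 1e-9)
  expect_error(correction_factor(pressure_grid(matrix(0, 3, 3)), 5), "zero-pressure")
  expect_error(correction_factor(g, 0), "normal_force_N")
})

test_that("pressure summary matches a brute-force cell loop", {
  set.seed(11)
  for (i in 1:10) {
    m <- matrix(stats::runif(25, 0, 12), 5, 5)
    m[m < 2] <- 0
    force <- stats::runif(1, 50, 400)
    thr <- stats::runif(1, 0, 3)
    g <- pressure_grid(m, pitch_mm = 12.7)
    sm <- summarize_pressure(g, threshold_kpa = thr, normal_force_N = force)
    or <- oracle_pressure_summary(m, 12.7, thr, force)
    expect_equal(sm$ca_mm2, or$ca)
    expect_equal(sm$pp_kpa, or$pp)
    expect_equal(sm$mp_kpa, or$mp)
    expect_equal(sm$fcorr, or$fcorr)
  }
})

test_that("summary behaves on uniform and empty grids", {
  g <- pressure_grid(matrix(1, 6, 6), pitch_mm = 10)
  sm <- summarize_pressure(g, threshold_kpa = 0)
  expect_equal(sm$pp_kpa, 1)
  expect_equal(sm$mp_kpa, 1)
  expect_equal(sm$ca_mm2, 36 * 100)
  # nothing above threshold: CA = 0, MP flagged
  sm0 <- summarize_pressure(g, threshold_kpa = 2)
  expect_equal(sm0$ca_mm2, 0)
  expect_true(is.na(sm0$mp_kpa))
})

test_that("contact area is non-increasing in threshold; peak is threshold-free", {
  set.seed(5)
  m <- matrix(stats::rexp(48 * 48, rate = 0.5), 48, 48)
  g <- pressure_grid(m)
  thr <- seq(0, 5, by = 0.5)
  cas <- vapply(thr, function(t) summarize_pressure(g, t)$ca_mm2, numeric(1))
  expect_true(all(diff(cas) <= 0))
  pps <- vapply(thr, function(t) summarize_pressure(g, t)$pp_kpa, numeric(1))
  expect_true(all(pps == pps[1]))
})

test_that("profiles sum rows/columns and conserve the grid total", {
  g <- pressure_grid(matrix(c(1, 3, 2, 4), 2, 2))  # [[1,2],[3,4]] row-major
  pr <- pressure_profiles(g)
  expect_equal(pr$soc, c(3, 7))
  expect_equal(pr$sor, c(4, 6))
  set.seed(3)
  m <- matrix(stats::runif(100), 10, 10)
  pr2 <- pressure_profiles(pressure_grid(m))
  expect_equal(sum(pr2$soc), sum(m))
  expect_equal(sum(pr2$sor), sum(m))
})

test_that("region partition matches the enumeration oracle", {
  soc <- c(0, 1, 4, 2, 2, 1, 0)
  part <- partition_regions(soc, threshold = 0)
  expect_equal(part$x_beg, 2L)
  expect_equal(part$x_max, 3L)
  expect_equal(part$x_end, 6L)
  # midpoint of (3, 6) is 4.5: the tie resolves toward x_end
  expect_equal(part$x_mid1, 5L)
  expect_equal(part$x_mid2, 6L)
  props <- oracle_region_props(soc, part$x_beg, part$x_max, part$x_mid1,
                               part$x_mid2, part$x_end)
  expect_equal(c(part$p_i, part$p_ii, part$p_iii, part$p_iv), props)
  expect_equal(sum(props), 100)
})

test_that("degenerate partitions assign all mass and flag zero-width regions", {
  soc <- c(0, 0, 5, 0, 0)
  part <- partition_regions(soc, threshold = 0)
  expect_equal(part$x_beg, 3L)
  expect_equal(part$x_end, 3L)
  expect_equal(part$p_iv, 100)
  expect_true(all(part$degenerate[c("i", "ii", "iii")]))
  expect_error(partition_regions(c(0, 0, 0)), "threshold")
})

test_that("partition proportions always sum to 100 on random profiles", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    soc <- stats::rexp(n) * stats::rbinom(n, 1, 0.8)
    if (all(soc == 0)) soc[5] <- 1
    p <- partition_regions(soc, threshold = 0)
    expect_equal(p$p_i + p$p_ii + p$p_iii + p$p_iv, 100, tolerance = 0.1)
    expect_true(p$x_beg <= p$x_max && p$x_max <= p$x_mid1 &&
                  p$x_mid1 <= p$x_mid2 && p$x_mid2 <= p$x_end)
  }
})

test_that("published force/area pairs reproduce the published mean pressures", {
  pp <- reference_pressure_params()
  fl <- reference_forces_local()
  exp_rows <- pp[pp$source == "Exp", ]
  mps <- mean_pressure_kpa(
    abs(fl$fz[fl$source == "Exp" & fl$surface == "SP"]), exp_rows$ca_sp)
  expect_equal(mps, exp_rows$mp_sp, tolerance = 0.013)  # 0.05 kPa absolute
  expect_lt(max(abs(mps - exp_rows$mp_sp)), 0.05)
})

test_that("pressure grids round-trip through CSV with sidecar metadata", {
  set.seed(8)
  g <- pressure_grid(matrix(stats::runif(36), 6, 6), pitch_mm = 10, surface = "SB")
  tf <- tempfile(fileext = ".csv")
  write_pressure_grid(g, tf)
  back <- read_pressure_grid(tf)
  expect_equal(back$values, g$values, tolerance = 1e-12)
  expect_equal(back$pitch_mm, 10)
  expect_equal(back$surface, "SB")
})
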