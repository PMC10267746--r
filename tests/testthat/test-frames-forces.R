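test_that("surface tilt angles follow the seat geometry", {
  expect_equal(surface_tilt_angle(seat_config(5, 100, 784.8), "SB"), 15)
  expect_equal(surface_tilt_angle(seat_config(0, 100, 784.8), "SP"), 0)
  expect_equal(surface_tilt_angle(seat_config(15, 100, 784.8), "SB"), 25)
  expect_equal(surface_tilt_angle(seat_config(10, 100, 784.8), "FS"), 0)
  expect_error(surface_tilt_angle(seat_config(5, 100, 784.8), "XX"),
               "unknown surface")
})

test_that("seat_config rejects out-of-range geometry and weight", {
  expect_error(seat_config(-1, 100, 700), "spa_deg")
  expect_error(seat_config(5, 90, 700), "sp2ba_deg")
  expect_error(seat_config(5, 100, 0), "body_weight_N")
})

test_that("global-to-local rotation preserves norm and inverts exactly", {
  set.seed(42)
  for (i in 1:50) {
    f <- planar_force(stats::runif(1, -500, 500), stats::runif(1, -800, 0), "SP")
    a <- stats::runif(1, -60, 60)
    g <- rotate_global_to_local(f, a)
    expect_equal(g$fx^2 + g$fz^2, f$fx^2 + f$fz^2, tolerance = 1e-12)
    back <- rotate_local_to_global(g, a)
    expect_equal(back$fx, f$fx, tolerance = 1e-12)
    expect_equal(back$fz, f$fz, tolerance = 1e-12)
  }
  expect_error(rotate_global_to_local(
    planar_force(1, 1, "SP", frame = "local"), 5), "already")
  # zero-angle identity
  id <- rotate_global_to_local(planar_force(3.2, -7.5, "SB"), 0)
  expect_equal(c(id$fx, id$fz), c(3.2, -7.5))
})

test_that("rotating every bundled global force row reproduces the published local values", {
  glob <- reference_forces_global()
  loc <- reference_forces_local()
  conds <- reference_conditions()
  for (i in seq_len(nrow(loc))) {
    row <- loc[i, ]
    g <- glob[glob$condition == row$condition & glob$source == row$source &
                glob$surface == row$surface, ]
    ang <- surface_tilt_angle(conds[[row$condition]], row$surface)
    rl <- rotate_global_to_local(planar_force(g$fx, g$fz, g$surface), ang)
    expect_lt(abs(rl$fx - row$fx), 0.15)
    expect_lt(abs(rl$fz - row$fz), 0.15)
  }
})

test_that("force balance reproduces the published residuals and rejects bad input", {
  cfg <- reference_conditions()$SPA0
  g <- reference_forces_global()
  sub <- g[g$condition == "SPA0" & g$source == "Exp", ]
  forces <- lapply(seq_len(nrow(sub)), function(i)
    planar_force(sub$fx[i], sub$fz[i], sub$surface[i]))
  bal <- force_balance(forces, cfg)
  expect_equal(bal$abs_fx, 6.7, tolerance = 1e-9)
  expect_equal(bal$sum_fz, -10.2, tolerance = 1e-9)

  zero <- lapply(c("SB", "SP", "FS"), function(s) planar_force(0, 0, s))
  cfg0 <- seat_config(0, 100, body_weight_N = 1e-12)
  bal0 <- force_balance(zero, cfg0)
  expect_equal(bal0$sum_fx, 0)
  expect_equal(bal0$sum_fz, 0, tolerance = 1e-9)

  expect_error(force_balance(forces[1:2], cfg), "missing")
  expect_error(force_balance(list(forces[[1]], forces[[1]], forces[[2]]), cfg),
               "missing|duplicated")
})

test_that("comparison statistics match hand arithmetic and the identity case", {
  sim <- tibble::tibble(condition = c("A", "B"), q1 = c(10, 20), q2 = c(-5, 5))
  exp_t <- tibble::tibble(condition = c("A", "B"), q1 = c(8, 26), q2 = c(-5, 0))
  cmp <- compare_conditions(sim, exp_t)
  expect_equal(cmp$d$q1, c(2, -6))
  expect_equal(cmp$all$mean_d[cmp$all$quantity == "q1"], -2)
  expect_equal(cmp$d_pct$q1, c(100 * 2 / 8, 100 * -6 / 26))
  expect_true(is.na(cmp$d_pct$q2[2]))  # Exp = 0 flagged undefined

  same <- compare_conditions(sim, sim)
  expect_true(all(same$d$q1 == 0) && all(same$d$q2 == 0))
  expect_true(all(same$all$mean_d == 0))

  bad <- exp_t; bad$condition <- c("A", "C")
  expect_error(compare_conditions(sim, bad), "labels differ")
})

test_that("bundled force tables reproduce the published All-row mean differences", {
  study <- study_config()
  res <- run_forces(study)
  all_d <- res$comparison$all
  get <- function(q) all_d$mean_d[all_d$quantity == q]
  expect_equal(get("fx_sb_g"), -22.3, tolerance = 0.05)
  expect_equal(get("fz_sb_g"), 16.6, tolerance = 0.05)
  expect_equal(get("fx_sp_g"), 20.5, tolerance = 0.05)
  expect_equal(get("fz_sp_g"), -15.5, tolerance = 0.05)
  expect_equal(get("fx_fs_g"), 6.3, tolerance = 0.05)
  expect_equal(get("fz_fs_g"), 3.0, tolerance = 0.05)
})

test_that("force CSV round-trips and normalises unicode minus", {
  tab <- reference_forces_global()
  tf <- tempfile(fileext = ".csv")
  write_force_table(tab, tf)
  back <- read_force_table(tf)
  expect_equal(back$fx, tab$fx)

  tf2 <- tempfile(fileext = ".csv")
  writeLines(c("condition,surface,frame,fx,fz",
               "SPA0,SP,global,−73.5,−697.0"), tf2, useBytes = FALSE)
  u <- read_force_table(tf2)
  expect_equal(u$fx, -73.5)
  expect_equal(u$fz, -697)
})
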