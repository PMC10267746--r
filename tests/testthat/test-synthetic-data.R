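test_that("synthetic pressure maps round-trip the calibration error through fcorr", {
  rec <- map_recipe(calibration_error = 1.4, noise_cv = 0, seed = 3)
  gm <- gen_pressure_map(rec)
  fc <- correction_factor(gm$grid, rec$target_force_N)
  expect_equal(fc, 1.4, tolerance = 1e-6)
  # corrected grid integrates to the target force exactly
  corr <- apply_correction(gm$grid, fc)
  expect_equal(sum(corr$values) * 12.7^2 * 1e-3, rec$target_force_N,
               tolerance = 1e-9)
})

test_that("synthetic maps are bit-identical per seed and differ across seeds", {
  a <- gen_pressure_map(map_recipe(seed = 7))
  b <- gen_pressure_map(map_recipe(seed = 7))
  c <- gen_pressure_map(map_recipe(seed = 8))
  expect_identical(a$grid$values, b$grid$values)
  expect_false(identical(a$grid$values, c$grid$values))
})

test_that("generator ground truth agrees with the pressure metrics", {
  rec <- map_recipe(calibration_error = 1.2, noise_cv = 0, seed = 5)
  gm <- gen_pressure_map(rec)
  sm <- summarize_pressure(gm$grid, threshold_kpa = 0.1,
                           normal_force_N = rec$target_force_N)
  expect_lte(abs(sm$ca_mm2 - gm$truth$ca_mm2), 12.7^2)  # within one cell
  expect_equal(sm$pp_kpa, gm$truth$pp_kpa, tolerance = 1e-9)
  # SOC peak row equals the generator's IT row
  soc <- pressure_profiles(gm$grid)$soc
  expect_equal(which.max(soc), gm$truth$peak_row)
  # with the thigh ridge disabled, the partition ends at the last IT-active row
  rec2 <- map_recipe(thigh_ridge = NULL, calibration_error = 1, noise_cv = 0,
                     seed = 5)
  gm2 <- gen_pressure_map(rec2)
  part <- partition_regions(pressure_profiles(gm2$grid)$soc, threshold = 0)
  active_rows <- which(rowSums(gm2$grid$values) > 0)
  expect_equal(part$x_end, max(active_rows))
  expect_equal(part$x_max, gm2$truth$peak_row)
})

test_that("noiseless synthetic force sets balance exactly", {
  for (spa in c(0, 5, 10, 15)) {
    cfg <- seat_config(spa, 100, 784.8)
    fs <- gen_force_set(cfg, noise_sd_N = 5, seed = 11)
    forces <- lapply(1:3, function(i)
      planar_force(fs$noiseless$fx[i], fs$noiseless$fz[i],
                   fs$noiseless$surface[i]))
    bal <- force_balance(forces, cfg)
    expect_lt(bal$abs_fx, 1e-9)
    expect_lt(bal$abs_fz, 1e-9)
  }
  expect_error(gen_force_set(seat_config(5, 100, 784.8),
                             load_split = c(SB = 0.5, SP = 0.6, FS = -0.1)),
               "infeasible")
})

test_that("measurement noise leaves residuals small in almost all seeds", {
  cfg <- seat_config(5, 100, 784.8)
  n_ok <- 0; n <- 400
  for (s in seq_len(n)) {
    fs <- gen_force_set(cfg, noise_sd_N = 5, seed = s)
    forces <- lapply(1:3, function(i)
      planar_force(fs$exp$fx[i], fs$exp$fz[i], fs$exp$surface[i]))
    bal <- force_balance(forces, cfg)
    if (bal$abs_fx < 25 && bal$abs_fz < 25) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n, 0.98)
})

test_that("flat frictionless configuration produces no shear", {
  cfg <- seat_config(0, 90 + 1e-9, 784.8, cof_seat = 0, cof_foot = 0)
  fs <- gen_force_set(cfg, noise_sd_N = 0, seed = 1)
  expect_true(all(abs(fs$noiseless$fx) < 1e-6))
})

test_that("tissue pairs compress to the series-equilibrium stretch", {
  model <- column_model(sliding_fraction = 0)
  pair <- gen_tissue_pair(model, mesh_density_mm = 10, seed = 2)
  roi <- build_roi(pair$ischium_point, c(0, 0, 1), 20)
  r <- volume_reduction(pair$pre, pair$post, roi, ray_grid_mm = 1)
  expect_equal(r, (1 - pair$lambda) * 100, tolerance = 0.5)
  # the stretch itself solves the flesh law at the applied stress
  expect_equal(ogden_uniaxial_stress(model$flesh, pair$lambda),
               -model$applied_stress_kpa, tolerance = 1e-9)
  expect_equal(foam_loading_stress(model$foam, pair$foam_strain),
               model$applied_stress_kpa, tolerance = 1e-6)
})

test_that("zero applied stress leaves the mesh unloaded", {
  pair <- gen_tissue_pair(column_model(applied_stress_kpa = 0),
                          mesh_density_mm = 10)
  expect_equal(pair$post$nodes, pair$pre$nodes, tolerance = 1e-12)
  roi <- build_roi(pair$ischium_point, c(0, 0, 1), 20)
  expect_equal(volume_reduction(pair$pre, pair$post, roi, 1), 0)
})

test_that("sliding increases volume reduction in both ROIs at equal stress", {
  p0 <- gen_tissue_pair(column_model(sliding_fraction = 0), mesh_density_mm = 10)
  p1 <- gen_tissue_pair(column_model(sliding_fraction = 0.5), mesh_density_mm = 10)
  for (d in c(20, 50)) {
    roi <- build_roi(p0$ischium_point, c(0, 0, 1), d)
    r0 <- volume_reduction(p0$pre, p0$post, roi, 1)
    r1 <- volume_reduction(p1$pre, p1$post, roi, 1)
    expect_gt(r1, r0)
  }
})

test_that("tissue generation is deterministic and validates mesh density", {
  a <- gen_tissue_pair(column_model(), mesh_density_mm = 10, seed = 4)
  b <- gen_tissue_pair(column_model(), mesh_density_mm = 10, seed = 4)
  expect_identical(a$post$nodes, b$post$nodes)
  expect_error(gen_tissue_pair(column_model(), mesh_density_mm = 20),
               "mesh_density_mm")
  expect_error(gen_tissue_pair(column_model(applied_stress_kpa = 1e5),
                               mesh_density_mm = 10), "equilibrium|exceeds")
})
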