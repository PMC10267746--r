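test_that("ROI construction places the upper face at the ischium point", {
  p <- c(12.3, -4.5, 38.2)
  roi <- build_roi(p, c(0, 0, 1), 20)
  expect_equal(roi$apex, p)
  expect_equal(roi$axis, c(0, 0, 1))
  # tilted seat normal (SPA 15): apex lies in the top-face plane by construction
  n <- c(sin(15 * pi / 180), 0, cos(15 * pi / 180))
  roi_t <- build_roi(p, 2 * n, 50)  # non-unit input normalised
  expect_equal(sqrt(sum(roi_t$axis^2)), 1, tolerance = 1e-12)
  expect_equal(sum((p - roi_t$apex) * roi_t$axis), 0, tolerance = 1e-9)
  expect_error(build_roi(p, c(0, 0, 0), 20), "non-zero")
  expect_error(build_roi(p, c(0, 0, 1), -5), "diameter")
})

test_that("mean thickness of slabs is exact and scales with compression", {
  slab <- slab_mesh(40)
  roi <- build_roi(c(0, 0, 40), c(0, 0, 1), 20)
  expect_equal(mean_thickness(slab, roi), 40, tolerance = 1e-9)
  half <- transform_mesh(slab, function(p) cbind(p[, 1], p[, 2], p[, 3] * 0.5))
  roi_h <- build_roi(c(0, 0, 20), c(0, 0, 1), 20)
  expect_equal(mean_thickness(half, roi_h), 20, tolerance = 1e-9)
})

test_that("wedge thickness matches the analytic mean of a linear field", {
  # thickness t(x) = 30 + 0.2 x: shear the top face of a slab
  wedge <- transform_mesh(slab_mesh(30), function(p)
    cbind(p[, 1], p[, 2], p[, 3] * (30 + 0.2 * p[, 1]) / 30))
  roi <- build_roi(c(10, 0, 60), c(0, 0, 1), 50, height_mm = 100)
  t_num <- mean_thickness(wedge, roi, ray_grid_mm = 1)
  t_ana <- 30 + 0.2 * 10  # mean of a linear field over a disk centred at x = 10
  expect_equal(t_num, t_ana, tolerance = t_ana * 0.01)
})

test_that("ROI volume matches the analytic cylinder and converges under refinement", {
  slab <- slab_mesh(40)
  for (d in c(20, 50)) {
    roi <- build_roi(c(0, 0, 40), c(0, 0, 1), d)
    v <- roi_volume(slab, roi, ray_grid_mm = 0.5)
    v_ana <- pi * (d / 2)^2 * 40
    expect_lt(abs(v - v_ana) / v_ana, 0.01)
  }
  roi <- build_roi(c(0, 0, 40), c(0, 0, 1), 20)
  v1 <- roi_volume(slab, roi, ray_grid_mm = 1)
  v2 <- roi_volume(slab, roi, ray_grid_mm = 0.5)
  expect_lt(abs(v2 - v1) / v2, 0.005)
  # empty intersection
  far <- build_roi(c(500, 500, 40), c(0, 0, 1), 20)
  expect_equal(roi_volume(slab, far), 0)
  expect_true(is.na(mean_thickness(slab, far)))
})

test_that("thickness and volume are mutually consistent and ROIs nest", {
  pair <- gen_tissue_pair(column_model(sliding_fraction = 0.5),
                          mesh_density_mm = 10)
  for (mesh in list(pair$pre, pair$post)) {
    st <- roi_ray_stats(mesh, build_roi(pair$ischium_point, c(0, 0, 1), 50), 1)
    v <- sum(st$chord) * st$cell_area_mm2
    t_mean <- mean(st$chord[st$chord > 0])
    expect_lt(abs(v - t_mean * st$n_hit * st$cell_area_mm2) / v, 1e-6)
    v20 <- roi_volume(mesh, build_roi(pair$ischium_point, c(0, 0, 1), 20), 1)
    expect_gte(v, v20)
  }
})

test_that("volume reduction is zero for identical meshes and exact for uniform compression", {
  slab <- slab_mesh(40)
  roi <- build_roi(c(0, 0, 40), c(0, 0, 1), 20)
  expect_equal(volume_reduction(slab, slab, roi), 0)
  for (lam in c(0.4, 0.55, 0.75)) {
    post <- transform_mesh(slab, function(p) cbind(p[, 1], p[, 2], p[, 3] * lam))
    r <- volume_reduction(slab, post, roi)
    expect_equal(r, (1 - lam) * 100, tolerance = 0.5)
  }
  empty <- transform_mesh(slab, function(p) cbind(p[, 1] + 1000, p[, 2], p[, 3]))
  expect_error(volume_reduction(empty, slab, roi), "zero")
})

test_that("R is invariant under a rigid transform applied jointly to meshes and ROI", {
  slab <- slab_mesh(40)
  post <- transform_mesh(slab, function(p) cbind(p[, 1], p[, 2], p[, 3] * 0.6))
  roi <- build_roi(c(0, 0, 40), c(0, 0, 1), 20)
  r0 <- volume_reduction(slab, post, roi)
  th <- 25 * pi / 180
  Q <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  shift <- c(15, -40, 7)
  rigid <- function(p) sweep(p %*% t(Q), 2, shift, `+`)
  roi_r <- build_roi(as.numeric(rigid(matrix(roi$apex, 1))),
                     as.numeric(Q %*% roi$axis), 20)
  r1 <- volume_reduction(transform_mesh(slab, rigid),
                         transform_mesh(post, rigid), roi_r)
  expect_equal(r1, r0, tolerance = 1e-9)
})

test_that("meshes round-trip through legacy VTK with boundary tags", {
  pair <- gen_tissue_pair(column_model(), mesh_density_mm = 10)
  tf <- tempfile(fileext = ".vtk")
  write_vtk_ugrid(pair$pre, tf)
  back <- read_vtk_ugrid(tf)
  expect_equal(back$nodes, pair$pre$nodes, tolerance = 1e-6)
  expect_equal(back$skin, pair$pre$skin)
  expect_equal(back$bone, pair$pre$bone)
  expect_equal(length(back$cells), length(pair$pre$cells))
  expect_true(all(cell_volumes(back) > 0))
  expect_error(suppressWarnings(read_vtk_ugrid(tempfile())), "cannot open|No such")
})
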