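#' Cylinder region of interest under the ischial tuberosity
#'
#' A cylinder of given diameter whose axis is perpendicular to the seat-pan
#' plane and passes through the ischium point closest to the seat; the
#' cylinder's upper face plane contains that point and the body extends
#' seat-ward by `height_mm`, so the ROI samples the tissue column between the
#' ischium and the seat.
#'
#' @param apex Length-3 ischium point (mm).
#' @param axis Length-3 seat-plane normal (need not be unit; must be
#'   non-zero). Stored normalised, pointing from the seat toward the body.
#' @param diameter_mm Cylinder diameter, typically 20 or 50.
#' @param height_mm Sampling extent toward the seat (default 200, enough to
#'   cover any tissue column).
#' @return A `cylinder_roi` object.
#' @export
cylinder_roi <- function(apex, axis, diameter_mm, height_mm = 200) {
  apex <- as.numeric(apex); axis <- as.numeric(axis)
  stopifnot(length(apex) == 3, length(axis) == 3, all(is.finite(apex)),
            all(is.finite(axis)))
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("`axis` must be a non-zero seat normal")
  if (!is.finite(diameter_mm) || diameter_mm <= 0) stop("`diameter_mm` must be > 0")
  if (height_mm <= 0) stop("`height_mm` must be > 0")
  structure(list(apex = apex, axis = axis / nrm, diameter_mm = diameter_mm,
                 height_mm = height_mm),
            class = "cylinder_roi")
}

#' @rdname cylinder_roi
#' @param ischium_point,seat_normal Aliases of `apex` and `axis` in the
#'   construction-from-landmark reading.
#' @export
build_roi <- function(ischium_point, seat_normal, diameter_mm,
                      height_mm = 200) {
  cylinder_roi(ischium_point, seat_normal, diameter_mm, height_mm)
}

#' @export
print.cylinder_roi <- function(x, ...) {
  cat(sprintf("<cylinder_roi>  d = %g mm, h = %g mm, apex (%.1f, %.1f, %.1f), axis (%.2f, %.2f, %.2f)\n",
              x$diameter_mm, x$height_mm, x$apex[1], x$apex[2], x$apex[3],
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

# orthonormal basis with e3 = axis (deterministic)
axis_basis <- function(axis) {
  e3 <- axis / sqrt(sum(axis^2))
  ref <- if (abs(e3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * e3) * e3
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  cbind(e1, e2, e3)
}

# For one tagged triangle soup, accumulate axis-parallel ray intersections.
# xy: local node coords; rays on a regular grid xs x ys (full square).
# Returns list(ray = integer ids, z = heights).
ray_hits <- function(nodes_local, tris, xs, ys) {
  nx <- length(xs); h <- xs[2] - xs[1]
  ray_ids <- integer(0); zs <- numeric(0)
  ax <- nodes_local[tris[, 1], 1]; ay <- nodes_local[tris[, 1], 2]; az <- nodes_local[tris[, 1], 3]
  bx <- nodes_local[tris[, 2], 1]; by <- nodes_local[tris[, 2], 2]; bz <- nodes_local[tris[, 2], 3]
  cx <- nodes_local[tris[, 3], 1]; cy <- nodes_local[tris[, 3], 2]; cz <- nodes_local[tris[, 3], 3]
  det <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
  x0 <- xs[1]; y0 <- ys[1]
  for (t in seq_len(nrow(tris))) {
    if (abs(det[t]) < 1e-12) next  # vertical (edge-on) triangle
    txmin <- min(ax[t], bx[t], cx[t]); txmax <- max(ax[t], bx[t], cx[t])
    tymin <- min(ay[t], by[t], cy[t]); tymax <- max(ay[t], by[t], cy[t])
    i1 <- max(1L, ceiling((txmin - x0) / h) + 1L)
    i2 <- min(nx, floor((txmax - x0) / h) + 1L)
    if (i1 > i2) next
    j1 <- max(1L, ceiling((tymin - y0) / h) + 1L)
    j2 <- min(length(ys), floor((tymax - y0) / h) + 1L)
    if (j1 > j2) next
    gx <- xs[i1:i2]; gy <- ys[j1:j2]
    px <- rep(gx, times = length(gy)); py <- rep(gy, each = length(gx))
    inv <- 1 / det[t]
    u <- ((px - ax[t]) * (cy[t] - ay[t]) - (cx[t] - ax[t]) * (py - ay[t])) * inv
    v <- ((bx[t] - ax[t]) * (py - ay[t]) - (px - ax[t]) * (by[t] - ay[t])) * inv
    eps <- 1e-9
    hit <- u >= -eps & v >= -eps & (u + v) <= 1 + eps
    if (!any(hit)) next
    zhit <- az[t] + u[hit] * (bz[t] - az[t]) + v[hit] * (cz[t] - az[t])
    ii <- rep(i1:i2, times = length(gy))[hit]
    jj <- rep(j1:j2, each = length(gx))[hit]
    ray_ids <- c(ray_ids, (jj - 1L) * nx + ii)
    zs <- c(zs, zhit)
  }
  list(ray = ray_ids, z = zs)
}

# sorted crossing heights -> "inside" intervals; dedupes coincident
# crossings (shared coplanar edges) and drops an unpaired trailing crossing
crossings_to_intervals <- function(z, tol = 1e-7) {
  z <- sort(z)
  if (length(z) > 1) z <- z[c(TRUE, diff(z) > tol)]
  if (length(z) %% 2 == 1) z <- z[-length(z)]
  if (!length(z)) return(matrix(numeric(0), ncol = 2))
  matrix(z, ncol = 2, byrow = TRUE)
}

# total length of intervals a minus intervals b, clipped to [lo, hi]
interval_diff_length <- function(a, b, lo, hi) {
  if (!nrow(a)) return(0)
  total <- 0
  for (r in seq_len(nrow(a))) {
    s <- max(a[r, 1], lo); e <- min(a[r, 2], hi)
    if (e <= s) next
    len <- e - s
    if (!is.null(b) && nrow(b)) for (q in seq_len(nrow(b))) {
      os <- max(s, b[q, 1]); oe <- min(e, b[q, 2])
      if (oe > os) len <- len - (oe - os)
    }
    total <- total + max(len, 0)
  }
  total
}

#' Per-ray chord lengths of tissue inside a cylinder ROI
#'
#' Casts rays parallel to the ROI axis on a square grid over the cylinder
#' cross-section (cells whose centres lie inside the circle). Each ray's
#' chord is the total length inside the skin boundary and outside the bone
#' boundary, clipped to the cylinder extent. This is the shared kernel of
#' [mean_thickness()] and [roi_volume()], which are therefore mutually
#' consistent (`v = t_mean * hit area` by construction).
#'
#' @param mesh A [soft_tissue_mesh()].
#' @param roi A [cylinder_roi()].
#' @param ray_grid_mm Ray-grid spacing (mm, default 0.5).
#' @return A list: `chord` (per-ray chords, mm), `cell_area_mm2`, `n_rays`,
#'   `n_hit`.
#' @export
roi_ray_stats <- function(mesh, roi, ray_grid_mm = 0.5) {
  stopifnot(inherits(mesh, "soft_tissue_mesh"), inherits(roi, "cylinder_roi"))
  if (!is.finite(ray_grid_mm) || ray_grid_mm <= 0)
    stop("`ray_grid_mm` must be > 0")
  R <- axis_basis(roi$axis)
  local <- sweep(mesh$nodes, 2, roi$apex) %*% R
  r <- roi$diameter_mm / 2
  h <- ray_grid_mm
  m <- floor((r - h / 2) / h)
  xs <- seq(-m, m, by = 1) * h  # cell centres, symmetric about the axis
  ys <- xs
  nx <- length(xs)
  cx <- rep(xs, times = length(ys)); cy <- rep(ys, each = nx)
  in_circle <- (cx^2 + cy^2) <= r^2

  chord <- numeric(nx * nx)
  skin_hits <- ray_hits(local, mesh$skin, xs, ys)
  bone_hits <- if (!is.null(mesh$bone)) ray_hits(local, mesh$bone, xs, ys) else NULL
  lo <- -roi$height_mm; hi <- 0

  skin_by_ray <- split(skin_hits$z, skin_hits$ray)
  bone_by_ray <- if (is.null(bone_hits)) list() else split(bone_hits$z, bone_hits$ray)
  for (key in names(skin_by_ray)) {
    id <- as.integer(key)
    if (!in_circle[id]) next
    a <- crossings_to_intervals(skin_by_ray[[key]])
    b <- if (!is.null(bone_by_ray[[key]])) crossings_to_intervals(bone_by_ray[[key]]) else NULL
    chord[id] <- interval_diff_length(a, b, lo, hi)
  }
  chord <- chord[in_circle]
  list(chord = chord, cell_area_mm2 = h^2, n_rays = sum(in_circle),
       n_hit = sum(chord > 0))
}

#' Mean soft-tissue thickness along the ROI axis
#'
#' Average chord length over the rays that hit tissue ([roi_ray_stats()]).
#'
#' @inheritParams roi_ray_stats
#' @return Mean thickness in mm; `NA` (flagged) when no ray intersects
#'   tissue.
#' @export
mean_thickness <- function(mesh, roi, ray_grid_mm = 0.5) {
  st <- roi_ray_stats(mesh, roi, ray_grid_mm)
  if (st$n_hit == 0) return(NA_real_)
  mean(st$chord[st$chord > 0])
}

#' Tissue volume inside the ROI cylinder
#'
#' Per-ray chord length times ray-cell area, summed over the grid.
#'
#' @inheritParams roi_ray_stats
#' @return Volume in mm^3 (0 for an empty intersection).
#' @export
roi_volume <- function(mesh, roi, ray_grid_mm = 0.5) {
  st <- roi_ray_stats(mesh, roi, ray_grid_mm)
  sum(st$chord) * st$cell_area_mm2
}

#' Tissue volume reduction between unloaded and loaded states
#'
#' `R = (1 - V_loaded / V_preload) * 100` with both volumes measured inside
#' the same ROI cylinder, frozen in the seat frame and applied identically to
#' the two states.
#'
#' @param pre,post Unloaded / loaded [soft_tissue_mesh()] states.
#' @inheritParams roi_ray_stats
#' @return Volume reduction in percent.
#' @export
volume_reduction <- function(pre, post, roi, ray_grid_mm = 0.5) {
  v_pre <- roi_volume(pre, roi, ray_grid_mm)
  if (v_pre <= 0) stop("pre-load ROI volume is zero: R undefined")
  v_post <- roi_volume(post, roi, ray_grid_mm)
  (1 - v_post / v_pre) * 100
}
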