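#' Volumetric soft-tissue mesh with tagged boundary surfaces
#'
#' Container for a tissue mesh in mm: a node array, volume cells
#' (hexahedra and/or tetrahedra, VTK node ordering), and closed triangulated
#' boundary surfaces tagged `skin` (outer tissue envelope) and `bone`
#' (excluded bone region; may be absent). Tissue membership along a ray is
#' "inside skin and outside bone".
#'
#' @param nodes Numeric `n x 3` matrix of coordinates (mm).
#' @param cells List of integer vectors (1-based node indices): length 8 for
#'   hexahedra, 4 for tetrahedra. May be empty when only boundary surfaces
#'   matter.
#' @param skin,bone Integer `m x 3` triangle matrices (1-based node indices)
#'   describing closed boundary surfaces; `bone` may be `NULL`.
#' @param check_volumes Validate positive volume of every volume cell
#'   (default `TRUE`).
#' @return A `soft_tissue_mesh` object.
#' @export
soft_tissue_mesh <- function(nodes, cells = list(), skin, bone = NULL,
                             check_volumes = TRUE) {
  nodes <- as.matrix(nodes)
  stopifnot(is.numeric(nodes), ncol(nodes) == 3, all(is.finite(nodes)))
  n <- nrow(nodes)
  chk_idx <- function(idx) all(idx >= 1L & idx <= n)
  for (c in cells) {
    if (!length(c) %in% c(4L, 8L)) stop("volume cells must have 4 or 8 nodes")
    if (!chk_idx(c)) stop("cell node index out of range")
  }
  skin <- as.matrix(skin)
  if (ncol(skin) != 3 || !chk_idx(skin)) stop("`skin` must be an m x 3 index matrix")
  if (!is.null(bone)) {
    bone <- as.matrix(bone)
    if (ncol(bone) != 3 || !chk_idx(bone)) stop("`bone` must be an m x 3 index matrix")
  }
  mesh <- structure(list(nodes = nodes, cells = cells, skin = skin, bone = bone),
                    class = "soft_tissue_mesh")
  if (check_volumes && length(cells)) {
    v <- cell_volumes(mesh)
    if (any(v <= 0)) stop(sum(v <= 0), " volume cell(s) have non-positive volume")
  }
  mesh
}

#' @export
print.soft_tissue_mesh <- function(x, ...) {
  cat(sprintf("<soft_tissue_mesh>  %d nodes, %d volume cells, %d skin tris%s\n",
              nrow(x$nodes), length(x$cells), nrow(x$skin),
              if (is.null(x$bone)) "" else sprintf(", %d bone tris", nrow(x$bone))))
  invisible(x)
}

tet_volume <- function(a, b, c, d) {
  det(rbind(b - a, c - a, d - a)) / 6
}

#' Volumes of the mesh's volume cells
#'
#' Tetrahedra directly; hexahedra by decomposition into six tetrahedra
#' (consistent with VTK node ordering: 1-4 bottom face, 5-8 top face).
#'
#' @param mesh A [soft_tissue_mesh()].
#' @return Numeric vector of volumes (mm^3).
#' @export
cell_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "soft_tissue_mesh"))
  vapply(mesh$cells, function(c) {
    p <- mesh$nodes
    if (length(c) == 4L) return(abs(tet_volume(p[c[1], ], p[c[2], ], p[c[3], ], p[c[4], ])))
    # hex -> 6 tets sharing the diagonal 1-7
    tets <- list(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                 c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
    sum(vapply(tets, function(t)
      tet_volume(p[c[t[1]], ], p[c[t[2]], ], p[c[t[3]], ], p[c[t[4]], ]),
      numeric(1)))
  }, numeric(1))
}

#' Apply a coordinate transform to a mesh
#'
#' @param mesh A [soft_tissue_mesh()].
#' @param f Function mapping an `n x 3` coordinate matrix to an `n x 3`
#'   matrix (e.g. a displacement field or a rigid transform).
#' @return The transformed mesh (connectivity unchanged).
#' @export
transform_mesh <- function(mesh, f) {
  stopifnot(inherits(mesh, "soft_tissue_mesh"))
  mesh$nodes <- f(mesh$nodes)
  stopifnot(is.matrix(mesh$nodes), ncol(mesh$nodes) == 3)
  dimnames(mesh$nodes) <- NULL
  mesh
}

#' Axis-aligned hexahedral block mesh
#'
#' Regular hex block spanning `[x0, x0+lx] x [y0, y0+ly] x [z0, z0+lz]` with
#' target element size `h`; the outer surface is triangulated and tagged as
#' skin.
#'
#' @param lx,ly,lz Edge lengths (mm).
#' @param h Target element size (mm).
#' @param origin Length-3 lower corner (default centred in x/y, base at z=0).
#' @return A [soft_tissue_mesh()] without a bone surface.
#' @export
hex_block_mesh <- function(lx, ly, lz, h = 5,
                           origin = c(-lx / 2, -ly / 2, 0)) {
  nx <- max(1L, round(lx / h)); ny <- max(1L, round(ly / h))
  nz <- max(1L, round(lz / h))
  xs <- seq(origin[1], origin[1] + lx, length.out = nx + 1)
  ys <- seq(origin[2], origin[2] + ly, length.out = ny + 1)
  zs <- seq(origin[3], origin[3] + lz, length.out = nz + 1)
  nid <- function(i, j, k) ((k - 1L) * (ny + 1L) + (j - 1L)) * (nx + 1L) + i
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL

  cells <- vector("list", nx * ny * nz)
  idx <- 1L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    cells[[idx]] <- c(nid(i, j, k), nid(i + 1L, j, k), nid(i + 1L, j + 1L, k),
                      nid(i, j + 1L, k),
                      nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                      nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
    idx <- idx + 1L
  }

  quads <- list()
  add_quad <- function(a, b, c, d) quads[[length(quads) + 1L]] <<- c(a, b, c, d)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    add_quad(nid(i, j, 1L), nid(i + 1L, j, 1L), nid(i + 1L, j + 1L, 1L), nid(i, j + 1L, 1L))
    add_quad(nid(i, j, nz + 1L), nid(i + 1L, j, nz + 1L),
             nid(i + 1L, j + 1L, nz + 1L), nid(i, j + 1L, nz + 1L))
  }
  for (k in seq_len(nz)) for (i in seq_len(nx)) {
    add_quad(nid(i, 1L, k), nid(i + 1L, 1L, k), nid(i + 1L, 1L, k + 1L), nid(i, 1L, k + 1L))
    add_quad(nid(i, ny + 1L, k), nid(i + 1L, ny + 1L, k),
             nid(i + 1L, ny + 1L, k + 1L), nid(i, ny + 1L, k + 1L))
  }
  for (k in seq_len(nz)) for (j in seq_len(ny)) {
    add_quad(nid(1L, j, k), nid(1L, j + 1L, k), nid(1L, j + 1L, k + 1L), nid(1L, j, k + 1L))
    add_quad(nid(nx + 1L, j, k), nid(nx + 1L, j + 1L, k),
             nid(nx + 1L, j + 1L, k + 1L), nid(nx + 1L, j, k + 1L))
  }
  skin <- do.call(rbind, lapply(quads, function(q)
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])))
  soft_tissue_mesh(nodes, cells, skin = skin, check_volumes = FALSE)
}

#' Closed hemispherical surface (flat face down)
#'
#' Triangulated closed surface of a hemisphere of radius `r` whose flat disk
#' face lies in the plane `z = base_z` (centred at `centre_xy`) with the dome
#' rising above it. Used as the idealised ischial bone boundary.
#'
#' @param r Radius (mm).
#' @param base_z Height of the flat face (mm).
#' @param centre_xy Length-2 centre of the flat face.
#' @param n_theta,n_phi Azimuthal / elevation resolution.
#' @return A list `nodes` (`n x 3`) and `tris` (`m x 3`, 1-based, local).
#' @export
hemisphere_surface <- function(r, base_z = 0, centre_xy = c(0, 0),
                               n_theta = 36, n_phi = 9) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ph <- seq(0, pi / 2, length.out = n_phi + 1)  # elevation 0 (rim) to 90 (pole)
  nodes <- list(); tris <- list()
  ring_ids <- matrix(0L, n_phi, n_theta)  # rings below the pole
  id <- 0L
  for (q in seq_len(n_phi)) for (t in seq_len(n_theta)) {
    id <- id + 1L
    nodes[[id]] <- c(centre_xy[1] + r * cos(ph[q]) * cos(th[t]),
                     centre_xy[2] + r * cos(ph[q]) * sin(th[t]),
                     base_z + r * sin(ph[q]))
    ring_ids[q, t] <- id
  }
  pole <- id + 1L
  nodes[[pole]] <- c(centre_xy[1], centre_xy[2], base_z + r)
  centre <- pole + 1L
  nodes[[centre]] <- c(centre_xy[1], centre_xy[2], base_z)
  nxt <- function(t) if (t == n_theta) 1L else t + 1L
  for (q in seq_len(n_phi - 1)) for (t in seq_len(n_theta)) {
    a <- ring_ids[q, t]; b <- ring_ids[q, nxt(t)]
    c2 <- ring_ids[q + 1, nxt(t)]; d <- ring_ids[q + 1, t]
    tris[[length(tris) + 1L]] <- c(a, b, c2)
    tris[[length(tris) + 1L]] <- c(a, c2, d)
  }
  for (t in seq_len(n_theta)) {  # cap to pole
    tris[[length(tris) + 1L]] <- c(ring_ids[n_phi, t], ring_ids[n_phi, nxt(t)], pole)
  }
  for (t in seq_len(n_theta)) {  # flat face fan
    tris[[length(tris) + 1L]] <- c(ring_ids[1, nxt(t)], ring_ids[1, t], centre)
  }
  list(nodes = do.call(rbind, nodes), tris = do.call(rbind, tris))
}

#' Read a legacy VTK ASCII unstructured grid
#'
#' Supports the subset written by [write_vtk_ugrid()]: `POINTS`, `CELLS`,
#' `CELL_TYPES` (hexahedra 12, tetrahedra 10, triangles 5) and `CELL_DATA`
#' integer scalar fields named `skin` and `bone` tagging the boundary
#' triangles.
#'
#' @param path File path.
#' @return A [soft_tissue_mesh()].
#' @export
read_vtk_ugrid <- function(path) {
  lines <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  i_pts <- grep("^POINTS", lines)
  if (!length(i_pts)) stop("not a legacy VTK unstructured grid: ", path)
  n_pts <- as.integer(toks(lines[i_pts])[2])
  num_after <- function(i0, count) {
    vals <- numeric(0); i <- i0
    while (length(vals) < count) {
      i <- i + 1L
      vals <- c(vals, as.numeric(toks(lines[i])))
    }
    list(vals = vals[seq_len(count)], last = i)
  }
  pts <- num_after(i_pts, n_pts * 3)
  nodes <- matrix(pts$vals, ncol = 3, byrow = TRUE)

  i_cells <- grep("^CELLS", lines)[1]
  hdr <- toks(lines[i_cells]); n_cells <- as.integer(hdr[2]); n_ints <- as.integer(hdr[3])
  cl <- num_after(i_cells, n_ints)
  i_types <- grep("^CELL_TYPES", lines)[1]
  ct <- as.integer(num_after(i_types, n_cells)$vals)

  conn <- vector("list", n_cells)
  pos <- 1L
  for (k in seq_len(n_cells)) {
    m <- as.integer(cl$vals[pos])
    conn[[k]] <- as.integer(cl$vals[(pos + 1L):(pos + m)]) + 1L  # 0- to 1-based
    pos <- pos + m + 1L
  }

  read_field <- function(name) {
    i_f <- grep(paste0("^SCALARS\\s+", name, "\\b"), lines)
    if (!length(i_f)) return(NULL)
    as.integer(num_after(i_f + 1L, n_cells)$vals)  # skip LOOKUP_TABLE line
  }
  skin_tag <- read_field("skin"); bone_tag <- read_field("bone")
  is_tri <- ct == 5L
  vols <- conn[!is_tri]
  tri_mat <- if (any(is_tri)) do.call(rbind, conn[is_tri]) else NULL
  pick <- function(tag) {
    if (is.null(tag) || is.null(tri_mat)) return(NULL)
    sel <- tag[is_tri] == 1L
    if (!any(sel)) NULL else tri_mat[sel, , drop = FALSE]
  }
  skin <- pick(skin_tag); bone <- pick(bone_tag)
  if (is.null(skin)) stop("mesh has no triangles tagged `skin`: ", path)
  soft_tissue_mesh(nodes, vols, skin = skin, bone = bone, check_volumes = FALSE)
}

#' Write a mesh as a legacy VTK ASCII unstructured grid
#'
#' Volume cells first, then skin and bone boundary triangles; two integer
#' `CELL_DATA` scalar fields (`skin`, `bone`) tag the triangles.
#'
#' @param mesh A [soft_tissue_mesh()].
#' @param path Output path.
#' @export
write_vtk_ugrid <- function(mesh, path) {
  stopifnot(inherits(mesh, "soft_tissue_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  n <- nrow(mesh$nodes)
  w("# vtk DataFile Version 3.0")
  w("sitpress soft-tissue mesh (mm)")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", n)
  writeLines(apply(mesh$nodes, 1, function(p)
    sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])), con)

  tri_list <- list()
  if (nrow(mesh$skin)) tri_list <- c(tri_list, split(mesh$skin, seq_len(nrow(mesh$skin))))
  n_skin <- if (is.null(mesh$skin)) 0L else nrow(mesh$skin)
  n_bone <- if (is.null(mesh$bone)) 0L else nrow(mesh$bone)
  all_cells <- c(mesh$cells,
                 lapply(seq_len(n_skin), function(i) mesh$skin[i, ]),
                 if (n_bone) lapply(seq_len(n_bone), function(i) mesh$bone[i, ]))
  n_cells <- length(all_cells)
  n_ints <- sum(vapply(all_cells, length, integer(1))) + n_cells
  w("CELLS %d %d", n_cells, n_ints)
  writeLines(vapply(all_cells, function(c)
    paste(c(length(c), c - 1L), collapse = " "), character(1)), con)
  types <- c(vapply(mesh$cells, function(c) if (length(c) == 8L) 12L else 10L,
                    integer(1)),
             rep(5L, n_skin + n_bone))
  w("CELL_TYPES %d", n_cells)
  writeLines(as.character(types), con)

  w("CELL_DATA %d", n_cells)
  n_vol <- length(mesh$cells)
  skin_tag <- c(rep(0L, n_vol), rep(1L, n_skin), rep(0L, n_bone))
  bone_tag <- c(rep(0L, n_vol), rep(0L, n_skin), rep(1L, n_bone))
  w("SCALARS skin int 1"); w("LOOKUP_TABLE default")
  writeLines(as.character(skin_tag), con)
  w("SCALARS bone int 1"); w("LOOKUP_TABLE default")
  writeLines(as.character(bone_tag), con)
  invisible(path)
}
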