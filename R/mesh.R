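#' Voxelized hexahedral mesh of an MTU design
#'
#' Builds an axis-aligned hexahedral (voxel) mesh of the design. The design
#' geometry is rectilinear, so voxelization is exact up to snapping of
#' non-grid-aligned bridge widths: the grid spans the full bounding box with
#' `round(dim / h)` elements per axis and an element is kept when its center
#' lies inside the solid (bridges in the muscle section, anchors minus anchor
#' holes elsewhere).
#'
#' Elements are labelled `muscle` (|z| <= muscle_length/2) or `tendon`.
#' Muscle elements within `surface_layer_depth` element layers of the exterior
#' form the contractile set, reflecting that tissue only matures in a thin
#' (150-200 um) surface layer; the default depth of one element layer
#' represents that shell at the default resolution.
#'
#' @param design An [mtu_design()].
#' @param h Target element size (mm). Default 0.1 mm reproduces a sparse-MTU
#'   mesh with on the order of 3e5 vertices; coarser meshes (0.5 mm) are used
#'   for quick sweeps.
#' @param surface_layer_depth Contractile shell thickness in element layers.
#' @return An object of class `hex_mesh` with fields `vertices` (N x 3 mm),
#'   `hexes` (M x 8 one-based connectivity, VTK corner order), `region`
#'   (factor per element), `contractile` (logical per element), `h` (actual
#'   element sizes per axis), `design`.
#' @examples
#' m <- hex_mesh(mtu_design(), h = 0.75)
#' table(m$region)
#' @export
hex_mesh <- function(design, h = 0.1, surface_layer_depth = 1L) {
  stopifnot(inherits(design, "mtu_design"))
  stop_if_not_scalar_pos(h, "h")
  surface_layer_depth <- as.integer(surface_layer_depth)
  if (is.na(surface_layer_depth) || surface_layer_depth < 1L)
    abort("`surface_layer_depth` must be an integer >= 1")

  nx <- max(1L, round(design$width / h))
  ny <- max(1L, round(design$height / h))
  nz <- max(1L, round(design$length / h))
  hx <- design$width / nx; hy <- design$height / ny; hz <- design$length / nz

  # element-center coordinates
  cx <- -design$width / 2 + (seq_len(nx) - 0.5) * hx
  cy <- -design$height / 2 + (seq_len(ny) - 0.5) * hy
  cz <- -design$length / 2 + (seq_len(nz) - 0.5) * hz

  # bridge/gap boundaries are snapped to the nearest element boundary, which
  # keeps the overall layout width exact and each bridge within one element
  # of its nominal width at any resolution
  n_b <- design$n_bridges
  span <- n_b * design$bridge_width + (n_b - 1L) * design$bridge_gap
  offset <- (design$width - span) / 2
  in_bridge_x <- logical(nx)
  prev_hi <- 0L
  for (k in seq_len(n_b)) {
    lo_mm <- offset + (k - 1L) * (design$bridge_width + design$bridge_gap)
    lo <- floor(lo_mm / hx + 0.5)
    hi <- floor((lo_mm + design$bridge_width) / hx + 0.5)
    if (hi - lo < 2L)
      abort(sprintf(
        "element size h = %.3g mm cannot resolve a %.3g mm bridge (< 2 elements across)",
        h, design$bridge_width))
    if (k > 1L && lo <= prev_hi)
      abort(sprintf(
        "element size h = %.3g mm cannot resolve the %.3g mm bridge gap",
        h, design$bridge_gap))
    in_bridge_x[(lo + 1L):hi] <- TRUE
    prev_hi <- hi
  }

  muscle_z <- abs(cz) <= design$muscle_length / 2 + 1e-9
  # anchor hole: through-height rectangle centred in each anchor
  anchor_z_center <- (design$length + design$muscle_length) / 4
  hole_x <- abs(cx) <= design$anchor_hole[1] / 2 + 1e-9
  hole_z <- abs(abs(cz) - anchor_z_center) <= design$anchor_hole[2] / 2 + 1e-9

  # occupancy array [nx, ny, nz]
  occ <- array(TRUE, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    if (muscle_z[k]) {
      occ[, , k] <- in_bridge_x
    } else if (hole_z[k]) {
      occ[, , k] <- !hole_x
    }
  }

  keep <- which(occ)
  idx <- arrayInd(keep, dim(occ))
  M <- nrow(idx)

  # global vertex grid ids, (nx+1)(ny+1)(nz+1), x fastest
  vx <- nx + 1L; vy <- ny + 1L
  vid <- function(i, j, k) (k - 1L) * vx * vy + (j - 1L) * vx + i
  i0 <- idx[, 1L]; j0 <- idx[, 2L]; k0 <- idx[, 3L]
  # VTK hexahedron corner order
  conn <- cbind(
    vid(i0,      j0,      k0),
    vid(i0 + 1L, j0,      k0),
    vid(i0 + 1L, j0 + 1L, k0),
    vid(i0,      j0 + 1L, k0),
    vid(i0,      j0,      k0 + 1L),
    vid(i0 + 1L, j0,      k0 + 1L),
    vid(i0 + 1L, j0 + 1L, k0 + 1L),
    vid(i0,      j0 + 1L, k0 + 1L))
  used <- sort(unique(as.vector(conn)))
  remap <- integer(vx * vy * (nz + 1L))
  remap[used] <- seq_along(used)
  conn <- matrix(remap[conn], nrow = M)

  ug <- used - 1L
  gi <- ug %% vx
  gj <- (ug %/% vx) %% vy
  gk <- ug %/% (vx * vy)
  vertices <- cbind(
    x = -design$width / 2 + gi * hx,
    y = -design$height / 2 + gj * hy,
    z = -design$length / 2 + gk * hz)

  region <- factor(ifelse(muscle_z[k0], "muscle", "tendon"),
                   levels = c("muscle", "tendon"))

  # layer index = element distance to the exterior (6-neighbourhood)
  layer <- array(NA_integer_, dim = dim(occ))
  surf <- function(o) {
    pad <- array(FALSE, dim = dim(o) + 2L)
    pad[2:(nx + 1L), 2:(ny + 1L), 2:(nz + 1L)] <- o
    o & !(pad[1:nx, 2:(ny + 1L), 2:(nz + 1L)] &
          pad[3:(nx + 2L), 2:(ny + 1L), 2:(nz + 1L)] &
          pad[2:(nx + 1L), 1:ny, 2:(nz + 1L)] &
          pad[2:(nx + 1L), 3:(ny + 2L), 2:(nz + 1L)] &
          pad[2:(nx + 1L), 2:(ny + 1L), 1:nz] &
          pad[2:(nx + 1L), 2:(ny + 1L), 3:(nz + 2L)])
  }
  remaining <- occ
  depth <- 0L
  while (any(remaining) && depth < surface_layer_depth) {
    depth <- depth + 1L
    s <- surf(remaining)
    layer[s] <- depth
    remaining <- remaining & !s
  }
  contractile <- !is.na(layer[keep]) & region == "muscle"

  structure(list(
    vertices = vertices, hexes = conn, region = region,
    contractile = contractile, h = c(hx, hy, hz),
    dims = c(nx, ny, nz), design = design
  ), class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf(
    "<hex_mesh> %d vertices, %d hexahedra (h = %.3g x %.3g x %.3g mm)\n",
    nrow(x$vertices), nrow(x$hexes), x$h[1], x$h[2], x$h[3]))
  cat(sprintf("  muscle %d / tendon %d elements, %d contractile\n",
              sum(x$region == "muscle"), sum(x$region == "tendon"),
              sum(x$contractile)))
  invisible(x)
}

#' Structured hexahedral mesh of a plain box
#'
#' A single-region box mesh used for validation against closed-form
#' elasticity solutions (e.g. uniform contraction of a free bar). The box is
#' centred at the origin with z along `length`.
#'
#' @param length,width,height Box dimensions (mm), z/x/y respectively.
#' @param h Element size (mm).
#' @param region Region label for all elements.
#' @param contractile `"all"`, `"surface"` (an exterior shell) or `"none"`.
#' @param surface_layers Shell thickness in element layers for
#'   `contractile = "surface"`; pick `depth_mm / h` to keep the shell at a
#'   fixed physical thickness across resolutions.
#' @return A `hex_mesh`.
#' @export
hex_box_mesh <- function(length = 10, width = 1, height = 1, h = 0.5,
                         region = c("muscle", "tendon"),
                         contractile = c("all", "surface", "none"),
                         surface_layers = 1L) {
  region <- match.arg(region)
  contractile <- match.arg(contractile)
  nx <- max(1L, round(width / h)); ny <- max(1L, round(height / h))
  nz <- max(1L, round(length / h))
  hx <- width / nx; hy <- height / ny; hz <- length / nz
  vx <- nx + 1L; vy <- ny + 1L
  vid <- function(i, j, k) (k - 1L) * vx * vy + (j - 1L) * vx + i
  idx <- as.matrix(expand.grid(i = seq_len(nx), j = seq_len(ny),
                               k = seq_len(nz)))
  i0 <- idx[, 1L]; j0 <- idx[, 2L]; k0 <- idx[, 3L]
  conn <- cbind(
    vid(i0, j0, k0), vid(i0 + 1L, j0, k0), vid(i0 + 1L, j0 + 1L, k0),
    vid(i0, j0 + 1L, k0), vid(i0, j0, k0 + 1L), vid(i0 + 1L, j0, k0 + 1L),
    vid(i0 + 1L, j0 + 1L, k0 + 1L), vid(i0, j0 + 1L, k0 + 1L))
  g <- as.matrix(expand.grid(i = 0:nx, j = 0:ny, k = 0:nz))
  vertices <- cbind(x = -width / 2 + g[, 1] * hx,
                    y = -height / 2 + g[, 2] * hy,
                    z = -length / 2 + g[, 3] * hz)
  M <- nrow(conn)
  d <- as.integer(surface_layers)
  on_surface <- i0 <= d | i0 > nx - d | j0 <= d | j0 > ny - d |
    k0 <= d | k0 > nz - d
  contr <- switch(contractile, all = rep(TRUE, M), surface = on_surface,
                  none = rep(FALSE, M))
  structure(list(
    vertices = vertices, hexes = conn,
    region = factor(rep(region, M), levels = c("muscle", "tendon")),
    contractile = contr, h = c(hx, hy, hz), dims = c(nx, ny, nz),
    design = NULL), class = "hex_mesh")
}

#' Total mesh volume
#' @param mesh A [hex_mesh()].
#' @return Volume in mm^3 (number of elements x element volume).
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "hex_mesh"))
  nrow(mesh$hexes) * prod(mesh$h)
}

#' Export a mesh (optionally with deformed frames) as legacy VTK
#'
#' Writes an ASCII VTK unstructured grid with region and contractile flags as
#' cell data; pass `points` to export a deformed configuration instead of the
#' rest positions.
#'
#' @param mesh A [hex_mesh()].
#' @param file Output path (`.vtk`).
#' @param points Optional N x 3 matrix of vertex positions to export.
#' @return `file`, invisibly.
#' @export
write_vtk <- function(mesh, file, points = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"))
  P <- if (is.null(points)) mesh$vertices else points
  stopifnot(nrow(P) == nrow(mesh$vertices), ncol(P) == 3L)
  M <- nrow(mesh$hexes)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "mtukit hexahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(P))), con)
  writeLines(apply(format(P, scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", M, 9L * M), con)
  writeLines(paste(8L, apply(mesh$hexes - 1L, 1, paste, collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", M), con)
  writeLines(rep("12", M), con)
  writeLines(c(sprintf("CELL_DATA %d", M),
               "SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$region)), con)
  writeLines(c("SCALARS contractile int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$contractile)), con)
  invisible(file)
}
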