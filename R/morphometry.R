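# Myotube morphometry: fusion index, shift angles, widths, texture variance.

check_scene <- function(scene) {
  stopifnot(inherits(scene, "morphometry_scene") ||
              (is.list(scene) && all(c("tube_labels", "marker_positive",
                                       "nuclei") %in% names(scene))))
  if (any(scene$tube_labels < 0L))
    abort("tube labels must be non-negative integers")
  n_lab <- max(scene$tube_labels)
  if (n_lab > 0L && length(scene$marker_positive) < n_lab)
    abort("every tube label needs a marker_positive flag")
  invisible(scene)
}

#' Fusion index of a morphometry scene
#'
#' Fraction of nuclei whose centroid lies inside a MyHC-positive myotube
#' (boundary pixels count as inside). Nuclei inside marker-negative tubes or
#' on background do not count.
#'
#' @param scene A `morphometry_scene` (see [gen_morphometry_scene()]).
#' @return Fusion index in `[0, 1]`.
#' @export
fusion_index <- function(scene) {
  check_scene(scene)
  nn <- nrow(scene$nuclei)
  if (nn == 0L) abort("scene contains no nuclei")
  ny <- nrow(scene$tube_labels); nx <- ncol(scene$tube_labels)
  yi <- pmin(pmax(round(scene$nuclei$y), 1L), ny)
  xi <- pmin(pmax(round(scene$nuclei$x), 1L), nx)
  lab <- scene$tube_labels[cbind(yi, xi)]
  inside <- lab > 0L & scene$marker_positive[pmax(lab, 1L)]
  sum(inside) / nn
}

# principal-axis direction and anisotropy of a pixel set via second central
# moments; returns unit axis (x, y) and eigenvalue ratio
mask_principal_axis <- function(xs, ys) {
  cx <- mean(xs); cy <- mean(ys)
  cxx <- mean((xs - cx)^2); cyy <- mean((ys - cy)^2)
  cxy <- mean((xs - cx) * (ys - cy))
  C <- matrix(c(cxx, cxy, cxy, cyy), 2, 2)
  eg <- eigen(C, symmetric = TRUE)
  list(axis = eg$vectors[, 1], ratio = eg$values[1] / max(eg$values[2], 1e-12),
       lambda = eg$values)
}

#' Per-myotube shift angles
#'
#' Acute angle, in degrees, between each tube's principal (long) axis - from
#' the second central moments of its mask - and the scene's reference axis
#' (the tension axis). Lower angles mean better alignment. Near-circular
#' tubes (moment ratio below `eccentricity_floor`) have no well-defined long
#' axis and are excluded with a message.
#'
#' @param scene A `morphometry_scene`.
#' @param eccentricity_floor Minimum major/minor moment ratio.
#' @return A tibble `label`, `shift_angle_deg`, with the mean angle as
#'   attribute `mean_shift_angle_deg`.
#' @export
shift_angles <- function(scene, eccentricity_floor = 1.5) {
  check_scene(scene)
  labs <- sort(unique(scene$tube_labels[scene$tube_labels > 0L]))
  ref <- scene$reference_axis
  ny <- nrow(scene$tube_labels)
  rows <- lapply(labs, function(l) {
    px <- which(scene$tube_labels == l)
    xs <- ((px - 1L) %/% ny) + 1L
    ys <- ((px - 1L) %% ny) + 1L
    pa <- mask_principal_axis(xs, ys)
    if (pa$ratio < eccentricity_floor) {
      message(sprintf("tube %d excluded: near-circular (moment ratio %.2f)",
                      l, pa$ratio))
      return(NULL)
    }
    ang <- acos(pmin(abs(sum(pa$axis * ref)), 1)) * 180 / pi
    tibble::tibble(label = l, shift_angle_deg = ang)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_shift_angle_deg") <-
    if (nrow(out)) mean(out$shift_angle_deg) else NA_real_
  out
}

#' Per-myotube widths
#'
#' Width of each tube as twice the median distance-transform value along the
#' medial axis, converted to um. The medial axis is approximated by binning
#' tube pixels along the principal axis and taking the per-bin maximum of
#' the Euclidean distance transform. Tubes thinner than 2 px are flagged
#' unreliable.
#'
#' @param scene A `morphometry_scene`.
#' @return A tibble `label`, `width_px`, `width_um`, `reliable`.
#' @export
myotube_widths <- function(scene) {
  check_scene(scene)
  labs <- sort(unique(scene$tube_labels[scene$tube_labels > 0L]))
  ny <- nrow(scene$tube_labels)
  rows <- lapply(labs, function(l) {
    m <- scene$tube_labels == l
    dist <- as_mat(EBImage::distmap(m * 1))
    px <- which(m)
    xs <- ((px - 1L) %/% ny) + 1L
    ys <- ((px - 1L) %% ny) + 1L
    pa <- mask_principal_axis(xs, ys)
    proj <- round((xs - mean(xs)) * pa$axis[1] + (ys - mean(ys)) * pa$axis[2])
    ridge <- tapply(dist[px], proj, max)
    width_px <- 2 * median(ridge)
    # the distance transform cannot resolve tubes under ~2 px across
    tibble::tibble(label = l, width_px = width_px,
                   width_um = width_px * scene$pixel_size,
                   reliable = width_px >= 3)
  })
  dplyr::bind_rows(rows)
}

#' Intensity variance inside a region of interest
#'
#' Population variance of the pixel intensities inside the ROI, used to
#' discriminate tissue textures (muscle vs tendon matrix differ in texture
#' graininess).
#'
#' @param image Grayscale image.
#' @param roi Either a logical mask of the image size or a polygon given as
#'   an n x 2 matrix of `(x, y)` vertices (even-odd rule).
#' @return Intensity variance.
#' @export
texture_variance <- function(image, roi) {
  image <- as_mat(image)
  stop_if_not_image(image)
  if (is.matrix(roi) && !is.logical(roi) && ncol(roi) == 2L) {
    roi <- polygon_mask(roi, nrow(image), ncol(image))
  }
  if (!is.logical(roi) || !all(dim(roi) == dim(image)))
    abort("`roi` must be a logical mask of the image size or an n x 2 polygon")
  if (!any(roi)) abort("ROI is empty or lies outside the image")
  x <- image[roi]
  mean((x - mean(x))^2)
}

# even-odd rasterization of a polygon given as (x, y) vertices
polygon_mask <- function(poly, ny, nx) {
  if (any(poly[, 1] < 0.5) || any(poly[, 1] > nx + 0.5) ||
      any(poly[, 2] < 0.5) || any(poly[, 2] > ny + 0.5))
    abort("polygon ROI lies (partly) outside the image")
  xg <- rep(seq_len(nx), each = ny)
  yg <- rep(seq_len(ny), times = nx)
  n <- nrow(poly)
  inside <- rep(FALSE, nx * ny)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > yg) != (yj > yg)) &
      (xg < (xj - xi) * (yg - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, ny, nx)
}

#' Per-tube morphometry table
#'
#' Convenience wrapper joining widths, shift angles and marker positivity
#' into one tidy per-tube table.
#'
#' @param scene A `morphometry_scene`.
#' @return A tibble with one row per tube.
#' @export
morphometry_table <- function(scene) {
  check_scene(scene)
  w <- myotube_widths(scene)
  a <- shift_angles(scene)
  out <- dplyr::left_join(w, a, by = "label")
  out$marker_positive <- scene$marker_positive[out$label]
  out
}
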