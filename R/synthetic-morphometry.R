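#' Generate a labelled morphometry scene with known ground truth
#'
#' Builds a synthetic field of view for the tissue-maturity statistics:
#' elongated myotube masks (rotated rectangles) whose orientations scatter
#' about the reference axis with a concentration parameter, per-tube
#' myosin-heavy-chain (MyHC) positivity flags, and nuclei placed so that
#' exactly `round(fusion_fraction * n_nuclei)` fall inside marker-positive
#' tubes and the rest on background.
#'
#' Orientation deviations are drawn as wrapped-normal angles with
#' SD `1/sqrt(angle_concentration)` rad (a von-Mises-type concentration: the
#' limit of infinite concentration gives perfectly aligned tubes, zero gives
#' uniform orientations).
#'
#' @param n_tubes Number of myotubes.
#' @param mean_width_um Mean tube width, um.
#' @param angle_concentration Orientation concentration about the reference
#'   axis (>= 0).
#' @param fusion_fraction Target fusion index in `[0, 1]`.
#' @param n_nuclei Total nuclei.
#' @param marker_positive_fraction Fraction of tubes flagged MyHC-positive.
#' @param width_px,height_px Scene size, px.
#' @param pixel_size um/px.
#' @param reference_axis Unit vector of the tension axis in image (x, y)
#'   coordinates; default along y, the construct's longitudinal axis.
#' @param seed Integer seed.
#' @param max_tries Placement retries per tube before giving up.
#' @return A `morphometry_scene`: `tube_labels` (integer matrix, 0 =
#'   background), `marker_positive` (logical per tube), `nuclei` (tibble
#'   `x`, `y` in px), `reference_axis`, `pixel_size`.
#' @export
gen_morphometry_scene <- function(n_tubes = 8L, mean_width_um = 25,
                                  angle_concentration = 8,
                                  fusion_fraction = 0.25, n_nuclei = 40L,
                                  marker_positive_fraction = 0.75,
                                  width_px = 256L, height_px = 256L,
                                  pixel_size = 2,
                                  reference_axis = c(0, 1), seed = 1L,
                                  max_tries = 200L) {
  if (fusion_fraction < 0 || fusion_fraction > 1)
    abort("`fusion_fraction` must lie in [0, 1]")
  if (angle_concentration < 0) abort("`angle_concentration` must be >= 0")
  stop_if_not_scalar_pos(mean_width_um, "mean_width_um")
  reference_axis <- reference_axis / sqrt(sum(reference_axis^2))

  withr::with_seed(seed, {
    labels <- matrix(0L, height_px, width_px)
    w_px <- mean_width_um / pixel_size
    len_px <- 0.4 * min(width_px, height_px)
    ref_angle <- atan2(reference_axis[2], reference_axis[1])

    xg <- matrix(rep(seq_len(width_px), each = height_px), height_px, width_px)
    yg <- matrix(rep(seq_len(height_px), times = width_px), height_px, width_px)

    for (tube in seq_len(n_tubes)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        dev <- if (angle_concentration < 1e-6) runif(1, -pi / 2, pi / 2)
               else rnorm(1, sd = 1 / sqrt(angle_concentration))
        ang <- ref_angle + dev
        ax <- c(cos(ang), sin(ang))
        cx <- runif(1, 0.2 * width_px, 0.8 * width_px)
        cy <- runif(1, 0.2 * height_px, 0.8 * height_px)
        along <- (xg - cx) * ax[1] + (yg - cy) * ax[2]
        across <- -(xg - cx) * ax[2] + (yg - cy) * ax[1]
        mask <- abs(along) <= len_px / 2 & abs(across) <= w_px / 2
        mask <- mask & xg >= 1 & xg <= width_px & yg >= 1 & yg <= height_px
        if (!any(mask)) next
        if (!any(labels[mask] > 0L)) {
          labels[mask] <- tube
          placed <- TRUE
          break
        }
      }
      if (!placed)
        abort(sprintf("could not place tube %d without overlap after %d tries",
                      tube, max_tries))
    }

    n_pos <- max(1L, round(marker_positive_fraction * n_tubes))
    marker_positive <- seq_len(n_tubes) %in% sample.int(n_tubes, n_pos)

    n_in <- round(fusion_fraction * n_nuclei)
    n_out <- n_nuclei - n_in
    pos_px <- which(matrix(marker_positive[pmax(labels, 1L)] & labels > 0L,
                           height_px, width_px))
    bg_px <- which(labels == 0L)
    if (n_in > 0L && length(pos_px) == 0L)
      abort("no marker-positive tube area to place fused nuclei")
    sel_in <- if (n_in > 0L) sample(pos_px, n_in, replace = n_in > length(pos_px)) else integer(0)
    sel_out <- if (n_out > 0L) sample(bg_px, n_out) else integer(0)
    sel <- c(sel_in, sel_out)
    nuclei <- tibble::tibble(
      x = ((sel - 1L) %/% height_px) + 1L,
      y = ((sel - 1L) %% height_px) + 1L)

    structure(list(tube_labels = labels, marker_positive = marker_positive,
                   nuclei = nuclei, reference_axis = reference_axis,
                   pixel_size = pixel_size),
              class = "morphometry_scene")
  })
}

#' @export
print.morphometry_scene <- function(x, ...) {
  cat(sprintf(
    "<morphometry_scene> %d x %d px, %d tubes (%d MyHC+), %d nuclei\n",
    nrow(x$tube_labels), ncol(x$tube_labels), max(x$tube_labels),
    sum(x$marker_positive), nrow(x$nuclei)))
  invisible(x)
}
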