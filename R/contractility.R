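# Contractility metrics computed from dense optical flow.
#
# Angle convention: flow components are (u, v) with u rightward and v downward
# (image rows increase downward). Angles are quoted in display (mathematical)
# orientation, i.e. measured counterclockwise from +x after flipping y:
#   theta = atan2(-v, u) in degrees, wrapped to [0, 360).
# Under this convention the conventional "contraction angle" of 135 degrees
# points up-left on the screen.

flow_angle_deg <- function(u, v) {
  (atan2(-v, u) * 180 / pi) %% 360
}

#' Count flow vectors aligned with a contraction direction
#'
#' Counts the flow vectors whose direction lies within `tolerance` of
#' `angle` (see the angle convention in the package vignette: counterclockwise
#' from +x in display orientation). Vectors with magnitude below
#' `min_magnitude` are excluded as noise. The interval is half-open
#' (`[angle - tolerance, angle + tolerance)`), so disjoint bins tiling the
#' circle partition the vectors exactly.
#'
#' @param flow A `flow_field` (see [estimate_flow()]).
#' @param angle Designated contraction angle, degrees (default 135).
#' @param tolerance Half-width of the acceptance sector, degrees, in
#'   (0, 180). The default 22.5 corresponds to an 8-sector hue-wheel
#'   quantization.
#' @param min_magnitude Magnitude floor, px/frame.
#' @param mask Optional logical matrix restricting the counted pixels.
#' @return A one-row tibble: `count`, `fraction` (of above-floor vectors),
#'   `n_considered`.
#' @export
directional_alignment <- function(flow, angle = 135, tolerance = 22.5,
                                  min_magnitude = 0.1, mask = NULL) {
  stopifnot(inherits(flow, "flow_field"))
  if (tolerance <= 0 || tolerance >= 180)
    abort("`tolerance` must lie in (0, 180)")
  u <- flow$u; v <- flow$v
  sel <- sqrt(u^2 + v^2) >= min_magnitude
  if (!is.null(mask)) sel <- sel & mask
  n <- sum(sel)
  if (n == 0L)
    return(tibble::tibble(count = 0L, fraction = NA_real_, n_considered = 0L))
  th <- flow_angle_deg(u[sel], v[sel])
  d <- ((th - angle + 180) %% 360) - 180
  cnt <- sum(d >= -tolerance & d < tolerance)
  tibble::tibble(count = cnt, fraction = cnt / n, n_considered = n)
}

#' Volumetric contractile kinetic energy trace
#'
#' For each flow field, converts per-pixel speeds to m/s using the pixel size
#' and frame interval and computes the kinetic energy of the moving tissue
#' normalized by the total tissue volume,
#' `E_k = (rho / 2) * mean(v_i^2)` over the masked pixels (J/m^3). Because
#' every pixel volumizes equally (uniform section depth), the depth cancels
#' in the volume normalization and is carried only as metadata.
#'
#' @param flows A `flow_field` or list of them.
#' @param mask Logical matrix selecting tissue pixels (voids excluded), same
#'   shape as the flow; `NULL` uses all pixels.
#' @param rho Tissue density, kg/m^3 (default 1000, water-like).
#' @param section_depth Section depth, um (bookkeeping only).
#' @return A tibble (class `ek_trace`): `pair`, `time_s`, `Ek_J_per_m3`,
#'   with `rho` and `section_depth` as attributes.
#' @examples
#' fl <- structure(list(u = matrix(1, 4, 4), v = matrix(0, 4, 4),
#'                      pixel_size = 1000, frame_interval = 1),
#'                 class = "flow_field")  # 1 mm/s everywhere
#' kinetic_energy(fl)$Ek_J_per_m3  # 5e-4 J/m^3
#' @export
kinetic_energy <- function(flows, mask = NULL, rho = 1000,
                           section_depth = 150) {
  if (inherits(flows, "flow_field")) flows <- list(flows)
  stopifnot(length(flows) >= 1L, all(vapply(flows, inherits, logical(1),
                                            "flow_field")))
  stop_if_not_scalar_pos(rho, "rho")
  ek <- vapply(seq_along(flows), function(i) {
    fl <- flows[[i]]
    m <- mask %||% matrix(TRUE, nrow(fl$u), ncol(fl$u))
    if (!all(dim(m) == dim(fl$u)))
      abort("`mask` must match the flow dimensions")
    if (!any(m)) abort("`mask` selects no pixels")
    scale <- fl$pixel_size * 1e-6 / fl$frame_interval  # px/frame -> m/s
    v2 <- (fl$u[m]^2 + fl$v[m]^2) * scale^2
    rho / 2 * mean(v2)
  }, numeric(1))
  t_s <- cumsum(vapply(flows, `[[`, numeric(1), "frame_interval"))
  out <- tibble::tibble(pair = seq_along(flows), time_s = t_s,
                        Ek_J_per_m3 = ek)
  structure(out, rho = rho, section_depth = section_depth,
            class = c("ek_trace", class(out)))
}

#' @export
autoplot.ek_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data$Ek_J_per_m3)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (s)", y = expression(E[k] ~ (J / m^3))) +
    ggplot2::theme_minimal()
}

#' Segment dark void areas by superpixel brightness clustering
#'
#' Clusters the frame into SLIC-style superpixels (k-means in joint spatial
#' and intensity space over local neighbourhoods) and marks as void every
#' superpixel whose mean brightness falls below `threshold`. The brightness
#' threshold is deliberately explicit: it is tuned per imaging setup to best
#' remove the dark void areas before volume normalization.
#'
#' @param frame Grayscale image in `[0, 1]`.
#' @param n_superpixels Approximate superpixel count.
#' @param threshold Void brightness threshold (cluster mean below -> void).
#' @param compactness Relative weight of spatial vs intensity distance.
#' @param iterations SLIC refinement iterations.
#' @param refine_pixels If `TRUE` (default), a pixel must itself be darker
#'   than `threshold` in addition to belonging to a dark cluster; this
#'   sharpens superpixel boundaries that straddle a void edge.
#' @return Logical matrix, `TRUE` on void pixels.
#' @export
segment_voids <- function(frame, n_superpixels = 200, threshold = 0.15,
                          compactness = 0.1, iterations = 5L,
                          refine_pixels = TRUE) {
  frame <- as_mat(frame)
  stop_if_not_image(frame, "frame")
  ny <- nrow(frame); nx <- ncol(frame)
  S <- max(2, round(sqrt(ny * nx / n_superpixels)))
  cyv <- seq(S / 2, ny, by = S); cxv <- seq(S / 2, nx, by = S)
  centers <- expand.grid(y = cyv, x = cxv)
  centers$i <- frame[cbind(pmin(round(centers$y), ny),
                           pmin(round(centers$x), nx))]
  k <- nrow(centers)
  xg <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  yg <- matrix(rep(seq_len(ny), times = nx), ny, nx)
  lab <- matrix(1L, ny, nx)
  dist_best <- matrix(Inf, ny, nx)
  m <- compactness
  for (it in seq_len(iterations)) {
    dist_best[] <- Inf
    for (c_i in seq_len(k)) {
      y0 <- max(1, floor(centers$y[c_i] - S)); y1 <- min(ny, ceiling(centers$y[c_i] + S))
      x0 <- max(1, floor(centers$x[c_i] - S)); x1 <- min(nx, ceiling(centers$x[c_i] + S))
      di <- (frame[y0:y1, x0:x1] - centers$i[c_i])^2 +
        (m / S)^2 * ((yg[y0:y1, x0:x1] - centers$y[c_i])^2 +
                     (xg[y0:y1, x0:x1] - centers$x[c_i])^2)
      upd <- di < dist_best[y0:y1, x0:x1]
      blk <- lab[y0:y1, x0:x1]; blk[upd] <- c_i
      lab[y0:y1, x0:x1] <- blk
      db <- dist_best[y0:y1, x0:x1]; db[upd] <- di[upd]
      dist_best[y0:y1, x0:x1] <- db
    }
    for (c_i in seq_len(k)) {
      sel <- lab == c_i
      if (any(sel)) {
        centers$y[c_i] <- mean(yg[sel])
        centers$x[c_i] <- mean(xg[sel])
        centers$i[c_i] <- mean(frame[sel])
      }
    }
  }
  cluster_mean <- vapply(seq_len(k), function(c_i) {
    sel <- lab == c_i
    if (any(sel)) mean(frame[sel]) else Inf
  }, numeric(1))
  void <- matrix(cluster_mean[lab] < threshold, ny, nx)
  if (refine_pixels) void <- void & frame < threshold
  void
}

#' Lateral displacement from image subtraction
#'
#' Returns the absolute-difference image of the two frames together with a
#' one-dimensional displacement estimate along `axis`: edge profiles
#' (gradient magnitude averaged across the other axis) are cross-correlated
#' and the shift maximizing the correlation, refined to sub-pixel precision
#' by parabolic interpolation, is converted to um.
#'
#' @param frame_a,frame_b Grayscale frames, same shape.
#' @param axis `"x"` or `"y"`: direction of the reported lateral shift.
#' @param pixel_size um/px.
#' @param max_shift Largest shift searched, px.
#' @return A list: `difference` (image), `displacement_px`,
#'   `displacement_um` (`NA` with a warning if the frames are featureless).
#' @export
subtraction_displacement <- function(frame_a, frame_b, axis = c("x", "y"),
                                     pixel_size = 10, max_shift = 20L) {
  frame_a <- as_mat(frame_a); frame_b <- as_mat(frame_b)
  stop_if_not_image(frame_a, "frame_a")
  if (!all(dim(frame_a) == dim(frame_b)))
    abort("frames must have identical dimensions")
  axis <- match.arg(axis)
  difference <- abs(frame_b - frame_a)

  # signed derivative along the axis keeps edge phase; its magnitude would
  # blur the correlation peak
  profile_of <- function(img) {
    g <- img_gradients(img)
    if (axis == "x") colMeans(g$gx) else rowMeans(g$gy)
  }
  pa <- profile_of(frame_a); pb <- profile_of(frame_b)
  if (sd(pa) < 1e-12 || sd(pb) < 1e-12) {
    warn("featureless frames: lateral displacement is undefined")
    return(list(difference = difference, displacement_px = NA_real_,
                displacement_um = NA_real_))
  }
  pa <- pa - mean(pa); pb <- pb - mean(pb)
  n <- length(pa)
  lags <- -min(max_shift, n - 2L):min(max_shift, n - 2L)
  cc <- vapply(lags, function(L) {
    ia <- seq_len(n); ib <- ia + L
    ok <- ib >= 1L & ib <= n
    sum(pa[ia[ok]] * pb[ib[ok]])
  }, numeric(1))
  i0 <- which.max(cc)
  shift <- lags[i0]
  if (i0 > 1L && i0 < length(lags)) {   # parabolic sub-pixel refinement
    y1 <- cc[i0 - 1L]; y2 <- cc[i0]; y3 <- cc[i0 + 1L]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-12) shift <- shift + 0.5 * (y1 - y3) / den
  }
  # features moving by +d between a and b put the correlation peak at L = d
  disp_px <- shift
  list(difference = difference, displacement_px = disp_px,
       displacement_um = disp_px * pixel_size)
}

#' Arrow visualization of a flow field
#'
#' Overlays direction-hued, magnitude-scaled arrows at a uniformly sampled
#' subset of pixels, in the style used to display contraction videos: arrow
#' length scaled 25x and 0.02% of pixels drawn by default.
#'
#' @param flow A `flow_field`.
#' @param background Optional grayscale image drawn under the arrows.
#' @param arrow_scale Length multiplier for arrows.
#' @param sample_fraction Fraction of pixels at which to draw arrows.
#' @param seed Seed for the uniform pixel sample (deterministic output).
#' @return A ggplot object; the arrow layer data has one row per drawn arrow.
#' @export
visualize_flow <- function(flow, background = NULL, arrow_scale = 25,
                           sample_fraction = 2e-4, seed = 1L) {
  stopifnot(inherits(flow, "flow_field"))
  ny <- nrow(flow$u); nx <- ncol(flow$u)
  p <- ggplot2::ggplot()
  if (!is.null(background)) {
    bg <- as_mat(background)
    dfb <- tibble::tibble(
      x = rep(seq_len(ncol(bg)), each = nrow(bg)),
      y = rep(seq_len(nrow(bg)), times = ncol(bg)),
      fill = as.vector(bg))
    p <- p + ggplot2::geom_raster(data = dfb,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$fill)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   guide = "none")
  }
  n_arrows <- round(ny * nx * sample_fraction)
  if (n_arrows > 0) {
    idx <- withr::with_seed(seed, sample.int(ny * nx, n_arrows))
    y <- ((idx - 1L) %% ny) + 1L
    x <- ((idx - 1L) %/% ny) + 1L
    df <- tibble::tibble(
      x = x, y = y,
      u = flow$u[idx], v = flow$v[idx],
      hue = flow_angle_deg(flow$u[idx], flow$v[idx]))
    p <- p + ggplot2::geom_segment(
      data = df,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x + arrow_scale * .data$u,
                   yend = .data$y + arrow_scale * .data$v,
                   colour = .data$hue),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
      ggplot2::scale_colour_gradientn(
        colours = grDevices::hsv(seq(0, 1, length.out = 9)),
        limits = c(0, 360), guide = "none")
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @export
autoplot.flow_field <- function(object, ...) visualize_flow(object, ...)
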