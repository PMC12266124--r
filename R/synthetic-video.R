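#' Specification of a synthetic contraction video
#'
#' Describes a textured grayscale video with a known, analytically defined
#' motion field, used to validate the optical-flow pipeline. The texture is
#' spatially low-pass filtered Gaussian noise (correlation length
#' `texture_scale`), which gives gradient-based flow estimators
#' well-conditioned image gradients, as in real tissue video. Frames are
#' warped by the chosen affine motion model with bilinear interpolation and
#' corrupted by additive Gaussian sensor noise.
#'
#' Intensities are in `[0, 1]`. Image convention: matrices are indexed
#' `[y, x]` with y increasing downward (row 1 at the top).
#'
#' @param width_px,height_px Frame size in pixels.
#' @param n_frames Number of frames (>= 2).
#' @param pixel_size Pixel size, um/px. The study's videos do not state a
#'   pixel size; 10 um/px is a configurable default typical of stereoscope
#'   video of mm-scale constructs.
#' @param frame_rate Frames per second (videos were recorded at 25 or 50 fps).
#' @param texture_scale Texture correlation length, px.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param motion One of [motion_translation()], [motion_contraction()],
#'   [motion_rotation()].
#' @param voids Optional list of dark rectangles `c(x0, x1, y0, y1)` (px,
#'   frame coordinates) embedded in the texture and recorded in the ground
#'   truth.
#' @param seed Integer seed; output is reproducible bit-exactly.
#' @return A `video_spec` list.
#' @export
video_spec <- function(width_px = 128L, height_px = 128L, n_frames = 6L,
                       pixel_size = 10, frame_rate = 25,
                       texture_scale = 8, noise_sd = 0.01,
                       motion = motion_translation(0, 0),
                       voids = NULL, seed = 1L) {
  if (n_frames < 2L) abort("`n_frames` must be >= 2")
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  stop_if_not_scalar_pos(frame_rate, "frame_rate")
  stop_if_not_scalar_pos(texture_scale, "texture_scale")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  stopifnot(inherits(motion, "motion_model"))
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_frames = as.integer(n_frames), pixel_size = pixel_size,
                 frame_rate = frame_rate, texture_scale = texture_scale,
                 noise_sd = noise_sd, motion = motion, voids = voids,
                 seed = as.integer(seed)),
            class = "video_spec")
}

#' Affine motion models for synthetic videos
#'
#' `motion_translation`: rigid translation of `vx`, `vy` px/frame.
#' `motion_contraction`: uniaxial contraction by `strain_per_frame` per frame
#' along `axis` about `center` (default frame center); the per-frame-pair
#' displacement at position p is `-strain * (p - center)` along the axis.
#' `motion_rotation`: rigid rotation of `omega` rad/frame about `center`.
#'
#' @param vx,vy Translation, px/frame.
#' @param strain_per_frame Contraction strain per frame.
#' @param axis `"x"` or `"y"`.
#' @param center Rotation/contraction center `c(x, y)` px, or `NULL` for the
#'   frame center.
#' @param omega Rotation rate, rad/frame.
#' @return A `motion_model` list.
#' @name motion_models
NULL

#' @rdname motion_models
#' @export
motion_translation <- function(vx, vy) {
  structure(list(kind = "translation", vx = vx, vy = vy),
            class = "motion_model")
}

#' @rdname motion_models
#' @export
motion_contraction <- function(strain_per_frame, axis = c("x", "y"),
                               center = NULL) {
  axis <- match.arg(axis)
  structure(list(kind = "contraction", strain = strain_per_frame, axis = axis,
                 center = center), class = "motion_model")
}

#' @rdname motion_models
#' @export
motion_rotation <- function(omega, center = NULL) {
  structure(list(kind = "rotation", omega = omega, center = center),
            class = "motion_model")
}

# forward map of frame-0 coordinates to frame-t coordinates and its inverse;
# coordinates are (x, y) matrices
motion_map <- function(motion, t, xy, center, inverse = FALSE) {
  switch(motion$kind,
    translation = {
      d <- c(motion$vx, motion$vy) * t
      if (inverse) cbind(xy[, 1] - d[1], xy[, 2] - d[2])
      else cbind(xy[, 1] + d[1], xy[, 2] + d[2])
    },
    contraction = {
      s <- (1 - motion$strain)^t
      if (inverse) s <- 1 / s
      out <- xy
      j <- if (motion$axis == "x") 1L else 2L
      out[, j] <- center[j] + s * (xy[, j] - center[j])
      out
    },
    rotation = {
      a <- motion$omega * t * (if (inverse) -1 else 1)
      dx <- xy[, 1] - center[1]; dy <- xy[, 2] - center[2]
      cbind(center[1] + cos(a) * dx - sin(a) * dy,
            center[2] + sin(a) * dx + cos(a) * dy)
    })
}

# bilinear sample of matrix img [y, x] at (x, y) coordinates, clamped to edges
bilinear_sample <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x <- pmin(pmax(x, 1), nx)
  y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * ny + y0
  (1 - fx) * (1 - fy) * img[i00] +
    fx * (1 - fy) * img[i00 + ny] +
    (1 - fx) * fy * img[i00 + 1] +
    fx * fy * img[i00 + ny + 1]
}

# per-frame maximum displacement magnitude of the motion model
motion_speed <- function(motion, w, h, center) {
  switch(motion$kind,
    translation = sqrt(motion$vx^2 + motion$vy^2),
    contraction = abs(motion$strain) * max(w, h) / 2,
    rotation = abs(motion$omega) * sqrt(w^2 + h^2) / 2)
}

#' Generate a synthetic textured video with known motion ground truth
#'
#' Renders `n_frames` frames of a band-limited random texture advected by the
#' spec's motion model, together with the exact per-frame-pair displacement
#' fields and (if voids were requested) the void mask. Same spec and seed
#' give bit-identical output.
#'
#' @param spec A [video_spec()].
#' @return A list with `frames` (array `[y, x, t]`, intensities in `[0, 1]`
#'   before noise), `truth` (list with `flow_fields`, one `(u, v)` pair per
#'   consecutive frame pair in px/frame, and `void_mask`), and `spec`.
#' @examples
#' v <- gen_video(video_spec(motion = motion_translation(2, 0), noise_sd = 0))
#' v$truth$flow_fields[[1]]$u[1:2, 1:2]  # uniformly 2
#' @export
gen_video <- function(spec) {
  stopifnot(inherits(spec, "video_spec"))
  w <- spec$width_px; h <- spec$height_px; n <- spec$n_frames
  motion <- spec$motion
  center <- motion$center %||% c((w + 1) / 2, (h + 1) / 2)

  speed <- motion_speed(motion, w, h, center)
  if (speed > spec$texture_scale / 2)
    warn(sprintf(
      "per-frame displacement (%.2f px) exceeds texture_scale/2 (%.2f px); flow estimation may be ill-posed",
      speed, spec$texture_scale / 2))

  pad <- ceiling(speed * (n - 1)) + ceiling(2 * spec$texture_scale) + 4L
  cw <- w + 2L * pad; ch <- h + 2L * pad

  withr::with_seed(spec$seed, {
    canvas <- matrix(rnorm(ch * cw), ch, cw)
    canvas <- as.matrix(EBImage::gblur(canvas, sigma = spec$texture_scale / 2))
    # tissue texture stays well above the void intensity so that brightness
    # separates the two, as in backlit video of a printed construct
    canvas <- 0.55 + 0.15 * (canvas - mean(canvas)) / sd(canvas)
    canvas <- pmin(pmax(canvas, 0.2), 0.95)

    void_mask <- matrix(FALSE, h, w)
    if (!is.null(spec$voids)) {
      for (r in spec$voids) {
        xs <- max(1, round(r[1])):min(w, round(r[2]))
        ys <- max(1, round(r[3])):min(h, round(r[4]))
        void_mask[ys, xs] <- TRUE
        canvas[ys + pad, xs + pad] <- 0.05
      }
    }

    px <- rep(seq_len(w), each = h)   # column-major [y, x]
    py <- rep(seq_len(h), times = w)
    xy <- cbind(px, py)

    frames <- array(0, dim = c(h, w, n))
    for (t in seq_len(n)) {
      src <- motion_map(motion, t - 1L, xy, center, inverse = TRUE)
      vals <- bilinear_sample(canvas, src[, 1] + pad, src[, 2] + pad)
      fr <- matrix(vals, h, w)
      if (spec$noise_sd > 0)
        fr <- fr + matrix(rnorm(h * w, sd = spec$noise_sd), h, w)
      frames[, , t] <- fr
    }

    flow_fields <- vector("list", n - 1L)
    for (t in seq_len(n - 1L)) {
      src <- motion_map(motion, t - 1L, xy, center, inverse = TRUE)
      dst <- motion_map(motion, t, src, center, inverse = FALSE)
      flow_fields[[t]] <- list(u = matrix(dst[, 1] - px, h, w),
                               v = matrix(dst[, 2] - py, h, w))
    }

    list(frames = frames,
         truth = list(flow_fields = flow_fields, void_mask = void_mask),
         spec = spec)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
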