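# Shared fixtures built in code.

# tiny free bar, all elements contractile: closed-form equilibrium is the
# rest shape scaled by (1 - strain) along z
bar_mesh <- function(length = 10, width = 1, height = 1, h = 0.5,
                     contractile = "all") {
  hex_box_mesh(length = length, width = width, height = height, h = h,
               contractile = contractile)
}

quick_actuation <- function(strain = 0.1, dt = 0.02, duration = 0.2, ...) {
  actuation_spec(strain = strain, dt = dt, duration = duration, ...)
}

# flow field wrapper around plain u/v matrices
make_flow <- function(u, v, pixel_size = 10, frame_interval = 1 / 25) {
  structure(list(u = u, v = v, pixel_size = pixel_size,
                 frame_interval = frame_interval), class = "flow_field")
}

# hand-built three-tube scene: tube 1 positive, tube 2 negative, tube 3
# positive; one nucleus in each tube plus one on background
toy_scene <- function() {
  lab <- matrix(0L, 40, 40)
  lab[5:10, 2:30] <- 1L
  lab[20:25, 2:30] <- 2L
  lab[32:37, 2:30] <- 3L
  structure(list(
    tube_labels = lab,
    marker_positive = c(TRUE, FALSE, TRUE),
    nuclei = tibble::tibble(x = c(10, 10, 10, 35), y = c(7, 22, 34, 15)),
    reference_axis = c(1, 0),
    pixel_size = 2), class = "morphometry_scene")
}

# rectangle mask rotated by `angle_deg` (display convention) in a square image
rotated_rect_mask <- function(n = 200, len = 140, wid = 20, angle_deg = 30,
                              ref = c(1, 0)) {
  xg <- matrix(rep(seq_len(n), each = n), n, n)
  yg <- matrix(rep(seq_len(n), times = n), n, n)
  # display angle theta: image-coordinate direction (cos, -sin)
  ax <- c(cos(angle_deg * pi / 180), -sin(angle_deg * pi / 180))
  c0 <- (n + 1) / 2
  al <- (xg - c0) * ax[1] + (yg - c0) * ax[2]
  ac <- -(xg - c0) * ax[2] + (yg - c0) * ax[1]
  abs(al) <= len / 2 & abs(ac) <= wid / 2
}

scene_from_mask <- function(mask, ref = c(1, 0), pixel_size = 2) {
  structure(list(tube_labels = matrix(as.integer(mask), nrow(mask)),
                 marker_positive = TRUE,
                 nuclei = tibble::tibble(x = ncol(mask) / 2,
                                         y = nrow(mask) / 2),
                 reference_axis = ref / sqrt(sum(ref^2)),
                 pixel_size = pixel_size),
            class = "morphometry_scene")
}

interior_epe <- function(flow, truth, margin = 8) {
  e <- sqrt((flow$u - truth$u)^2 + (flow$v - truth$v)^2)
  ny <- nrow(e); nx <- ncol(e)
  mean(e[(margin + 1):(ny - margin), (margin + 1):(nx - margin)])
}
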