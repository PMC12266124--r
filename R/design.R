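#' Parameterize a muscle-tendon-unit (MTU) construct design
#'
#' An MTU construct is a rectangular block (default 6 mm wide, 3 mm high,
#' 15 mm long) whose central section is contractile muscle and whose two ends
#' are tendon-mimicking anchors, each pierced by a 2 mm x 1 mm rectangular
#' anchor hole. The muscle section is either *compact* (one solid slab,
#' `n_bridges = 1`) or *sparse*: split into `n_bridges` parallel bridges of
#' width `bridge_width` separated by `bridge_gap`, which increases the surface
#' area available for tissue formation. The muscle-tendon interface is
#' interdigitated with invagination radius `interdigitation_radius`.
#'
#' Coordinates: origin at the construct center, z along the long (contraction)
#' axis, x across the width, y across the height; units mm.
#'
#' @param length Total construct length (mm).
#' @param width Construct width (mm).
#' @param height Construct height (mm).
#' @param n_bridges Number of parallel muscle bridges (1 = compact design).
#' @param bridge_width Width of each bridge (mm). Defaults to `width` for the
#'   compact design and to `width / (2 * n_bridges - 1)` (equal bridges and
#'   gaps) for sparse designs.
#' @param bridge_gap Gap between adjacent bridges (mm). Defaults to an equal
#'   split of the leftover width.
#' @param muscle_length Length of the central muscle section (mm).
#' @param anchor_hole Anchor hole size, `c(across_width, along_length)` mm.
#' @param interdigitation_radius Invagination radius r_i of the
#'   muscle-tendon interface (mm).
#' @return An object of class `mtu_design` (a named list of resolved
#'   parameters).
#' @examples
#' mtu_design()                      # compact design
#' mtu_design(n_bridges = 4)         # sparse four-bridged design
#' @export
mtu_design <- function(length = 15, width = 6, height = 3,
                       n_bridges = 1L, bridge_width = NULL, bridge_gap = NULL,
                       muscle_length = 9, anchor_hole = c(2, 1),
                       interdigitation_radius = 0.8) {
  stop_if_not_scalar_pos(length, "length")
  stop_if_not_scalar_pos(width, "width")
  stop_if_not_scalar_pos(height, "height")
  stop_if_not_scalar_pos(muscle_length, "muscle_length")
  if (muscle_length >= length)
    abort("`muscle_length` must be smaller than `length`")
  n_bridges <- as.integer(n_bridges)
  if (is.na(n_bridges) || n_bridges < 1L)
    abort("`n_bridges` must be an integer >= 1")

  if (is.null(bridge_width))
    bridge_width <- if (n_bridges == 1L) width else width / (2 * n_bridges - 1)
  stop_if_not_scalar_pos(bridge_width, "bridge_width")
  if (is.null(bridge_gap)) {
    bridge_gap <- if (n_bridges == 1L) 0
                  else max(0, (width - n_bridges * bridge_width) / (n_bridges - 1))
  }
  if (n_bridges == 1L) bridge_gap <- 0
  if (bridge_gap < 0 || !is.finite(bridge_gap))
    abort("`bridge_gap` must be non-negative")

  span <- n_bridges * bridge_width + (n_bridges - 1) * bridge_gap
  if (span > width + 1e-9)
    abort(sprintf(
      "bridges overflow the construct width: %d x %.3g mm + %d gaps x %.3g mm = %.3g mm > width %.3g mm",
      n_bridges, bridge_width, n_bridges - 1L, bridge_gap, span, width))

  if (length(anchor_hole) != 2L || any(anchor_hole <= 0))
    abort("`anchor_hole` must be two positive sizes (mm)")
  if (anchor_hole[1] >= width || anchor_hole[2] >= (length - muscle_length) / 2)
    abort("anchor hole does not fit inside the anchor")

  stop_if_not_scalar_pos(interdigitation_radius, "interdigitation_radius")
  if (interdigitation_radius >= muscle_length / 2)
    abort("`interdigitation_radius` must be < muscle_length / 2")

  structure(list(
    length = length, width = width, height = height,
    n_bridges = n_bridges, bridge_width = bridge_width,
    bridge_gap = bridge_gap, muscle_length = muscle_length,
    anchor_hole = as.numeric(anchor_hole),
    interdigitation_radius = interdigitation_radius
  ), class = "mtu_design")
}

#' @export
print.mtu_design <- function(x, ...) {
  kind <- if (x$n_bridges == 1L) "compact" else sprintf("sparse (%d bridges)", x$n_bridges)
  cat(sprintf("<mtu_design> %s, %.3g x %.3g x %.3g mm\n", kind,
              x$width, x$height, x$length))
  if (x$n_bridges > 1L)
    cat(sprintf("  bridges: %.3g mm wide, %.3g mm gaps\n",
                x$bridge_width, x$bridge_gap))
  cat(sprintf("  muscle section %.3g mm, r_i %.3g mm, anchor holes %.3g x %.3g mm\n",
              x$muscle_length, x$interdigitation_radius,
              x$anchor_hole[1], x$anchor_hole[2]))
  invisible(x)
}

#' x-intervals covered by the muscle bridges
#' @noRd
bridge_intervals <- function(design) {
  n <- design$n_bridges
  span <- n * design$bridge_width + (n - 1) * design$bridge_gap
  x0 <- -span / 2 + (seq_len(n) - 1) * (design$bridge_width + design$bridge_gap)
  cbind(lo = x0, hi = x0 + design$bridge_width)
}

#' Exterior surface area of the muscle section
#'
#' Closed-form total exterior area of the muscle section: each of the
#' `n_bridges` bridges is a box `bridge_width x height x muscle_length`, and
#' the area is the sum of the six box faces over all bridges. Splitting a slab
#' into more bridges at fixed total bridge width strictly increases the area
#' (internal faces become exterior), which is the design rationale for the
#' sparse geometry.
#'
#' @param design An [mtu_design()].
#' @return Surface area in mm^2.
#' @examples
#' surface_area(mtu_design())               # compact 6 x 3 x 9 slab
#' surface_area(mtu_design(n_bridges = 4))  # sparse: larger
#' @export
surface_area <- function(design) {
  stopifnot(inherits(design, "mtu_design"))
  a <- design$bridge_width
  b <- design$height
  c <- design$muscle_length
  design$n_bridges * 2 * (a * b + a * c + b * c)
}

#' Interpenetration of muscle and tendon at the interface
#'
#' Fraction of the total construct length over which the two printed tissues
#' interpenetrate at the interdigitated interface, `100 * r_i / L` percent.
#'
#' @param r_i Invagination (interdigitation) radius, mm.
#' @param L Total construct length, mm.
#' @return Percent of total length.
#' @examples
#' interdigitation_fraction(0.8, 15)  # ~5.33 %
#' @export
interdigitation_fraction <- function(r_i, L) {
  stop_if_not_scalar_pos(r_i, "r_i")
  stop_if_not_scalar_pos(L, "L")
  if (r_i >= L) abort("`r_i` must be smaller than the construct length `L`")
  100 * r_i / L
}
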