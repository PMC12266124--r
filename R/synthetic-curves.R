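# Synthetic mechanics curves with known ground truth: the Hertz forward model
# for spherical indentation and a linear-elastic tensile response with a
# fracture point.

#' Hertz forward model for a rigid spherical indenter
#'
#' `F = (4/3) * (E / (1 - nu^2)) * sqrt(R) * delta^(3/2)` (rigid indenter on
#' an elastic half-space). Inputs in kPa / um, output in uN.
#'
#' @param depth_um Indentation depth(s), um.
#' @param E_kPa Sample Young's modulus, kPa.
#' @param nu Sample Poisson ratio.
#' @param R_um Indenter radius, um.
#' @return Force(s), uN.
#' @export
hertz_force <- function(depth_um, E_kPa, nu = 0.4, R_um = 100) {
  E_star <- E_kPa * 1e3 / (1 - nu^2)                      # Pa
  f_N <- (4 / 3) * E_star * sqrt(R_um * 1e-6) * (depth_um * 1e-6)^1.5
  f_N * 1e6
}

#' Generate a synthetic spherical-indentation curve
#'
#' Samples the Hertz forward model on an even depth grid up to `d_max_um`,
#' optionally adding Gaussian force noise. The maximum depth is restricted to
#' 10% of the indenter radius, the validity bound used when acquiring the
#' real curves (R = 100 um, d_max = 10 um).
#'
#' @param E_kPa Ground-truth Young's modulus, kPa.
#' @param nu Poisson ratio.
#' @param R_um Indenter radius, um.
#' @param d_max_um Maximum indentation depth, um (must be <= 0.1 * R).
#' @param n_points Number of samples.
#' @param noise_sd_uN Gaussian force noise SD, uN.
#' @param condition `"immersed"` or `"air"` (metadata only).
#' @param seed Integer seed.
#' @return An `indentation_curve` tibble with columns `depth_um`, `force_uN`
#'   and attributes `R_um`, `condition`.
#' @examples
#' gen_indentation_curve(158.9)
#' @export
gen_indentation_curve <- function(E_kPa, nu = 0.4, R_um = 100, d_max_um = 10,
                                  n_points = 100L, noise_sd_uN = 0,
                                  condition = c("immersed", "air"),
                                  seed = 1L) {
  stop_if_not_scalar_pos(E_kPa, "E_kPa")
  if (nu < 0 || nu >= 0.5) abort("`nu` must lie in [0, 0.5)")
  stop_if_not_scalar_pos(R_um, "R_um")
  if (d_max_um <= 0 || d_max_um > 0.1 * R_um)
    abort("`d_max_um` must lie in (0, 0.1 * R]: the Hertz model is only valid for shallow indentation")
  condition <- match.arg(condition)
  depth <- seq(0, d_max_um, length.out = n_points)
  force <- hertz_force(depth, E_kPa, nu, R_um)
  if (noise_sd_uN > 0)
    force <- force + withr::with_seed(seed, rnorm(n_points, sd = noise_sd_uN))
  new_indentation_curve(depth, force, R_um, condition)
}

new_indentation_curve <- function(depth_um, force_uN, R_um, condition) {
  out <- tibble::tibble(depth_um = depth_um, force_uN = force_uN)
  structure(out, R_um = R_um, condition = condition,
            class = c("indentation_curve", class(out)))
}

#' Generate a synthetic tensile force-displacement curve
#'
#' Linear-elastic loading `F = E * A * (x / L0)` up to the fracture strain,
#' followed by a drop to near zero. Noise is added to the pre-fracture
#' samples only. Default geometry matches the tested constructs (6 x 3 mm
#' cross-section, 15 mm gauge length).
#'
#' @param E_kPa Ground-truth elastic modulus, kPa.
#' @param cross_section_mm2 Cross-sectional area, mm^2.
#' @param gauge_length_mm Gauge length, mm.
#' @param fracture_strain Strain at fracture (dimensionless, < 1).
#' @param n_points Pre-fracture samples.
#' @param noise_sd_mN Gaussian force noise SD, mN.
#' @param seed Integer seed.
#' @return A `tensile_curve` tibble with columns `displacement_mm`,
#'   `force_mN` and attributes `cross_section_mm2`, `gauge_length_mm`.
#' @examples
#' gen_tensile_curve(61.5, fracture_strain = 0.156)
#' @export
gen_tensile_curve <- function(E_kPa, cross_section_mm2 = 18,
                              gauge_length_mm = 15, fracture_strain = 0.156,
                              n_points = 200L, noise_sd_mN = 0, seed = 1L) {
  stop_if_not_scalar_pos(E_kPa, "E_kPa")
  stop_if_not_scalar_pos(cross_section_mm2, "cross_section_mm2")
  stop_if_not_scalar_pos(gauge_length_mm, "gauge_length_mm")
  if (fracture_strain <= 0 || fracture_strain >= 1)
    abort("`fracture_strain` must lie in (0, 1)")
  strain <- seq(0, fracture_strain, length.out = n_points)
  force <- E_kPa * cross_section_mm2 * strain      # kPa * mm^2 = mN
  if (noise_sd_mN > 0)
    force <- force + withr::with_seed(seed, rnorm(n_points, sd = noise_sd_mN))
  peak <- E_kPa * cross_section_mm2 * fracture_strain
  # post-fracture tail: force collapses to a few permille of the peak
  post_strain <- fracture_strain + seq_len(3L) * fracture_strain / n_points
  strain <- c(strain, post_strain)
  force <- c(force, rep(0.002 * peak, 3L))
  new_tensile_curve(strain * gauge_length_mm, force, cross_section_mm2,
                    gauge_length_mm)
}

new_tensile_curve <- function(displacement_mm, force_mN, cross_section_mm2,
                              gauge_length_mm) {
  out <- tibble::tibble(displacement_mm = displacement_mm, force_mN = force_mN)
  structure(out, cross_section_mm2 = cross_section_mm2,
            gauge_length_mm = gauge_length_mm,
            class = c("tensile_curve", class(out)))
}
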