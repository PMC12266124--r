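# Tissue mechanics: Hertzian microindentation fitting, tensile summaries and
# the derived arithmetic metrics (fold change, tissue-specific force,
# fracture-area fraction).

#' Fit Young's modulus from a spherical-indentation curve (Hertz model)
#'
#' Least-squares fit of `F = (4/3) * E* * sqrt(R) * delta^(3/2)` with
#' `E* = E / (1 - nu^2)` (rigid indenter: the cubic-zirconia sphere is many
#' orders of magnitude stiffer than kPa-scale tissue, so its compliance is
#' neglected). The model is linear in `E` after the `delta^(3/2)` transform,
#' so the fit is closed form:
#' `c = sum(F * delta^1.5) / sum(delta^3)`, `E = (3/4) * c * (1 - nu^2) / sqrt(R)`.
#' An optional two-parameter variant also fits a contact-point offset
#' `delta0` by a bounded one-dimensional search.
#'
#' @param curve An `indentation_curve` (tibble with `depth_um`, `force_uN`
#'   and attribute `R_um`), e.g. from [gen_indentation_curve()] or
#'   [read_indentation_csv()].
#' @param nu Poisson ratio assumed for the sample.
#' @param fit_contact_point If `TRUE`, also estimate the contact-point
#'   offset; default off (curves are assumed zeroed at contact).
#' @return A `hertz_fit` object; see [tidy()] and [glance()] methods.
#'   `$E_kPa` is the fitted modulus.
#' @examples
#' fit_hertz(gen_indentation_curve(158.9))$E_kPa
#' @export
fit_hertz <- function(curve, nu = 0.4, fit_contact_point = FALSE) {
  stopifnot(is.data.frame(curve),
            all(c("depth_um", "force_uN") %in% names(curve)))
  R_um <- attr(curve, "R_um") %||% 100
  if (nrow(curve) < 5L) abort("need at least 5 samples to fit")
  if (any(curve$depth_um < 0) || is.unsorted(curve$depth_um))
    abort("depths must be non-negative and non-decreasing")
  if (max(curve$depth_um) > 0.1 * R_um)
    abort(sprintf(
      "maximum depth %.3g um exceeds 10%% of the indenter radius (%.3g um): outside Hertz validity",
      max(curve$depth_um), R_um))
  if (all(abs(curve$force_uN) < 1e-15)) abort("degenerate all-zero force curve")

  d_m <- curve$depth_um * 1e-6
  f_N <- curve$force_uN * 1e-6
  R_m <- R_um * 1e-6

  fit_c <- function(delta0_m) {
    d <- pmax(d_m - delta0_m, 0)
    x <- d^1.5
    cc <- sum(f_N * x) / sum(x^2)
    rss <- sum((f_N - cc * x)^2)
    list(c = cc, rss = rss, x = x)
  }
  delta0_m <- 0
  if (fit_contact_point) {
    bound <- 0.2 * max(d_m)
    opt <- optimize(function(d0) fit_c(d0)$rss, c(-bound, bound),
                    tol = bound * 1e-6)
    delta0_m <- opt$minimum
  }
  ft <- fit_c(delta0_m)
  E_star <- ft$c * 3 / (4 * sqrt(R_m))                    # Pa
  E_kPa <- E_star * (1 - nu^2) / 1e3
  if (!is.finite(E_kPa) || E_kPa <= 0)
    abort("fitted Young's modulus is non-positive (non-physical curve)")
  tss <- sum((f_N - mean(f_N))^2)
  r2 <- if (tss > 0) 1 - ft$rss / tss else NA_real_
  structure(list(E_kPa = E_kPa, nu = nu, R_um = R_um,
                 delta0_um = delta0_m * 1e6, r2 = r2,
                 residual_sd_uN = sqrt(ft$rss / nrow(curve)) * 1e6,
                 n = nrow(curve), curve = curve),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> E = %.4g kPa (nu = %.2g, R = %.3g um), R^2 = %.4f\n",
              x$E_kPa, x$nu, x$R_um, x$r2))
  invisible(x)
}

#' @rdname fit_hertz
#' @param x A `hertz_fit`.
#' @param ... Unused.
#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble::tibble(term = c("E_kPa", "delta0_um"),
                 estimate = c(x$E_kPa, x$delta0_um))
}

#' @rdname fit_hertz
#' @export
glance.hertz_fit <- function(x, ...) {
  tibble::tibble(E_kPa = x$E_kPa, r2 = x$r2,
                 residual_sd_uN = x$residual_sd_uN, n = x$n)
}

#' @export
autoplot.hertz_fit <- function(object, ...) {
  cv <- object$curve
  pred <- tibble::tibble(
    depth_um = seq(0, max(cv$depth_um), length.out = 200))
  pred$force_uN <- hertz_force(pmax(pred$depth_um - object$delta0_um, 0),
                               object$E_kPa, object$nu, object$R_um)
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$depth_um, y = .data$force_uN)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = pred, colour = "red") +
    ggplot2::labs(x = "depth (um)", y = "force (uN)") +
    ggplot2::theme_minimal()
}

#' Elastic modulus and fracture point from a tensile curve
#'
#' Converts force-displacement to stress-strain using the cross-section and
#' gauge length, fits the elastic modulus as the stress-strain slope within
#' `linear_region`, and detects fracture as the first sample at which the
#' force drops below 50% of its running maximum; the fracture point is the
#' last sample before the drop. A monotone curve without such a drop yields
#' `NA` fracture fields (the modulus is still fitted).
#'
#' @param curve A `tensile_curve` (tibble with `displacement_mm`, `force_mN`
#'   and attributes `cross_section_mm2`, `gauge_length_mm`).
#' @param linear_region Strain window for the modulus fit (default 2-10%).
#' @param drop_fraction Running-max drop fraction defining fracture.
#' @return A `tensile_fit` with `E_kPa`, `fracture_force_mN`,
#'   `fracture_strain_pct` (percent elongation); see [glance()].
#' @examples
#' glance(tensile_summary(gen_tensile_curve(27.2, fracture_strain = 0.261)))
#' @export
tensile_summary <- function(curve, linear_region = c(0.02, 0.10),
                            drop_fraction = 0.5) {
  stopifnot(is.data.frame(curve),
            all(c("displacement_mm", "force_mN") %in% names(curve)))
  A <- attr(curve, "cross_section_mm2") %||% abort("missing cross_section_mm2")
  L0 <- attr(curve, "gauge_length_mm") %||% abort("missing gauge_length_mm")
  stop_if_not_scalar_pos(A, "cross_section_mm2")
  stop_if_not_scalar_pos(L0, "gauge_length_mm")

  strain <- curve$displacement_mm / L0
  stress_kPa <- curve$force_mN / A       # mN / mm^2 = kPa

  win <- strain >= linear_region[1] & strain <= linear_region[2]
  if (sum(win) < 2L) win <- strain <= max(strain) / 2   # degenerate short curves
  if (sum(win) < 2L) win <- rep(TRUE, length(strain))
  fit <- lm(stress_kPa[win] ~ strain[win])
  E_kPa <- unname(coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)

  runmax <- cummax(curve$force_mN)
  # only drops from a substantial load count: early low-force samples sit at
  # the noise floor and must not trigger the detector
  dropped <- which(curve$force_mN < drop_fraction * runmax &
                     runmax > 0.1 * max(curve$force_mN))
  if (length(dropped) > 0L && dropped[1] > 1L) {
    i <- dropped[1] - 1L
    frac_force <- curve$force_mN[i]
    frac_strain_pct <- 100 * strain[i]
  } else {
    frac_force <- NA_real_
    frac_strain_pct <- NA_real_
  }
  structure(list(E_kPa = E_kPa, r2 = r2, fracture_force_mN = frac_force,
                 fracture_strain_pct = frac_strain_pct,
                 fracture_detected = !is.na(frac_force),
                 linear_region = linear_region, n = nrow(curve),
                 curve = curve),
            class = "tensile_fit")
}

#' @export
print.tensile_fit <- function(x, ...) {
  cat(sprintf("<tensile_fit> E = %.4g kPa", x$E_kPa))
  if (x$fracture_detected)
    cat(sprintf(", fracture at %.4g mN / %.3g%% elongation",
                x$fracture_force_mN, x$fracture_strain_pct))
  else cat(", no fracture detected")
  cat("\n")
  invisible(x)
}

#' @rdname tensile_summary
#' @param x A `tensile_fit`.
#' @param ... Unused.
#' @export
tidy.tensile_fit <- function(x, ...) {
  tibble::tibble(
    term = c("E_kPa", "fracture_force_mN", "fracture_strain_pct"),
    estimate = c(x$E_kPa, x$fracture_force_mN, x$fracture_strain_pct))
}

#' @rdname tensile_summary
#' @export
glance.tensile_fit <- function(x, ...) {
  tibble::tibble(E_kPa = x$E_kPa, r2 = x$r2,
                 fracture_force_mN = x$fracture_force_mN,
                 fracture_strain_pct = x$fracture_strain_pct, n = x$n)
}

#' @export
autoplot.tensile_fit <- function(object, ...) {
  cv <- object$curve
  p <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$displacement_mm,
                                        y = .data$force_mN)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "displacement (mm)", y = "force (mN)") +
    ggplot2::theme_minimal()
  if (object$fracture_detected)
    p <- p + ggplot2::geom_point(
      data = cv[which.min(abs(cv$force_mN - object$fracture_force_mN)), ],
      colour = "red", size = 2)
  p
}

#' Fold change between two measurements
#'
#' @param a,b Values; returns `a / b`.
#' @return The ratio.
#' @examples
#' fold_change(245, 145)      # force output vs full-muscle control, ~1.7
#' fold_change(158.9, 47.23)  # anchor vs bioactuator stiffness, ~3.4
#' @export
fold_change <- function(a, b) {
  if (any(!is.finite(b)) || any(b <= 0)) abort("`b` must be positive")
  a / b
}

#' Tissue-specific force
#'
#' Contractile force output normalized by the active tissue surface area.
#'
#' @param force_uN Measured force, uN.
#' @param area_mm2 Surface area of the contributing tissue, mm^2.
#' @return Force per area, uN/mm^2.
#' @export
tissue_specific_force <- function(force_uN, area_mm2) {
  if (any(!is.finite(area_mm2)) || any(area_mm2 <= 0))
    abort("`area_mm2` must be positive")
  force_uN / area_mm2
}

#' Fracture-area fraction of the muscle tissue
#'
#' Percentage of the muscle tissue area that is fragmented or damaged after
#' a tensile test. The damaged mask is intersected with the tissue mask.
#'
#' @param damaged_mask,tissue_mask Logical matrices of equal shape.
#' @return Percent of the tissue area.
#' @export
fracture_area_fraction <- function(damaged_mask, tissue_mask) {
  stopifnot(is.logical(damaged_mask) || is.numeric(damaged_mask),
            all(dim(damaged_mask) == dim(tissue_mask)))
  tissue <- tissue_mask > 0
  if (!any(tissue)) abort("empty tissue mask")
  100 * sum(damaged_mask > 0 & tissue) / sum(tissue)
}
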