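test_that("noiseless Hertz round trip recovers E to machine precision", {
  for (E in c(47.23, 49.7, 158.9)) {
    fit <- fit_hertz(gen_indentation_curve(E, nu = 0.4, noise_sd_uN = 0))
    expect_equal(fit$E_kPa, E, tolerance = 1e-6)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
  }
})

test_that("Hertz fit is invariant to unit rescaling of the curve", {
  cv <- gen_indentation_curve(80, noise_sd_uN = 0)
  fit <- fit_hertz(cv)
  # same physical curve in nm / nN still yields the same modulus when the
  # radius metadata is expressed consistently
  cv_nm <- new_curve <- cv
  cv_nm$depth_um <- cv$depth_um      # depth unchanged; scale force by 1000x
  cv_scaled <- cv
  cv_scaled$force_uN <- cv$force_uN * 1e3
  fit_scaled <- fit_hertz(cv_scaled)
  expect_equal(fit_scaled$E_kPa, 1e3 * fit$E_kPa, tolerance = 1e-12)
})

test_that("Hertz fit rejects degenerate and non-physical curves", {
  cv <- gen_indentation_curve(50, noise_sd_uN = 0)
  cv$force_uN <- 0 * cv$force_uN
  expect_error(fit_hertz(cv), "degenerate")
  cv2 <- gen_indentation_curve(50, noise_sd_uN = 0)
  cv2$force_uN <- -cv2$force_uN
  expect_error(fit_hertz(cv2), "non-positive|non-physical")
  expect_error(fit_hertz(gen_indentation_curve(50)[1:3, ]), "5 samples")
})

test_that("median recovered E over noisy replicates is within 2% and centred", {
  E_true <- 49.7
  fits <- vapply(1:100, function(s) {
    cv <- gen_indentation_curve(E_true, noise_sd_uN = 2, seed = s)
    fit_hertz(cv)$E_kPa
  }, numeric(1))
  expect_lt(abs(median(fits) - E_true) / E_true, 0.02)
  expect_lt(abs(median(fits) - E_true) / E_true, 0.005 + 2 * sd(fits) /
              sqrt(100) / E_true)
})

test_that("contact-point fitting recovers a shifted contact", {
  cv <- gen_indentation_curve(100, noise_sd_uN = 0)
  cv_shift <- cv
  cv_shift$force_uN <- hertz_force(pmax(cv$depth_um - 0.5, 0), 100)
  fit <- fit_hertz(cv_shift, fit_contact_point = TRUE)
  expect_equal(fit$delta0_um, 0.5, tolerance = 0.05)
  expect_equal(fit$E_kPa, 100, tolerance = 0.02)
})

test_that("tensile summary recovers modulus and fracture point exactly", {
  cv <- gen_tensile_curve(27.2, fracture_strain = 0.261, noise_sd_mN = 0)
  ts <- tensile_summary(cv)
  expect_equal(ts$E_kPa, 27.2, tolerance = 1e-9)
  expect_equal(ts$fracture_strain_pct, 26.1, tolerance = 1e-6)
  expect_equal(ts$fracture_force_mN, max(cv$force_mN), tolerance = 1e-9)

  cv2 <- gen_tensile_curve(61.5, fracture_strain = 0.156, noise_sd_mN = 0)
  ts2 <- tensile_summary(cv2)
  expect_equal(ts2$E_kPa, 61.5, tolerance = 1e-9)
  expect_equal(ts2$fracture_strain_pct, 15.6, tolerance = 1e-6)
})

test_that("noisy tensile curves keep the fracture point at the peak", {
  ts <- tensile_summary(gen_tensile_curve(27.2, fracture_strain = 0.261,
                                          noise_sd_mN = 1, seed = 2))
  expect_equal(ts$fracture_strain_pct, 26.1, tolerance = 0.02)
  expect_equal(ts$E_kPa, 27.2, tolerance = 0.05)
  expect_gt(ts$fracture_force_mN, 0.9 * 27.2 * 18 * 0.261)
})

test_that("doubling the cross-section halves the fitted modulus", {
  cv <- gen_tensile_curve(40, cross_section_mm2 = 18, noise_sd_mN = 0)
  cv2 <- cv
  attr(cv2, "cross_section_mm2") <- 36
  expect_equal(tensile_summary(cv2)$E_kPa, tensile_summary(cv)$E_kPa / 2,
               tolerance = 1e-12)
})

test_that("monotone curves yield absent fracture but a fitted modulus", {
  cv <- gen_tensile_curve(30, fracture_strain = 0.3, noise_sd_mN = 0)
  cv_mono <- cv[cv$force_mN > 0.5 * max(cv$force_mN) |
                  cv$displacement_mm < 0.5 * max(cv$displacement_mm), ]
  cv_mono <- cv_mono[order(cv_mono$displacement_mm), ]
  cv_mono <- cv_mono[cv_mono$force_mN >= cummax(cv_mono$force_mN) * 0.999, ]
  ts <- tensile_summary(cv_mono)
  expect_false(ts$fracture_detected)
  expect_true(is.na(ts$fracture_force_mN))
  expect_equal(ts$E_kPa, 30, tolerance = 1e-6)
})

test_that("fold change and tissue-specific force are guarded ratios", {
  expect_equal(fold_change(245, 145), 245 / 145)
  expect_equal(round(fold_change(245, 145), 2), 1.69)
  expect_equal(round(fold_change(158.9, 47.23), 2), 3.36)
  expect_equal(fold_change(7, 7), 1)
  expect_error(fold_change(1, 0), "positive")

  expect_equal(tissue_specific_force(100, 50), 2)
  expect_equal(tissue_specific_force(0, 10), 0)
  expect_equal(tissue_specific_force(3 * 100, 3 * 50),
               tissue_specific_force(100, 50))
  expect_error(tissue_specific_force(10, -1), "positive")
})

test_that("fracture area fraction is an exact pixel count", {
  tissue <- matrix(FALSE, 20, 20); tissue[3:18, 3:18] <- TRUE  # 256 px
  damaged <- matrix(FALSE, 20, 20); damaged[3:10, 3:10] <- TRUE  # 64 px in
  expect_equal(fracture_area_fraction(damaged, tissue), 100 * 64 / 256)
  expect_equal(fracture_area_fraction(tissue, tissue), 100)
  expect_equal(fracture_area_fraction(matrix(FALSE, 20, 20), tissue), 0)
  # damage outside the tissue is clipped by intersection
  damaged_out <- matrix(FALSE, 20, 20); damaged_out[1:2, ] <- TRUE
  expect_equal(fracture_area_fraction(damaged_out, tissue), 0)
  expect_error(fracture_area_fraction(damaged, matrix(FALSE, 20, 20)),
               "empty")
})

test_that("tidy and glance methods return one-row summaries", {
  hf <- fit_hertz(gen_indentation_curve(60, noise_sd_uN = 0))
  expect_s3_class(tidy(hf), "tbl_df")
  expect_equal(glance(hf)$E_kPa, 60, tolerance = 1e-6)
  tf <- tensile_summary(gen_tensile_curve(30))
  expect_named(glance(tf),
               c("E_kPa", "r2", "fracture_force_mN", "fracture_strain_pct",
                 "n"))
  expect_equal(nrow(glance(tf)), 1L)
})
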