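# Flow estimation accuracy is asserted on the interior region where the
# Gaussian integration window has full support; frame borders receive
# content with no correspondence in the other frame.

test_that("identical frames give an (essentially) zero flow field", {
  v <- gen_video(video_spec(seed = 5))
  fr <- v$frames[, , 1]
  fl <- estimate_flow(fr, fr)
  expect_lt(max(sqrt(fl$u^2 + fl$v^2)), 1e-3)
})

test_that("mismatched frame shapes are rejected", {
  expect_error(estimate_flow(matrix(0, 32, 32), matrix(0, 32, 16)),
               "identical dimensions")
})

test_that("translation flow is recovered within the accuracy contract", {
  for (s in c(1, 2, 3)) {
    v <- gen_video(video_spec(motion = motion_translation(2, 0), seed = s))
    fl <- estimate_flow(v$frames[, , 1], v$frames[, , 2])
    expect_lt(interior_epe(fl, v$truth$flow_fields[[1]]), 0.2)
    expect_equal(mean(fl$u), 2, tolerance = 0.1)
    expect_equal(mean(fl$v), 0, tolerance = 0.2)
  }
  # diagonal motion, larger displacement
  v <- gen_video(video_spec(motion = motion_translation(-2.5, 2.5), seed = 4))
  fl <- estimate_flow(v$frames[, , 1], v$frames[, , 2])
  expect_lt(interior_epe(fl, v$truth$flow_fields[[1]], margin = 12), 0.2)
})

test_that("flow error grows monotonically (weakly) with sensor noise", {
  noise <- c(0.005, 0.02, 0.08)
  epe <- vapply(noise, function(ns) {
    v <- gen_video(video_spec(motion = motion_translation(2, 0), seed = 9,
                              noise_sd = ns))
    fl <- estimate_flow(v$frames[, , 1], v$frames[, , 2])
    interior_epe(fl, v$truth$flow_fields[[1]])
  }, numeric(1))
  expect_true(all(diff(epe) > -1e-3))
  expect_gt(epe[3], epe[1])
})

test_that("contraction yields negative flow divergence over the tissue", {
  v <- gen_video(video_spec(motion = motion_contraction(0.01, axis = "x"),
                            seed = 2))
  fl <- estimate_flow(v$frames[, , 1], v$frames[, , 2])
  div <- flow_divergence(fl, smooth_sigma = 12)
  interior <- div[13:116, 13:116]
  expect_gte(mean(interior < 0), 0.95)
})

test_that("directional alignment handles exact, empty and isotropic fields", {
  n <- 50
  th <- 135 * pi / 180
  fl <- make_flow(matrix(cos(th), n, n), matrix(-sin(th), n, n))
  expect_equal(directional_alignment(fl, 135, 22.5)$fraction, 1)

  fl0 <- make_flow(matrix(1, n, n), matrix(0, n, n))   # 0 degrees
  expect_equal(directional_alignment(fl0, 135, 22.5)$fraction, 0)

  # below the magnitude floor nothing is counted
  tiny <- make_flow(matrix(0.01, n, n), matrix(0, n, n))
  out <- directional_alignment(tiny, 0, 22.5, min_magnitude = 0.1)
  expect_equal(out$n_considered, 0L)
  expect_true(is.na(out$fraction))

  set.seed(7)
  ang <- runif(1e4, 0, 2 * pi)
  fli <- make_flow(matrix(cos(ang), 100, 100), matrix(sin(ang), 100, 100))
  fr <- directional_alignment(fli, 135, 22.5)$fraction
  se <- sqrt(0.125 * 0.875 / 1e4)
  expect_lt(abs(fr - 0.125), 4 * se)
})

test_that("disjoint tolerance bins tile the circle and fractions sum to 1", {
  set.seed(11)
  ang <- runif(5000, 0, 2 * pi)
  fl <- make_flow(matrix(cos(ang), 50, 100), matrix(sin(ang), 50, 100))
  centres <- seq(0, 315, by = 45)
  fr <- vapply(centres, function(a)
    directional_alignment(fl, a, 22.5)$fraction, numeric(1))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
})

test_that("kinetic energy matches closed forms and a brute-force oracle", {
  n <- 8
  # uniform 1 mm/s: 1 px/frame at 1000 um/px, 1 s per frame
  fl <- make_flow(matrix(1, n, n), matrix(0, n, n), pixel_size = 1000,
                  frame_interval = 1)
  expect_equal(kinetic_energy(fl, rho = 1000)$Ek_J_per_m3, 5e-4,
               tolerance = 1e-9 / 5e-4)

  # zero flow
  fl0 <- make_flow(matrix(0, n, n), matrix(0, n, n))
  expect_equal(kinetic_energy(fl0)$Ek_J_per_m3, 0)

  # two-region field: half v1, half v2 -> rho (v1^2 + v2^2) / 4
  u <- matrix(0, n, n); u[, 1:(n / 2)] <- 2; u[, (n / 2 + 1):n] <- 3
  fl2 <- make_flow(u, matrix(0, n, n), pixel_size = 1000, frame_interval = 1)
  v1 <- 2e-3; v2 <- 3e-3
  expect_equal(kinetic_energy(fl2, rho = 1000)$Ek_J_per_m3,
               1000 * (v1^2 + v2^2) / 4)
  # brute-force per-pixel summation oracle
  speeds_m <- sqrt(u^2 + 0) * 1000 * 1e-6 / 1
  ek_brute <- sum(1000 / 2 * speeds_m^2) / length(u)
  expect_equal(kinetic_energy(fl2, rho = 1000)$Ek_J_per_m3, ek_brute)

  expect_error(kinetic_energy(fl, mask = matrix(FALSE, n, n)), "no pixels")
})

test_that("kinetic energy ignores image intensities and scales quadratically", {
  v <- gen_video(video_spec(motion = motion_translation(2, 0), seed = 3))
  fl <- estimate_flow(v$frames[, , 1], v$frames[, , 2])
  e1 <- kinetic_energy(fl)$Ek_J_per_m3
  fl_rescaled <- estimate_flow(0.2 + 0.5 * v$frames[, , 1],
                               0.2 + 0.5 * v$frames[, , 2])
  e2 <- kinetic_energy(fl_rescaled)$Ek_J_per_m3
  expect_equal(e2, e1, tolerance = 0.02)

  mask <- matrix(FALSE, 128, 128); mask[13:116, 13:116] <- TRUE
  speeds <- c(0.5, 1, 2, 3)
  ek <- vapply(speeds, function(sp) {
    vv <- gen_video(video_spec(motion = motion_translation(sp, 0), seed = 11))
    kinetic_energy(estimate_flow(vv$frames[, , 1], vv$frames[, , 2]),
                   mask = mask)$Ek_J_per_m3
  }, numeric(1))
  expo <- unname(coef(lm(log(ek) ~ log(speeds)))[2])
  expect_equal(expo, 2, tolerance = 0.05 / 2)
})

test_that("void segmentation finds dark rectangles and nothing in bright frames", {
  bright <- matrix(0.7, 96, 96)
  expect_equal(sum(segment_voids(bright)), 0)

  # one dark rectangle covering ~10% of the frame
  v <- gen_video(video_spec(noise_sd = 0.005,
                            voids = list(c(20, 60, 30, 70)), seed = 2))
  vm <- segment_voids(v$frames[, , 1])
  tm <- v$truth$void_mask
  expect_lt(abs(sum(vm) - sum(tm)) / sum(tm), 0.05)
  expect_gt(sum(vm & tm) / sum(vm | tm), 0.9)

  # polarity symmetry: inverting the image and the threshold stops the
  # rectangle from being segmented as void
  inv <- 1 - v$frames[, , 1]
  vm_inv <- segment_voids(inv)
  expect_lt(sum(vm_inv & tm) / sum(tm), 0.05)
})

test_that("subtraction displacement recovers synthetic shifts in um", {
  a <- gen_video(video_spec(seed = 3, noise_sd = 0.005))$frames[, , 1]
  out0 <- subtraction_displacement(a, a, axis = "x", pixel_size = 2)
  expect_true(all(out0$difference == 0))
  expect_equal(out0$displacement_um, 0, tolerance = 1e-9)

  b <- cbind(a[, 4:128], a[, rep(128, 3)])   # content moves -3 px along x
  out <- subtraction_displacement(a, b, axis = "x", pixel_size = 2)
  expect_equal(out$displacement_um, -6, tolerance = 2 / 6)  # within 1 px

  # the difference image of a shift concentrates at edges
  g <- mtukit:::img_gradients(a)
  band <- sqrt(g$gx^2 + g$gy^2) > stats::quantile(sqrt(g$gx^2 + g$gy^2), 0.5)
  hot <- out$difference > stats::quantile(out$difference, 0.5)
  iou <- sum(hot & band) / sum(hot | band)
  expect_gt(iou, 0.5)

  expect_warning(
    outf <- subtraction_displacement(matrix(0.5, 40, 40),
                                     matrix(0.5, 40, 40), pixel_size = 2),
    "featureless")
  expect_true(is.na(outf$displacement_um))
})

test_that("flow visualization draws the sampled number of arrows", {
  fl <- make_flow(matrix(0.6, 100, 100), matrix(-0.6, 100, 100))
  p <- visualize_flow(fl, sample_fraction = 0.02, seed = 1)
  seg <- ggplot2::layer_data(p, 1)
  expect_equal(nrow(seg), round(100 * 100 * 0.02))
  # uniform field: all arrows same length and same hue
  len <- sqrt((seg$xend - seg$x)^2 + (seg$yend - seg$y)^2)
  expect_equal(diff(range(len)), 0, tolerance = 1e-9)
  expect_equal(length(unique(seg$colour)), 1L)

  p0 <- visualize_flow(fl, background = matrix(0.5, 100, 100),
                       sample_fraction = 0)
  expect_equal(length(p0$layers), 1L)   # background only, no arrows
})
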