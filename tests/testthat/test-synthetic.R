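test_that("same spec and seed give bit-identical videos", {
  sp <- video_spec(motion = motion_translation(1, -1), seed = 42)
  v1 <- gen_video(sp)
  v2 <- gen_video(sp)
  expect_identical(v1$frames, v2$frames)
  expect_identical(v1$truth, v2$truth)
  v3 <- gen_video(video_spec(motion = motion_translation(1, -1), seed = 43))
  expect_false(identical(v1$frames, v3$frames))
})

test_that("translation ground truth is the constant translation vector", {
  v <- gen_video(video_spec(motion = motion_translation(2, 0), noise_sd = 0,
                            n_frames = 3))
  for (fl in v$truth$flow_fields) {
    expect_true(all(fl$u == 2))
    expect_true(all(fl$v == 0))
  }
})

test_that("static video frames are identical up to noise", {
  v0 <- gen_video(video_spec(motion = motion_translation(0, 0), noise_sd = 0,
                             n_frames = 2))
  expect_equal(v0$frames[, , 1], v0$frames[, , 2], tolerance = 1e-12)
  vn <- gen_video(video_spec(motion = motion_translation(0, 0),
                             noise_sd = 0.02, n_frames = 2))
  d <- vn$frames[, , 2] - vn$frames[, , 1]
  expect_equal(sd(as.vector(d)), 0.02 * sqrt(2), tolerance = 0.1)
})

test_that("uniaxial contraction truth follows the affine closed form", {
  st <- 0.01
  v <- gen_video(video_spec(motion = motion_contraction(st, axis = "x"),
                            n_frames = 3, width_px = 64, height_px = 64))
  c0 <- (64 + 1) / 2
  fl <- v$truth$flow_fields[[1]]
  xs <- matrix(rep(seq_len(64), each = 64), 64, 64)
  expect_equal(fl$u, -st * (xs - c0), tolerance = 1e-12)
  expect_true(all(fl$v == 0))
  # later pairs follow the same per-pair rule (flow depends on current pos)
  fl2 <- v$truth$flow_fields[[2]]
  expect_equal(fl2$u, -st * (xs - c0), tolerance = 1e-12)
})

test_that("ground-truth flow of composed translations adds vectorially", {
  u1 <- gen_video(video_spec(motion = motion_translation(1.5, 0),
                             noise_sd = 0))$truth$flow_fields[[1]]
  u2 <- gen_video(video_spec(motion = motion_translation(0, -2),
                             noise_sd = 0))$truth$flow_fields[[1]]
  u12 <- gen_video(video_spec(motion = motion_translation(1.5, -2),
                              noise_sd = 0))$truth$flow_fields[[1]]
  expect_equal(u12$u, u1$u + u2$u)
  expect_equal(u12$v, u1$v + u2$v)
})

test_that("large per-frame displacement triggers the ill-posedness warning", {
  expect_warning(gen_video(video_spec(motion = motion_translation(5, 0),
                                      texture_scale = 8)), "ill-posed")
})

test_that("void rectangles are dark and recorded in the mask", {
  v <- gen_video(video_spec(voids = list(c(20, 50, 30, 60)), noise_sd = 0))
  tm <- v$truth$void_mask
  expect_equal(sum(tm), 31 * 31)
  expect_true(all(v$frames[, , 1][tm] < 0.1))
  expect_true(mean(v$frames[, , 1][!tm]) > 0.3)
})

test_that("Hertz generator matches the closed-form force", {
  cv <- gen_indentation_curve(158.9, nu = 0.4, R_um = 100, d_max_um = 10,
                              noise_sd_uN = 0)
  # F(10 um) = (4/3) * (158.9 kPa / 0.84) * sqrt(100 um) * (10 um)^1.5
  f10 <- (4 / 3) * (158.9e3 / (1 - 0.4^2)) * sqrt(100e-6) * (10e-6)^1.5
  expect_equal(max(cv$force_uN), f10 * 1e6, tolerance = 1e-12)
  expect_equal(f10, 7.97595e-5, tolerance = 1e-5)
  expect_equal(cv$force_uN[1], 0)               # zero contact depth
  expect_true(all(diff(cv$force_uN) > 0))       # monotone noiseless curve
  # force is linear in E
  cv2 <- gen_indentation_curve(2 * 158.9, noise_sd_uN = 0)
  expect_equal(cv2$force_uN, 2 * cv$force_uN)
})

test_that("indentation beyond 10% of the indenter radius is rejected", {
  expect_error(gen_indentation_curve(50, d_max_um = 11, R_um = 100),
               "0.1")
  expect_error(fit_hertz(new_curve <- {
    cv <- gen_indentation_curve(50, d_max_um = 10)
    cv$depth_um <- cv$depth_um * 2
    cv
  }), "Hertz")
})

test_that("tensile generator hits the closed-form peak and slope", {
  cv <- gen_tensile_curve(61.5, cross_section_mm2 = 18, gauge_length_mm = 15,
                          fracture_strain = 0.156, noise_sd_mN = 0)
  expect_equal(max(cv$force_mN), 61.5 * 18 * 0.156, tolerance = 1e-12)
  # recovered slope of the noiseless curve is E * A / L0
  pre <- cv[cv$force_mN > 0.01 * max(cv$force_mN), ]
  slope <- coef(lm(force_mN ~ displacement_mm, pre))[2]
  expect_equal(unname(slope), 61.5 * 18 / 15, tolerance = 1e-9)
  # post-fracture tail is near zero
  expect_lt(min(cv$force_mN[cv$displacement_mm > 0.156 * 15]),
            0.01 * max(cv$force_mN))
})

test_that("morphometry scene places the exact number of fused nuclei", {
  sc <- gen_morphometry_scene(fusion_fraction = 0.25, n_nuclei = 40, seed = 2)
  ny <- nrow(sc$tube_labels)
  lab <- sc$tube_labels[cbind(sc$nuclei$y, sc$nuclei$x)]
  inside_pos <- lab > 0 & sc$marker_positive[pmax(lab, 1)]
  expect_equal(sum(inside_pos), 10L)

  sc1 <- gen_morphometry_scene(fusion_fraction = 1, n_nuclei = 20, seed = 3)
  lab1 <- sc1$tube_labels[cbind(sc1$nuclei$y, sc1$nuclei$x)]
  expect_true(all(lab1 > 0 & sc1$marker_positive[lab1]))
})

test_that("infinite angle concentration aligns all tubes with the axis", {
  sc <- gen_morphometry_scene(angle_concentration = 1e9, n_tubes = 5,
                              seed = 4)
  a <- shift_angles(sc)
  expect_lt(max(a$shift_angle_deg), 1.5)
})
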