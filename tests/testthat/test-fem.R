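# Corotational contraction solver, validated against closed forms on a free
# homogeneous bar: a prescribed strain eps applied to every element puts the
# stress-free equilibrium at the rest shape scaled by (1 - eps) along the
# actuation axis, so the end vertices move eps * L / 2 toward the centre.

test_that("zero strain leaves the mesh at rest", {
  bar <- bar_mesh(h = 0.5)
  tr <- simulate_contraction(bar, actuation = quick_actuation(strain = 0))
  expect_equal(tr$frames[[1]], bar$vertices)
  expect_equal(max_deformation(tr), 0, tolerance = 1e-12)
  expect_equal(length(tr$frames), length(tr$times))
})

test_that("uniform bar contraction matches the closed-form equilibrium", {
  bar <- bar_mesh(length = 10, h = 0.5)
  tr <- simulate_contraction(bar, material_params(E_muscle = 49.7),
                             actuation_spec(strain = 0.1))
  expect_equal(max_deformation(tr), 0.5, tolerance = 0.01 * 0.5)
  zfin <- range(tr$frames[[length(tr$frames)]][, 3])
  expect_equal(diff(zfin), 9, tolerance = 1e-6)
  # transverse dimensions unchanged (stress-free equilibrium, no Poisson)
  xfin <- range(tr$frames[[length(tr$frames)]][, 1])
  expect_equal(diff(xfin), 1, tolerance = 1e-6)
})

test_that("small-strain corotational solve matches linear elasticity", {
  bar <- bar_mesh(length = 10, h = 0.5)
  eps <- 1e-3
  tr <- simulate_contraction(bar, actuation = quick_actuation(strain = eps))
  expect_equal(max_deformation(tr), eps * 10 / 2, tolerance = 0.01 * eps * 5)
})

test_that("max deformation is invariant to rigid drift of the final frame", {
  bar <- bar_mesh(h = 0.5)
  tr <- simulate_contraction(bar, actuation = quick_actuation(strain = 0))
  # translate and rotate the final frame rigidly: metric must stay 0
  th <- 0.3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr$frames[[length(tr$frames)]] <-
    sweep(bar$vertices %*% t(R), 2, c(1, -2, 0.5), "+")
  expect_lt(max_deformation(tr), 1e-8)
})

test_that("solution is objective under rotation of the rest mesh", {
  bar <- bar_mesh(length = 6, h = 0.5)
  act <- quick_actuation(strain = 0.08)
  d0 <- max_deformation(simulate_contraction(bar, actuation = act))
  th <- 0.7
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  bar_rot <- bar
  bar_rot$vertices <- bar$vertices %*% t(R)
  d1 <- max_deformation(simulate_contraction(bar_rot, actuation = act))
  expect_equal(d1, d0, tolerance = 1e-4)
})

test_that("surface-only actuation lies strictly between none and full", {
  bar <- hex_box_mesh(length = 6, width = 1.5, height = 1.5, h = 0.5,
                      contractile = "surface")
  act <- quick_actuation(strain = 0.1)
  d_surf <- max_deformation(simulate_contraction(bar, actuation = act))
  full <- hex_box_mesh(length = 6, width = 1.5, height = 1.5, h = 0.5,
                       contractile = "all")
  d_full <- max_deformation(simulate_contraction(full, actuation = act))
  expect_gt(d_surf, 0)
  expect_lt(d_surf, d_full)
  expect_equal(d_full, 0.1 * 6 / 2, tolerance = 1e-3)
})

test_that("equilibrium residual meets the convergence tolerance", {
  bar <- bar_mesh(h = 0.5)
  tr <- simulate_contraction(bar, actuation = quick_actuation(strain = 0.1))
  expect_lt(tr$residual, tr$control$tol)
})

test_that("potential energy decreases across settle iterations", {
  bar <- hex_box_mesh(length = 6, width = 1.5, height = 1.5, h = 0.5,
                      contractile = "surface")
  tr <- simulate_contraction(bar, actuation = actuation_spec(
    strain = 0.1, duration = 0.05, dt = 0.05, ramp = "step"))
  en <- tr$settle_energy
  expect_gte(length(en), 2)
  expect_true(all(diff(en) <= 1e-9 * max(abs(en))))
})

test_that("bar deformation is mesh-converged at the working resolution", {
  # the contractile shell is kept at 0.5 mm physical thickness while the
  # element size is halved
  act <- quick_actuation(strain = 0.1)
  d_coarse <- max_deformation(simulate_contraction(
    hex_box_mesh(6, 1.5, 1.5, h = 0.5, contractile = "surface",
                 surface_layers = 1L),
    actuation = act))
  d_fine <- max_deformation(simulate_contraction(
    hex_box_mesh(6, 1.5, 1.5, h = 0.25, contractile = "surface",
                 surface_layers = 2L),
    actuation = act))
  expect_lt(abs(d_fine - d_coarse) / d_coarse, 0.02)
})

test_that("empty contractile set with positive strain is rejected", {
  bar <- hex_box_mesh(length = 4, width = 1, height = 1, h = 0.5,
                      contractile = "none")
  expect_error(simulate_contraction(bar, actuation = quick_actuation(0.1)),
               "contractile")
})

test_that("a single-cell sweep equals a direct simulation", {
  act <- quick_actuation(strain = 0.1)
  sw <- design_sweep(n_bridges = 2L, bridge_widths = 1.5, h = 0.75,
                     bridge_gap = 0.75, actuation = act)
  expect_equal(nrow(sw), 1L)
  d <- mtu_design(n_bridges = 2, bridge_width = 1.5, bridge_gap = 0.75)
  tr <- simulate_contraction(hex_mesh(d, h = 0.75), actuation = act)
  expect_equal(sw$max_deformation_mm, max_deformation(tr), tolerance = 1e-12)
})

test_that("sweep records infeasible combinations instead of failing", {
  sw <- design_sweep(n_bridges = c(1L, 4L), bridge_widths = c(1.5, 4.5),
                     h = 0.75, actuation = quick_actuation(strain = 0.05))
  expect_equal(nrow(sw), 4L)
  bad <- dplyr::filter(sw, !feasible)
  expect_equal(nrow(bad), 2L)   # 4 bridges never fit at these widths
  expect_match(bad$note, "overflow")
  best <- optimal_design(sw)
  expect_true(best$feasible)
  expect_equal(max(sw$max_deformation_mm, na.rm = TRUE),
               best$max_deformation_mm)
})
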