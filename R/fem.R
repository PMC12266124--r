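#' Material parameters for the corotational contraction model
#'
#' Defaults follow microindentation measurements on matured constructs:
#' Young's moduli of 49.7 kPa (muscle) and 158.9 kPa (tendon) and a Poisson
#' ratio of 0.4 for both regions; density of water-like tissue.
#'
#' @param E_muscle,E_tendon Young's moduli (kPa).
#' @param nu Poisson ratio (both regions).
#' @param density Mass density (kg/m^3).
#' @return A `material_params` list.
#' @export
material_params <- function(E_muscle = 49.7, E_tendon = 158.9,
                            nu = 0.4, density = 1000) {
  stop_if_not_scalar_pos(E_muscle, "E_muscle")
  stop_if_not_scalar_pos(E_tendon, "E_tendon")
  if (!is.numeric(nu) || nu < 0 || nu >= 0.5)
    abort("`nu` must lie in [0, 0.5)")
  stop_if_not_scalar_pos(density, "density")
  structure(list(E_muscle = E_muscle, E_tendon = E_tendon, nu = nu,
                 density = density), class = "material_params")
}

#' Prescribed-strain actuation
#'
#' Contractile elements target a rest shape shortened by `strain` along
#' `direction` (the long axis, parallel to the bridges). The contraction is
#' ramped over `duration` (`ramp = "linear"`) or applied at once
#' (`ramp = "step"`); the simulation runs `duration / dt` implicit time steps.
#'
#' @param strain Prescribed contractile strain (0 <= strain < 1). The strain
#'   magnitude of matured tissue is not identifiable from geometry alone;
#'   0.10 is the package default and all design comparisons hold it fixed.
#' @param direction Unit actuation direction (mm frame).
#' @param duration Simulated time (s).
#' @param dt Time step (s).
#' @param ramp `"linear"` or `"step"`.
#' @return An `actuation_spec` list.
#' @export
actuation_spec <- function(strain = 0.10, direction = c(0, 0, 1),
                           duration = 0.4, dt = 0.010, ramp = c("linear", "step")) {
  if (!is.numeric(strain) || strain < 0 || strain >= 1)
    abort("`strain` must lie in [0, 1)")
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(dt, "dt")
  if (duration < dt) abort("`duration` must be >= `dt`")
  direction <- as.numeric(direction)
  if (length(direction) != 3L || sum(direction^2) == 0)
    abort("`direction` must be a nonzero 3-vector")
  direction <- direction / sqrt(sum(direction^2))
  ramp <- match.arg(ramp)
  structure(list(strain = strain, direction = direction, duration = duration,
                 dt = dt, ramp = ramp), class = "actuation_spec")
}

# unit-modulus stiffness of a hx x hy x hz trilinear hexahedron (2x2x2 Gauss)
hex_k0 <- function(nu, hx, hy, hz) {
  signs <- rbind(
    c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
    c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  fac <- 1 / ((1 + nu) * (1 - 2 * nu))
  D <- fac * rbind(
    c(1 - nu, nu, nu, 0, 0, 0),
    c(nu, 1 - nu, nu, 0, 0, 0),
    c(nu, nu, 1 - nu, 0, 0, 0),
    c(0, 0, 0, (1 - 2 * nu) / 2, 0, 0),
    c(0, 0, 0, 0, (1 - 2 * nu) / 2, 0),
    c(0, 0, 0, 0, 0, (1 - 2 * nu) / 2))
  g <- 1 / sqrt(3)
  detJ <- hx * hy * hz / 8
  K <- matrix(0, 24, 24)
  for (gx in c(-g, g)) for (gy in c(-g, g)) for (gz in c(-g, g)) {
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      s <- signs[a, ]
      dNx <- s[1] * (1 + gy * s[2]) * (1 + gz * s[3]) / 8 * (2 / hx)
      dNy <- s[2] * (1 + gx * s[1]) * (1 + gz * s[3]) / 8 * (2 / hy)
      dNz <- s[3] * (1 + gx * s[1]) * (1 + gy * s[2]) / 8 * (2 / hz)
      cj <- 3 * (a - 1)
      B[1, cj + 1] <- dNx
      B[2, cj + 2] <- dNy
      B[3, cj + 3] <- dNz
      B[4, cj + 1] <- dNy; B[4, cj + 2] <- dNx
      B[5, cj + 2] <- dNz; B[5, cj + 3] <- dNy
      B[6, cj + 1] <- dNz; B[6, cj + 3] <- dNx
    }
    K <- K + t(B) %*% D %*% B * detJ
  }
  (K + t(K)) / 2
}

# rest offsets of the voxel element corners from its centroid (VTK order)
hex_offsets <- function(hx, hy, hz) {
  signs <- rbind(
    c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
    c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  signs %*% diag(c(hx, hy, hz) / 2)
}

#' Simulate prescribed-strain contraction of an MTU mesh
#'
#' Implicit backward-Euler dynamics of corotational hexahedral elasticity.
#' Each element extracts its rotation by polar decomposition, applies linear
#' elasticity in the rotated frame, and contractile elements pull toward a
#' rest shape shortened by the prescribed strain along the actuation
#' direction. The construct is free-floating (no anchor contact), with
#' lumped mass and Rayleigh damping; after the actuation ramp completes, the
#' final state is relaxed until the internal-force residual falls below the
#' convergence tolerance, so the last frame is an equilibrium.
#'
#' @param mesh A [hex_mesh()].
#' @param materials A [material_params()].
#' @param actuation An [actuation_spec()].
#' @param control Solver controls: `newton_iter` inner iterations per step,
#'   `settle_iter` equilibrium iteration cap, `tol` residual force
#'   infinity-norm tolerance (mN; default `1e-8 * E_muscle * min(h)^2`),
#'   `alpha` (1/s) and `beta` (s) Rayleigh damping coefficients.
#' @return An `mtu_trajectory`: list of per-step vertex positions (`frames`,
#'   N x 3 mm), `times` (s), solver diagnostics.
#' @examples
#' \donttest{
#' m <- hex_mesh(mtu_design(), h = 0.75)
#' tr <- simulate_contraction(m)
#' max_deformation(tr)
#' }
#' @export
simulate_contraction <- function(mesh, materials = material_params(),
                                 actuation = actuation_spec(),
                                 control = list()) {
  stopifnot(inherits(mesh, "hex_mesh"),
            inherits(materials, "material_params"),
            inherits(actuation, "actuation_spec"))
  ctl <- utils::modifyList(list(
    newton_iter = 1L, settle_iter = 200L,
    tol = 1e-8 * materials$E_muscle * min(mesh$h)^2,
    alpha = 1, beta = 0.002), control)

  if (actuation$strain > 0 && !any(mesh$contractile))
    abort("contractile set is empty but strain > 0")

  N <- nrow(mesh$vertices)
  M <- nrow(mesh$hexes)
  K0 <- hex_k0(materials$nu, mesh$h[1], mesh$h[2], mesh$h[3])
  Q <- hex_offsets(mesh$h[1], mesh$h[2], mesh$h[3])
  Evec <- ifelse(mesh$region == "muscle", materials$E_muscle, materials$E_tendon)

  # lumped mass (kg): rho * element volume / 8 per incident vertex
  elem_mass <- materials$density * prod(mesh$h) * 1e-9
  mv <- numeric(N)
  tab <- tabulate(as.vector(mesh$hexes), nbins = N)
  mv <- tab * elem_mass / 8
  mdof <- rep(mv, each = 3L)

  # fixed triplet pattern: element-major 24 x 24 blocks, column-major
  dofmat <- matrix(0L, M, 24L)
  for (a in 1:8) dofmat[, (3 * a - 2):(3 * a)] <-
    cbind(3L * mesh$hexes[, a] - 2L, 3L * mesh$hexes[, a] - 1L, 3L * mesh$hexes[, a])
  tdm <- t(dofmat)
  i_all <- as.vector(tdm[rep(1:24, times = 24), , drop = FALSE])
  j_all <- as.vector(tdm[rep(1:24, each = 24), , drop = FALSE])

  dt <- actuation$dt
  times <- seq(0, actuation$duration, by = dt)
  n_steps <- length(times) - 1L
  dirv <- actuation$direction

  x <- as.vector(t(mesh$vertices))   # dof vector (x1,y1,z1,x2,...)
  v <- numeric(3L * N)
  frames <- vector("list", n_steps + 1L)
  frames[[1L]] <- mesh$vertices

  chol_cache <- NULL
  solve_H <- function(H, b) {
    Hs <- Matrix::forceSymmetric(H)
    if (is.null(chol_cache)) {
      chol_cache <<- Matrix::Cholesky(Hs, LDL = FALSE, super = TRUE)
    } else {
      chol_cache <<- tryCatch(
        Matrix::.updateCHMfactor(chol_cache, as(Hs, "CsparseMatrix"), mult = 0),
        error = function(e) Matrix::Cholesky(Hs, LDL = FALSE, super = TRUE))
    }
    as.vector(Matrix::solve(chol_cache, b))
  }

  assemble <- function(xv, epsv) {
    res <- corot_assemble(matrix(xv, ncol = 3, byrow = TRUE), mesh$hexes, K0,
                          Evec, Q, dirv, epsv)
    K <- Matrix::sparseMatrix(i = i_all, j = j_all, x = as.numeric(res$x),
                              dims = c(3L * N, 3L * N))
    list(K = K, f = as.numeric(res$f), energy = res$energy)
  }

  eps_at <- function(t) {
    if (actuation$ramp == "step") actuation$strain
    else actuation$strain * min(t / actuation$duration, 1)
  }

  # cap update length at half an element: the frozen-rotation linearization
  # is only trustworthy locally, and overshooting it can cycle
  max_step <- 0.5 * min(mesh$h)
  capped <- function(dx) {
    m <- max(abs(dx))
    if (m > max_step) dx * (max_step / m) else dx
  }

  for (k in seq_len(n_steps)) {
    epsv <- ifelse(mesh$contractile, eps_at(times[k + 1L]), 0)
    x_n <- x
    for (it in seq_len(ctl$newton_iter)) {
      a <- assemble(x, epsv)
      dx <- x - x_n
      r <- a$f -
        mdof * ((dx) / dt^2 - v / dt) -
        (ctl$alpha * mdof * dx + ctl$beta * as.vector(a$K %*% dx)) / dt
      H <- a$K * (1 + ctl$beta / dt) +
        Matrix::Diagonal(x = mdof * (1 / dt^2 + ctl$alpha / dt))
      x <- x + capped(solve_H(H, r))
      if (max(abs(r)) < ctl$tol) break
    }
    v <- (x - x_n) / dt
    frames[[k + 1L]] <- matrix(x, ncol = 3, byrow = TRUE)
  }

  # relax to equilibrium at full actuation (final frame contract)
  epsv <- ifelse(mesh$contractile, eps_at(actuation$duration), 0)
  settle_energy <- numeric(0)
  converged <- FALSE
  residual <- NA_real_
  for (it in seq_len(ctl$settle_iter)) {
    a <- assemble(x, epsv)
    settle_energy <- c(settle_energy, a$energy)
    residual <- max(abs(a$f))
    if (residual < ctl$tol) { converged <- TRUE; break }
    # the stiffness-scaled diagonal keeps the free construct's rigid modes
    # from amplifying force roundoff near equilibrium
    lam <- 1e-4 * materials$E_muscle * min(mesh$h)
    H <- a$K + Matrix::Diagonal(x = mdof * (1 / dt^2 + ctl$alpha / dt) + lam)
    x <- x + capped(solve_H(H, a$f))
  }
  if (!converged && actuation$strain > 0)
    abort(sprintf(
      "equilibrium not reached in %d iterations (residual %.3g mN > tol %.3g mN)",
      ctl$settle_iter, residual, ctl$tol))
  frames[[n_steps + 1L]] <- matrix(x, ncol = 3, byrow = TRUE)

  structure(list(frames = frames, times = times, mesh = mesh,
                 residual = residual, settle_energy = settle_energy,
                 control = ctl),
            class = "mtu_trajectory")
}

#' @export
print.mtu_trajectory <- function(x, ...) {
  cat(sprintf("<mtu_trajectory> %d frames over %.3g s, %d vertices\n",
              length(x$frames), max(x$times), nrow(x$frames[[1]])))
  cat(sprintf("  final residual %.3g mN, max deformation %.4g mm\n",
              x$residual, max_deformation(x)))
  invisible(x)
}

# best-fit rigid alignment of frame `a` onto frame `b` (Kabsch)
rigid_align <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(A %*% t(R), 2, cb, "+")
}

#' Maximum-deformation metric of a trajectory
#'
#' The largest per-vertex displacement magnitude between the first and last
#' frames, computed after removing the best-fit rigid transform (the free
#' construct may drift or rotate as a whole; the metric measures shape
#' change only).
#'
#' @param traj An `mtu_trajectory`.
#' @return Maximum deformation in mm.
#' @export
max_deformation <- function(traj) {
  stopifnot(inherits(traj, "mtu_trajectory"), length(traj$frames) >= 2L)
  x0 <- traj$frames[[1L]]
  xf <- rigid_align(traj$frames[[length(traj$frames)]], x0)
  max(sqrt(rowSums((xf - x0)^2)))
}

#' Sweep bridge count and bridge width of the sparse MTU design
#'
#' Simulates every combination of `n_bridges` and `bridge_widths` on the base
#' design and reports the maximum-deformation metric. Combinations whose
#' bridges do not fit the construct width (or that the mesh resolution cannot
#' resolve) are recorded as infeasible, not errors. More and thinner bridges
#' expose more contractile surface, which increases the deformation.
#'
#' @param base Base [mtu_design()] supplying all non-swept parameters.
#' @param n_bridges Integer vector of bridge counts.
#' @param bridge_widths Numeric vector of bridge widths (mm).
#' @param materials,actuation Passed to [simulate_contraction()].
#' @param h Mesh element size (mm).
#' @param bridge_gap Gap between bridges (mm) used for sparse combinations.
#' @param control Solver control overrides.
#' @return A tibble (class `mtu_sweep`) with columns `n_bridges`,
#'   `bridge_width_mm`, `feasible`, `max_deformation_mm`, `n_vertices`,
#'   `note`.
#' @export
design_sweep <- function(base = mtu_design(), n_bridges = c(1L, 2L, 4L),
                         bridge_widths = c(1, 2, 4),
                         materials = material_params(),
                         actuation = actuation_spec(),
                         h = 0.5, bridge_gap = 0.5, control = list()) {
  grid <- tidyr::expand_grid(n_bridges = as.integer(n_bridges),
                             bridge_width_mm = as.numeric(bridge_widths))
  rows <- purrr::pmap(grid, function(n_bridges, bridge_width_mm) {
    out <- list(n_bridges = n_bridges, bridge_width_mm = bridge_width_mm,
                feasible = FALSE, max_deformation_mm = NA_real_,
                n_vertices = NA_integer_, note = "")
    res <- tryCatch({
      d <- mtu_design(length = base$length, width = base$width,
                      height = base$height, n_bridges = n_bridges,
                      bridge_width = bridge_width_mm,
                      bridge_gap = if (n_bridges > 1L) bridge_gap else 0,
                      muscle_length = base$muscle_length,
                      anchor_hole = base$anchor_hole,
                      interdigitation_radius = base$interdigitation_radius)
      m <- hex_mesh(d, h = h)
      tr <- simulate_contraction(m, materials, actuation, control)
      list(def = max_deformation(tr), nv = nrow(m$vertices))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$note <- conditionMessage(res)
    } else {
      out$feasible <- TRUE
      out$max_deformation_mm <- res$def
      out$n_vertices <- res$nv
    }
    tibble::as_tibble(out)
  })
  structure(dplyr::bind_rows(rows), class = c("mtu_sweep", "tbl_df", "tbl", "data.frame"))
}

#' Pick the optimal design from a sweep
#'
#' Maximum deformation wins; ties break toward fewer bridges
#' (manufacturability).
#'
#' @param sweep An [design_sweep()] result.
#' @return One-row tibble.
#' @export
optimal_design <- function(sweep) {
  ok <- dplyr::filter(sweep, .data$feasible)
  if (nrow(ok) == 0L) abort("no feasible design in the sweep")
  dplyr::slice(dplyr::arrange(ok, dplyr::desc(.data$max_deformation_mm),
                              .data$n_bridges), 1L)
}

#' @export
autoplot.mtu_sweep <- function(object, ...) {
  ok <- dplyr::filter(object, .data$feasible)
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$bridge_width_mm,
                                   y = .data$max_deformation_mm,
                                   colour = factor(.data$n_bridges))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "bridge width (mm)", y = "max deformation (mm)",
                  colour = "bridges") +
    ggplot2::theme_minimal()
}
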