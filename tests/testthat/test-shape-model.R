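test_that("velocity basis: inert and rigid-translation coordinates are exact", {
  base <- sphere_sample(50, 1e-6)
  gen <- function(q) {
    # q1 translates along x; q2 does not move the surface at all
    sphere_sample(50, 1e-6, center = c(q[1], 0, 0))
  }
  mod <- shape_model(gen, 2, coord_roles = c("rigid_translation", "linear"),
                     coord_axes = list(c(1, 0, 0), NULL))
  vb <- velocity_basis(mod, c(0.3e-6, 5))
  expect_equal(vb$w[[1]], matrix(rep(c(1, 0, 0), each = 50), 50, 3))
  expect_equal(max(abs(vb$w[[2]])), 0)
})

test_that("central differences converge at second order", {
  cvec <- c(2e-6, -1e-6, 3e-6)
  # quadratic family: the central difference of q^2 is exact
  gen2 <- function(q) {
    pts <- rbind(c(0, 0, 0), c(1e-6, 0, 0)) +
      matrix(q[1]^2 * cvec, 2, 3, byrow = TRUE)
    surface_sample(pts, rep(1e-13, 2), rep(1e-7, 2))
  }
  vb2 <- velocity_basis(shape_model(gen2, 1), 1, fd_step = 1e-2)
  exact2 <- matrix(2 * cvec, 2, 3, byrow = TRUE) # d/dq (q^2 c) at q = 1
  expect_equal(vb2$w[[1]], exact2, tolerance = 1e-10)
  # smooth nonpolynomial family: O(h^2) error, 4x reduction on halving
  gen <- function(q) {
    pts <- rbind(c(0, 0, 0), c(1e-6, 0, 0)) +
      matrix(sin(q[1]) * cvec, 2, 3, byrow = TRUE)
    surface_sample(pts, rep(1e-13, 2), rep(1e-7, 2))
  }
  mod <- shape_model(gen, 1)
  exact <- matrix(cos(1) * cvec, 2, 3, byrow = TRUE)
  err <- vapply(c(1e-2, 5e-3), function(h) {
    vb <- velocity_basis(mod, 1, fd_step = h)
    max(abs(vb$w[[1]] - exact))
  }, numeric(1))
  expect_equal(err[1] / err[2], 4, tolerance = 0.05)
})

test_that("element enumeration changes are a model-contract error", {
  gen <- function(q) {
    n <- if (q[1] > 0.5) 12 else 10
    sphere_sample(n, 1e-6)
  }
  mod <- shape_model(gen, 1)
  expect_error(velocity_basis(mod, 0.5, fd_step = 0.2), "enumeration")
})

test_that("force basis is independent of the normalization constant", {
  mod <- sphere_translation_model(n = 200)
  cfg <- kernel_free()
  vb <- velocity_basis(mod, c(0, 0, 0))
  fb1 <- force_basis(mod, c(0, 0, 0), vb, cfg, alpha = 1)
  fb2 <- force_basis(mod, c(0, 0, 0), vb, cfg, alpha = 10)
  expect_equal(fb1$g[[1]], fb2$g[[1]], tolerance = 1e-10)
  # surface-integrated force response of a translation equals Stokes drag
  Fx <- sum(fb1$g[[1]][, 1] * vb$sample$areas)
  expect_equal(Fx, stokes_drag(), tolerance = 0.05)
})

test_that("sphere friction matrix is the Stokes drag times identity", {
  mod <- sphere_translation_model(n = 300)
  G <- friction_matrix(mod, c(0, 0, 0), kernel_free())
  expect_equal(unclass(G), stokes_drag() * diag(3), tolerance = 0.05,
               ignore_attr = TRUE)
  offdiag <- unclass(G)[upper.tri(G)]
  expect_lt(max(abs(offdiag)), 1e-3 * stokes_drag())
})

test_that("friction matrix is symmetric and positive definite for cilia", {
  set.seed(31)
  pat <- test_pattern()
  cfg <- kernel_wall()
  # random two-cilium configurations
  for (k in 1:3) {
    pair <- cilia_pair_config(d = runif(1, 14e-6, 25e-6),
                              psi = runif(1, 0, 2 * pi))
    mod <- cilia_pair_model(pat, pair)
    G <- friction_matrix(mod, runif(2, 0, 2 * pi), cfg)
    expect_lt(attr(G, "asymmetry"), 1e-6)
    expect_true(is_positive_definite(G))
  }
  # single cilium at 8 phases: all eigenvalues positive
  mod1 <- cilium_shape_model(pat)
  for (phi in 2 * pi * (0:7) / 8) {
    G <- friction_matrix(mod1, phi, cfg)
    expect_gt(unclass(G)[1, 1], 0)
  }
})

test_that("coordinate rescaling scales friction rows and columns by 1/c", {
  pat <- test_pattern()
  cfg <- kernel_wall()
  pair <- cilia_pair_config()
  mod <- cilia_pair_model(pat, pair)
  cc <- 2.5
  gen2 <- function(q) mod$generate(c(q[1] * cc, q[2])) # q1' = q1 / cc
  mod2 <- shape_model(gen2, 2, coord_roles = mod$coord_roles,
                      fd_step = mod$fd_step)
  q <- c(1.1, 2.3)
  G <- unclass(friction_matrix(mod, q, cfg))
  G2 <- unclass(friction_matrix(mod2, c(q[1] / cc, q[2]), cfg))
  S <- diag(c(cc, 1))
  expect_equal(S %*% G %*% S, G2, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("generalized forces and dissipation follow the quadratic form", {
  G <- diag(c(3, 7))
  expect_equal(generalized_forces(G, c(0, 0)), c(0, 0))
  expect_equal(generalized_forces(G, c(1, 0)), c(3, 0))
  expect_equal(dissipation_rate(G, c(0, 0)), 0)
  expect_equal(dissipation_rate(G, c(2, 1)), 4 * 3 + 1 * 7)
  expect_equal(dissipation_rate(G, 2 * c(2, 1)),
               4 * dissipation_rate(G, c(2, 1)))
  expect_error(dissipation_rate(diag(c(-1, 1)), c(1, 0)), "negative")
})

test_that("dissipation rate matches the direct surface quadrature", {
  pat <- test_pattern()
  cfg <- kernel_wall()
  mod <- cilium_shape_model(pat)
  q <- 1.3
  qdot <- 150 # rad/s
  vb <- velocity_basis(mod, q)
  G <- friction_matrix(mod, q, cfg, basis = vb)
  R_gamma <- dissipation_rate(G, qdot)
  # direct: v = w qdot, f = solve_traction(v), R = sum v . f A
  v <- vb$w[[1]] * qdot
  f <- solve_traction(vb$sample, v, cfg)
  R_direct <- surface_power(vb$sample, v, f)
  expect_equal(R_gamma, R_direct, tolerance = 1e-8)
  expect_gte(R_gamma, 0)
})

test_that("superposition: tractions of combined rates equal combined tractions", {
  pat <- test_pattern()
  cfg <- kernel_wall()
  pair <- cilia_pair_config()
  mod <- cilia_pair_model(pat, pair)
  q <- c(0.7, 4.1)
  vb <- velocity_basis(mod, q)
  fb <- force_basis(mod, q, vb, cfg)
  al <- c(3.2, -1.4)
  v <- al[1] * vb$w[[1]] + al[2] * vb$w[[2]]
  f <- solve_traction(vb$sample, v, cfg)
  f_sup <- al[1] * fb$g[[1]] + al[2] * fb$g[[2]]
  expect_equal(unclass(f), unclass(f_sup), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("rigid-body generalized forces equal total force and torque", {
  cfg <- kernel_free()
  s <- sphere_cluster_sample(rbind(c(0, 0, 0), c(4e-6, 1e-6, 0)),
                             c(1e-6, 0.8e-6), n_per_sphere = 120)
  fr <- material_frame(x0 = c(1e-6, 0, 0))
  G6 <- grand_friction_matrix(s, fr, cfg)
  qdot <- c(1e-6, -2e-6, 0.5e-6, 2, -1, 3)
  P <- generalized_forces(G6, qdot)
  # direct route: rigid velocity field -> tractions -> surface integrals
  v <- rigid_velocity_field(s, fr, rigid_velocity(qdot[1:3], qdot[4:6]))
  tr <- solve_traction(s, v, cfg)
  ft <- total_force_torque(s, tr, fr$x0)
  expect_equal(P[1:3], drop(crossprod(fr$E, ft$force)), tolerance = 1e-8)
  expect_equal(P[4:6], drop(crossprod(fr$E, ft$torque)), tolerance = 1e-8)
})
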