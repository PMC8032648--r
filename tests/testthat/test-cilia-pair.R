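test_that("single-cilium self-friction is positive and phase dependent", {
  tab <- test_single_table(m = 12)
  g <- tab$values[, 1, 1]
  expect_true(all(g > 0))
  # the effective stroke dissipates markedly more than recovery
  # (regression constant of the shipped default pattern)
  expect_equal(max(g) / min(g), 12.55, tolerance = 0.2)
})

test_that("self-friction scales linearly with viscosity", {
  pat <- test_pattern()
  mod <- cilium_shape_model(pat)
  phi <- 1.7
  g1 <- friction_matrix(mod, phi, kernel_config(1e-3,
                                                "half_space_wall"))[1, 1]
  g2 <- friction_matrix(mod, phi, kernel_config(2e-3,
                                                "half_space_wall"))[1, 1]
  expect_equal(g2 / g1, 2, tolerance = 1e-12)
})

test_that("pair tables: reciprocity, self-friction approximation, far-field decay", {
  tabs <- test_pair_tables(m = 12)
  expect_lt(tabs$cross_asymmetry, 1e-4)
  # self-friction of one cilium is virtually independent of the other's
  # phase at d = 18 um
  expect_lt(tabs$self_approx_error, 0.05)
  # cross-friction norm decreases with separation
  norm18 <- sqrt(mean(tabs$pair$values[, , 1, 2]^2))
  tabs36 <- pair_friction_tables(test_pattern(),
                                 cilia_pair_config(d = 36e-6),
                                 kernel_wall(), m = 8)
  norm36 <- sqrt(mean(tabs36$pair$values[, , 1, 2]^2))
  expect_lt(norm36, norm18 / 4)
})

test_that("intersecting pair geometries are rejected", {
  pat <- test_pattern()
  expect_error(
    pair_friction_tables(pat, cilia_pair_config(d = 0.3e-6),
                         kernel_wall(), m = 8),
    "intersect")
})

test_that("uncoupled cilia advance at exactly omega0", {
  tabs <- uncoupled_pair_tables(m = 12)
  omega0 <- tabs$config$omega0
  tr <- integrate_cilia_pair(tabs, c(0.2, 1.4), n_cycles = 3)
  expect_equal(tr$phi1, 0.2 + omega0 * tr$t, tolerance = 1e-9)
  expect_equal(tr$phi2, 1.4 + omega0 * tr$t, tolerance = 1e-9)
  lam <- lyapunov_exponent(tabs)
  expect_lt(abs(as.numeric(lam)), 1e-8)
})

test_that("in-phase state is an invariant manifold", {
  tabs <- test_pair_tables(m = 12)
  tr <- integrate_cilia_pair(tabs, c(0, 0), n_cycles = 50,
                             save_per_cycle = 4)
  expect_lt(max(abs(tr$delta)), 1e-8)
})

test_that("relabeling the cilia maps to the point-reflected configuration", {
  tabsA <- test_pair_tables(m = 8, psi = 5 * pi / 6)
  tabsB <- test_pair_tables(m = 8, psi = 5 * pi / 6 + pi)
  trA <- integrate_cilia_pair(tabsA, c(0.3, 1.1), n_cycles = 2)
  trB <- integrate_cilia_pair(tabsB, c(1.1, 0.3), n_cycles = 2)
  # swapped initial phases under the swapped geometry: same trajectory
  # with the labels exchanged
  expect_equal(trA$phi1, trB$phi2, tolerance = 1e-7)
  expect_equal(trA$phi2, trB$phi1, tolerance = 1e-7)
})

test_that("Lyapunov exponent is in the linear regime and reflection symmetric", {
  tabs <- test_pair_tables(m = 12)
  lam1 <- as.numeric(lyapunov_exponent(tabs, delta0 = 1e-3))
  lam2 <- as.numeric(lyapunov_exponent(tabs, delta0 = 1e-4))
  expect_equal(lam1, lam2, tolerance = 0.01)
  # in-phase stability at the default geometry (d = 18 um, psi = 5 pi/6)
  expect_lt(lam1, 0)
  # point-reflection symmetry psi -> psi + pi
  lamA <- as.numeric(lyapunov_exponent(test_pair_tables(m = 8,
                                                        psi = 5 * pi / 6)))
  lamB <- as.numeric(lyapunov_exponent(
    test_pair_tables(m = 8, psi = 5 * pi / 6 + pi)))
  expect_equal(lamA, lamB, tolerance = 0.02)
})

test_that("steady state: stable in-phase attractor and neutral detection", {
  # use the most strongly contracting direction so the default
  # convergence threshold is reached within the cycle horizon
  tabs <- test_pair_tables(m = 12, psi = pi / 2)
  ss <- steady_state_phase_difference(tabs, initial_deltas = c(0.5),
                                      max_cycles = 280)
  att <- attr(ss, "attractors")
  expect_gte(nrow(att), 1)
  expect_lt(min(abs(att$delta_star)), 0.05)
  # neutral (uncoupled) case is flagged, not reported as converged
  ssn <- steady_state_phase_difference(uncoupled_pair_tables(m = 12),
                                       initial_deltas = c(1.0),
                                       max_cycles = 20)
  expect_false(ssn$converged[1])
  expect_true(ssn$neutral[1])
  expect_equal(ssn$delta_star[1], 1.0)
})

test_that("scan and power-law fit run end to end on a coarse grid", {
  pat <- test_pattern()
  scan <- scan_cilia_pair(pat, d = c(20e-6, 30e-6, 45e-6, 67e-6),
                          psi = 5 * pi / 6, kernel_wall(), m = 8,
                          n_segments = 12)
  expect_s3_class(scan, "pair_scan")
  expect_equal(nrow(scan), 4)
  expect_true(all(diff(scan$gamma12_norm) < 0))
  fits <- fit_power_law(scan)
  # far-field decay close to the cubic law of wall-bounded interactions
  expect_gt(fits$exponent_gamma12, 2)
  expect_lt(fits$exponent_gamma12, 4)
  expect_gt(fits$exponent_lambda, 2)
  expect_lt(fits$exponent_lambda, 4)
  # near-field distances are excluded with a warning
  w <- capture_warnings(fit_power_law(scan, min_d = 25e-6))
  expect_match(w, "near-field", all = FALSE)
})

test_that("coupling decay approaches the Blake exponent 3 at large separations", {
  # at moderate separations (1.5-6 cilium lengths) the fitted exponent
  # carries O(L/d) corrections; far out it converges to the asymptotic
  # wall-bounded value 3
  pat <- test_pattern()
  ds <- c(120, 240, 480) * 1e-6
  nrm <- vapply(ds, function(d) {
    tabs <- pair_friction_tables(pat, cilia_pair_config(d = d),
                                 kernel_wall(), m = 8, n_segments = 12)
    sqrt(mean(tabs$pair$values[, , 1, 2]^2))
  }, numeric(1))
  slope <- -coef(lm(log(nrm) ~ log(ds)))[[2]]
  expect_equal(slope, 3, tolerance = 0.1 / 3)
})

test_that("plot methods return ggplot objects", {
  tabs <- test_pair_tables(m = 12)
  expect_s3_class(autoplot(tabs$single), "ggplot")
  expect_s3_class(autoplot(tabs$pair), "ggplot")
  expect_s3_class(autoplot(test_pattern()), "ggplot")
})
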