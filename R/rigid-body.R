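# Rigid-body generalized coordinates: material frames, the 6x6 grand
# friction (inverse grand mobility) matrix, free-swimmer solves under zero
# net force and torque, and exact exponential frame updates.

#' Material frame of a swimmer
#'
#' A reference point and a right-handed orthonormal triad tracking a
#' swimmer's rigid-body position and orientation.
#'
#' @param x0 Length-3 reference point (m).
#' @param e1,e2,e3 Orthonormal basis vectors.
#' @return Object of class `material_frame` with fields `x0` and `E`
#'   (3 x 3 matrix whose columns are `e1, e2, e3`).
#' @export
material_frame <- function(x0 = c(0, 0, 0), e1 = c(1, 0, 0),
                           e2 = c(0, 1, 0), e3 = c(0, 0, 1)) {
  E <- cbind(e1, e2, e3)
  if (max(abs(crossprod(E) - diag(3))) > 1e-10) {
    stop("frame vectors must be orthonormal (within 1e-10).", call. = FALSE)
  }
  if (det(E) < 0) stop("frame must be right-handed.", call. = FALSE)
  structure(list(x0 = as.numeric(x0), E = unname(E)),
            class = "material_frame")
}

#' Rigid-body velocity (material components)
#'
#' @param v Length-3 translational velocity components in the material
#'   basis (m/s).
#' @param omega Length-3 rotational velocity components in the material
#'   basis (rad/s).
#' @return Object of class `rigid_velocity`.
#' @export
rigid_velocity <- function(v = c(0, 0, 0), omega = c(0, 0, 0)) {
  stopifnot(all(is.finite(v)), all(is.finite(omega)))
  structure(list(v = as.numeric(v), omega = as.numeric(omega)),
            class = "rigid_velocity")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Surface velocity field of a rigid motion
#'
#' `v(x_k) = v0 + Omega x (x_k - x0)` with `v0`, `Omega` assembled from
#' material-basis components.
#'
#' @param sample A [surface_sample()] (points in the lab frame).
#' @param frame A [material_frame()].
#' @param rv A [rigid_velocity()].
#' @return n x 3 matrix of velocities.
#' @export
rigid_velocity_field <- function(sample, frame, rv) {
  v0 <- drop(frame$E %*% rv$v)
  Om <- drop(frame$E %*% rv$omega)
  r <- sweep(sample$points, 2, frame$x0, "-")
  cbind(v0[1] + Om[2] * r[, 3] - Om[3] * r[, 2],
        v0[2] + Om[3] * r[, 1] - Om[1] * r[, 3],
        v0[3] + Om[1] * r[, 2] - Om[2] * r[, 1])
}

# 3n x 6 matrix of interleaved rigid velocity basis fields (unit rates of
# the six rigid-body generalized coordinates, material components)
rigid_basis_matrix <- function(sample, frame) {
  n <- n_elements(sample)
  W <- matrix(0, 3L * n, 6L)
  for (i in 1:3) {
    W[, i] <- vec3(matrix(frame$E[, i], n, 3L, byrow = TRUE))
  }
  r <- sweep(sample$points, 2, frame$x0, "-")
  for (i in 1:3) {
    ax <- frame$E[, i]
    W[, 3L + i] <- vec3(cbind(ax[2] * r[, 3] - ax[3] * r[, 2],
                              ax[3] * r[, 1] - ax[1] * r[, 3],
                              ax[1] * r[, 2] - ax[2] * r[, 1]))
  }
  W
}

#' Grand friction matrix of a rigid body
#'
#' The 6 x 6 generalized friction matrix for the six rigid-body
#' coordinates (three translations, three rotations about the material
#' axes), i.e. the inverse mobility matrix of the body. The conjugate
#' generalized forces are the components of total force and torque in the
#' material basis.
#'
#' @param sample A [surface_sample()].
#' @param frame A [material_frame()].
#' @param config A [kernel_config()].
#' @param asym_tol Relative asymmetry tolerance before symmetrization.
#' @return A 6 x 6 `friction_matrix` (blocks: translation N s/m, coupling
#'   N s, rotation N m s).
#' @export
grand_friction_matrix <- function(sample, frame, config, asym_tol = 1e-4) {
  W <- rigid_basis_matrix(sample, frame)
  Fpt <- solve_traction(sample, W, config)
  G <- crossprod(W, Fpt)
  scale <- max(abs(G))
  asym <- if (scale > 0) max(abs(G - t(G))) / scale else 0
  if (asym > asym_tol) {
    warning(sprintf("grand friction matrix asymmetry %.3g exceeds %.3g",
                    asym, asym_tol), call. = FALSE)
  }
  G <- (G + t(G)) / 2
  structure(G, class = c("friction_matrix", "matrix"),
            coord_units = c(rep("m", 3), rep("rad", 3)),
            asymmetry = asym, model_id = "rigid_body")
}

#' Solve the free-swimmer problem (zero net force and torque)
#'
#' Given the instantaneous shape-change velocity field on the surface,
#' finds the rigid-body velocity such that the total hydrodynamic force and
#' torque vanish. The active traction (response to the pure shape change)
#' is computed first; its total force/torque projected on the material
#' basis forms the inhomogeneity of a 6 x 6 linear system with the grand
#' friction matrix.
#'
#' @param sample A [surface_sample()] in the lab frame.
#' @param frame A [material_frame()].
#' @param shape_rate_field n x 3 matrix: surface velocity due to the shape
#'   change alone (lab components).
#' @param config A [kernel_config()].
#' @return List with `rv` (a [rigid_velocity()], material components),
#'   `traction` (n x 3 total traction field), `residual_force`,
#'   `residual_torque` (should be ~0), and `gamma6` (the grand matrix).
#' @export
solve_free_swimmer <- function(sample, frame, shape_rate_field, config) {
  n <- n_elements(sample)
  W <- rigid_basis_matrix(sample, frame)
  rhs <- cbind(W, vec3(as.matrix(shape_rate_field)))
  Fpt <- solve_traction(sample, rhs, config)
  Frigid <- Fpt[, 1:6, drop = FALSE]
  Fact <- Fpt[, 7]
  G6 <- crossprod(W, Frigid)
  G6 <- (G6 + t(G6)) / 2
  Pact <- drop(crossprod(W, Fact))
  qdot <- tryCatch(
    -solve(G6, Pact),
    error = function(e) stop("singular grand friction matrix.",
                             call. = FALSE)
  )
  forces <- mat3(Fact + Frigid %*% qdot)
  traction <- forces / sample$areas
  tot <- total_force_torque(sample, traction, frame$x0)
  list(rv = rigid_velocity(qdot[1:3], qdot[4:6]),
       traction = traction,
       residual_force = tot$force, residual_torque = tot$torque,
       gamma6 = structure(G6, class = c("friction_matrix", "matrix")))
}

# Rodrigues rotation matrix for rotation vector w (lab frame)
rotation_exp <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-300) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Advance a material frame by one time step
#'
#' Exact rotation update: the triad is rotated by the matrix exponential of
#' the rotation vector `Omega dt` (not an Euler step), followed by a
#' re-orthonormalization guard; the reference point advances with the
#' lab-frame translational velocity.
#'
#' @param frame A [material_frame()].
#' @param rv A [rigid_velocity()] (material components).
#' @param dt Time step (s).
#' @return The advanced [material_frame()].
#' @export
step_frame <- function(frame, rv, dt) {
  Om_lab <- drop(frame$E %*% rv$omega)
  R <- rotation_exp(Om_lab * dt)
  E <- R %*% frame$E
  # polar re-orthonormalization via symmetric square root
  S <- crossprod(E)
  es <- eigen(S, symmetric = TRUE)
  E <- E %*% (es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors))
  v_lab <- drop(frame$E %*% rv$v)
  material_frame(frame$x0 + v_lab * dt, E[, 1], E[, 2], E[, 3])
}

# ---- built-in swimmer: three collinear spheres -------------------------

#' Three-sphere swimmer sample
#'
#' Three collinear spheres along the `e1` axis of `frame`: a middle sphere
#' at the reference point and two outer spheres at arm lengths `d1` (left)
#' and `d2` (right). Changing `d1`, `d2` cyclically and non-reciprocally
#' propels the cluster.
#'
#' @param d1,d2 Arm lengths (m), center-to-center.
#' @param frame A [material_frame()].
#' @param radius Sphere radius (m).
#' @param n_per_sphere Elements per sphere.
#' @return A [surface_sample()] (elements ordered left, middle, right).
#' @export
three_sphere_sample <- function(d1, d2, frame = material_frame(),
                                radius = 1e-6, n_per_sphere = 80) {
  ax <- frame$E[, 1]
  centers <- rbind(frame$x0 - d1 * ax, frame$x0, frame$x0 + d2 * ax)
  sphere_cluster_sample(centers, radius, n_per_sphere)
}

#' Shape-change velocity field of the three-sphere swimmer
#'
#' Lab-frame surface velocities for arm-length rates `(d1dot, d2dot)`:
#' the left sphere translates with `-d1dot e1`, the right sphere with
#' `+d2dot e1`, the middle sphere is at rest in the material frame.
#'
#' @param sample Output of [three_sphere_sample()].
#' @param frame A [material_frame()].
#' @param d_rates Length-2 rates (m/s).
#' @return n x 3 matrix of velocities.
#' @export
three_sphere_shape_rate <- function(sample, frame, d_rates) {
  n <- n_elements(sample)
  npart <- n / 3L
  ax <- frame$E[, 1]
  v <- matrix(0, n, 3L)
  v[seq_len(npart), ] <- matrix(-d_rates[1] * ax, npart, 3L, byrow = TRUE)
  v[2L * npart + seq_len(npart), ] <- matrix(d_rates[2] * ax, npart, 3L,
                                             byrow = TRUE)
  v
}

#' Swim a three-sphere swimmer through a prescribed arm stroke
#'
#' Quasi-statically integrates the free-swimmer problem along a prescribed
#' path in arm-length space `(d1(s), d2(s))`, `s` in `[0, 1]` (the path
#' parameter; at zero Reynolds number the net displacement depends only on
#' the path, not on the traversal speed). Uses midpoint evaluation per
#' step.
#'
#' @param path Function `s -> c(d1, d2)` (m).
#' @param n_steps Number of quadrature steps along the path.
#' @param frame Initial [material_frame()].
#' @param config A [kernel_config()] (free space for an unbounded swimmer).
#' @param radius,n_per_sphere Sphere discretization.
#' @return A tibble with columns `s`, `x`, `y`, `z` (reference-point
#'   trajectory) and attribute `"displacement"` (net displacement vector).
#' @export
swim_stroke <- function(path, n_steps = 40, frame = material_frame(),
                        config = kernel_config(), radius = 1e-6,
                        n_per_sphere = 80) {
  s_grid <- seq(0, 1, length.out = n_steps + 1L)
  x0 <- frame$x0
  out <- matrix(NA_real_, n_steps + 1L, 3L)
  out[1, ] <- frame$x0
  for (k in seq_len(n_steps)) {
    sm <- (s_grid[k] + s_grid[k + 1]) / 2
    ds <- s_grid[k + 1] - s_grid[k]
    d_mid <- path(sm)
    d_rate <- (path(s_grid[k + 1]) - path(s_grid[k])) / ds # per unit s
    sample <- three_sphere_sample(d_mid[1], d_mid[2], frame, radius,
                                  n_per_sphere)
    vs <- three_sphere_shape_rate(sample, frame, d_rate)
    sol <- solve_free_swimmer(sample, frame, vs, config)
    frame <- step_frame(frame, sol$rv, ds)
    out[k + 1L, ] <- frame$x0
  }
  tib <- tibble::tibble(s = s_grid, x = out[, 1], y = out[, 2], z = out[, 3])
  attr(tib, "displacement") <- frame$x0 - x0
  attr(tib, "frame") <- frame
  tib
}
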