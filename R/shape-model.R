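# Shape models over generalized coordinates q and the Lagrangian projection
# that turns surface tractions into generalized friction forces:
#   P_i = sum_k w_i(x_k) . f(x_k) A_k,   Gamma_ij = sum_k w_i . g_j A_k,
# with w_i = dx/dq_i the velocity basis and g_j the traction response to a
# unit rate of coordinate j.

#' Shape model: map from generalized coordinates to a surface sample
#'
#' A shape model describes a constrained family of surfaces `S(q)` through a
#' generator function. The generator must return samples with identical
#' element enumeration (same element count, same areas) for nearby `q`, so
#' that finite differences of element positions are well defined.
#'
#' @param generate Function `q -> surface_sample`.
#' @param n_coords Number of generalized coordinates.
#' @param coord_roles Character vector, one of `"periodic"` (period 2 pi),
#'   `"linear"`, `"rigid_translation"`, `"rigid_rotation"` per coordinate.
#' @param coord_units Unit labels per coordinate (documentation only; all
#'   numerics are SI).
#' @param coord_axes Optional list of unit 3-vectors, required for
#'   `rigid_translation` coordinates (their velocity basis is exact).
#' @param fd_step Default finite-difference step per coordinate.
#' @param id Model identifier used in table provenance.
#' @return An object of class `shape_model`.
#' @export
shape_model <- function(generate, n_coords,
                        coord_roles = rep("linear", n_coords),
                        coord_units = rep("1", n_coords),
                        coord_axes = NULL,
                        fd_step = rep(1e-6, n_coords),
                        id = "custom") {
  stopifnot(is.function(generate), n_coords >= 1L)
  coord_roles <- match.arg(coord_roles,
                           c("periodic", "linear", "rigid_translation",
                             "rigid_rotation"),
                           several.ok = TRUE)
  if (length(coord_roles) != n_coords) {
    stop("`coord_roles` must have one entry per coordinate.", call. = FALSE)
  }
  if (length(fd_step) == 1L) fd_step <- rep(fd_step, n_coords)
  structure(list(generate = generate, n_coords = n_coords,
                 coord_roles = coord_roles, coord_units = coord_units,
                 coord_axes = coord_axes, fd_step = fd_step, id = id),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat("<shape_model>", x$id, "|", x$n_coords, "coordinate(s):",
      paste(x$coord_roles, collapse = ", "), "\n")
  invisible(x)
}

check_same_enumeration <- function(s1, s2) {
  if (n_elements(s1) != n_elements(s2) ||
      max(abs(s1$areas - s2$areas)) >
        1e-12 * max(s1$areas, .Machine$double.xmin)) {
    stop(paste0("shape model contract violated: element enumeration ",
                "(count/areas) changed under a coordinate perturbation."),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Velocity basis w_i = dx/dq_i by central differences
#'
#' Numerically differentiates the shape generator with respect to each
#' generalized coordinate. Central differences (second-order accurate) are
#' used by default; rigid-translation coordinates return their exact,
#' uniform unit axis vectors.
#'
#' @param model A [shape_model()].
#' @param q Coordinate vector.
#' @param fd_step Per-coordinate steps (defaults to the model's).
#' @param scheme `"central"` or `"forward"` (for generators only defined
#'   one-sided).
#' @return Object of class `velocity_basis`: a list with the reference
#'   `sample` at `q` and `w`, a list of n (elements x 3) matrices.
#' @export
velocity_basis <- function(model, q, fd_step = model$fd_step,
                           scheme = c("central", "forward")) {
  scheme <- match.arg(scheme)
  if (length(fd_step) == 1L) fd_step <- rep(fd_step, model$n_coords)
  stopifnot(length(q) == model$n_coords, all(fd_step > 0))
  s0 <- model$generate(q)
  w <- vector("list", model$n_coords)
  for (i in seq_len(model$n_coords)) {
    if (model$coord_roles[i] == "rigid_translation" &&
        !is.null(model$coord_axes) && !is.null(model$coord_axes[[i]])) {
      ax <- model$coord_axes[[i]]
      w[[i]] <- matrix(ax, n_elements(s0), 3L, byrow = TRUE)
      next
    }
    h <- fd_step[i]
    dq <- replace(numeric(model$n_coords), i, h)
    sp <- model$generate(q + dq)
    check_same_enumeration(s0, sp)
    if (scheme == "central") {
      sm <- model$generate(q - dq)
      check_same_enumeration(s0, sm)
      w[[i]] <- (sp$points - sm$points) / (2 * h)
    } else {
      w[[i]] <- (sp$points - s0$points) / h
    }
  }
  structure(list(sample = s0, w = w, q = q), class = "velocity_basis")
}

#' Force basis g_j: traction response per unit coordinate rate
#'
#' Solves the resistance problem for each velocity basis field
#' `v_j = alpha_j w_j` and normalizes: `g_j = solve_traction(alpha_j w_j) /
#' alpha_j`. By linearity of Stokes flow the result is independent of the
#' unit-carrying constant `alpha_j` (default 1 coordinate-unit per second).
#'
#' @param model A [shape_model()].
#' @param q Coordinate vector.
#' @param basis A [velocity_basis()] at `q` (computed if missing).
#' @param config A [kernel_config()].
#' @param alpha Scalar or per-coordinate normalization rates.
#' @return Object of class `force_basis`: list with `g` (list of n
#'   element x 3 traction matrices, N/m^2 per unit rate) and `forces`
#'   (3n x n matrix of interleaved point forces `g_j A_k`).
#' @export
force_basis <- function(model, q, basis = NULL, config, alpha = 1) {
  if (is.null(basis)) basis <- velocity_basis(model, q)
  s <- basis$sample
  n <- model$n_coords
  if (length(alpha) == 1L) alpha <- rep(alpha, n)
  W <- vapply(seq_len(n), function(j) vec3(basis$w[[j]] * alpha[j]),
              numeric(3L * n_elements(s)))
  Fpt <- solve_traction(s, W, config) # 3n x n interleaved point forces
  Fpt <- sweep(Fpt, 2, alpha, "/")
  g <- lapply(seq_len(n), function(j) mat3(Fpt[, j]) / s$areas)
  structure(list(sample = s, g = g, forces = Fpt, q = q),
            class = "force_basis")
}

#' Generalized hydrodynamic friction matrix
#'
#' Assembles the n x n friction matrix by the Lagrangian projection
#' quadrature `Gamma_ij = sum_k w_i(x_k) . g_j(x_k) A_k`. The matrix is
#' symmetric by the Lorentz reciprocal theorem; discretization breaks the
#' symmetry slightly, so the assembled matrix is checked (relative
#' asymmetry below `asym_tol`, otherwise a warning reports the measured
#' value) and then symmetrized as `(Gamma + t(Gamma))/2`.
#'
#' @param model A [shape_model()].
#' @param q Coordinate vector.
#' @param config A [kernel_config()].
#' @param basis Optional precomputed [velocity_basis()].
#' @param asym_tol Relative asymmetry tolerance (default `1e-4`).
#' @return An n x n matrix of class `friction_matrix` with attributes
#'   `q`, `coord_units`, `asymmetry` (the measured relative asymmetry) and
#'   `model_id`. Entry (i, j) has units force-unit_i s / coordinate-unit_j.
#' @export
friction_matrix <- function(model, q, config, basis = NULL,
                            asym_tol = 1e-4) {
  if (is.null(basis)) basis <- velocity_basis(model, q)
  fb <- force_basis(model, q, basis, config)
  n <- model$n_coords
  W <- vapply(seq_len(n), function(j) vec3(basis$w[[j]]),
              numeric(3L * n_elements(basis$sample)))
  G <- crossprod(W, fb$forces) # w_i . (g_j A_k) summed over elements
  scale <- max(abs(G))
  asym_abs <- max(abs(G - t(G)))
  asym <- if (scale > 0) asym_abs / scale else 0
  if (asym > asym_tol) {
    warning(sprintf(paste0("friction matrix asymmetry %.3g exceeds ",
                           "tolerance %.3g (reported, then symmetrized)"),
                    asym, asym_tol), call. = FALSE)
  }
  G <- (G + t(G)) / 2
  structure(G, class = c("friction_matrix", "matrix"), q = q,
            coord_units = model$coord_units, asymmetry = asym,
            asymmetry_abs = asym_abs, model_id = model$id)
}

#' Generalized friction forces P = Gamma qdot
#'
#' @param Gamma Friction matrix (n x n).
#' @param qdot Generalized velocity vector.
#' @return Length-n generalized force vector.
#' @export
generalized_forces <- function(Gamma, qdot) {
  stopifnot(ncol(Gamma) == length(qdot))
  drop(unclass(Gamma) %*% qdot)
}

#' Hydrodynamic dissipation rate qdot . Gamma . qdot
#'
#' Nonnegative quadratic form; equals `sum(P * qdot)` exactly.
#'
#' @inheritParams generalized_forces
#' @param tol Values below `-tol * ||Gamma|| * ||qdot||^2` raise an error
#'   (numerical-quality contract).
#' @return Scalar power (W).
#' @export
dissipation_rate <- function(Gamma, qdot, tol = 1e-10) {
  r <- sum(qdot * generalized_forces(Gamma, qdot))
  floor_ <- -tol * max(abs(Gamma)) * sum(qdot^2)
  if (r < floor_) {
    stop(sprintf("negative dissipation rate %.3g (below tolerance %.3g).",
                 r, floor_), call. = FALSE)
  }
  r
}

#' Test positive definiteness of a friction matrix
#'
#' @param Gamma Friction matrix.
#' @param tol Eigenvalues are allowed down to `-tol * ||Gamma||`.
#' @return `TRUE`/`FALSE`.
#' @export
is_positive_definite <- function(Gamma, tol = 1e-8) {
  ev <- eigen(unclass(Gamma), symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(abs(Gamma)))
}
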