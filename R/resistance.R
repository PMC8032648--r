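# Resistance problem: prescribed surface velocities -> surface tractions,
# by dense collocation over regularized Stokeslets, plus surface integrals
# of the traction field (total force, torque, dissipated power).

#' Solve the resistance problem for surface tractions
#'
#' Finds the traction density `f(x_k)` (force/area) such that the flow
#' induced by the discretized force distribution reproduces the prescribed
#' velocities at the collocation points (the no-slip boundary condition on
#' the moving surface). The linear system is solved by dense LU
#' factorization; the map `velocities -> tractions` is linear.
#'
#' @param sample A [surface_sample()].
#' @param velocities n x 3 matrix of surface velocities (m/s). A
#'   3n x p matrix of interleaved stacked velocity vectors is also accepted
#'   for multiple right-hand sides.
#' @param config A [kernel_config()].
#' @param check_condition If `TRUE`, estimate the condition number of the
#'   collocation matrix and error out (with the estimate in the message)
#'   if it exceeds `1e12`.
#' @return For a single right-hand side, an n x 3 matrix of tractions
#'   (N/m^2) with attribute `"forces"` (n x 3 point forces `f_k A_k`);
#'   for multiple right-hand sides, a 3n x p matrix of interleaved point
#'   forces.
#' @export
solve_traction <- function(sample, velocities, config,
                           check_condition = FALSE) {
  n <- n_elements(sample)
  if (n < 1L) stop("empty surface sample.", call. = FALSE)
  M <- mobility_matrix(sample$points, config, eps = sample$element_radius)
  # single RHS: an n x 3 matrix of velocity vectors; multiple RHS: a
  # 3n x p matrix of interleaved stacked velocity columns
  multi <- is.matrix(velocities) && nrow(velocities) == 3L * n &&
    !(nrow(velocities) == n && ncol(velocities) == 3L)
  v <- if (multi) velocities else vec3(as.matrix(velocities))
  if (length(v) %% (3L * n) != 0L) {
    stop("`velocities` must provide 3 components per element.",
         call. = FALSE)
  }
  if (!all(is.finite(v))) stop("non-finite velocities.", call. = FALSE)
  if (check_condition) {
    kap <- kappa(M, exact = FALSE)
    if (!is.finite(kap) || kap > 1e12) {
      stop(sprintf(paste0("resistance system is ill-conditioned ",
                          "(condition estimate %.3g); coincident or ",
                          "near-coincident elements?"), kap), call. = FALSE)
    }
  }
  forces <- tryCatch(
    solve(M, v),
    error = function(e) {
      stop(sprintf(paste0("resistance solve failed (%s); condition ",
                          "estimate %.3g"), conditionMessage(e),
                   kappa(M, exact = FALSE)), call. = FALSE)
    }
  )
  if (multi) return(forces)
  fmat <- mat3(forces)
  traction <- fmat / sample$areas
  attr(traction, "forces") <- fmat
  traction
}

#' Total force and torque of a traction field
#'
#' Surface-integrates a traction density: `F = sum_k f_k A_k` and
#' `M = sum_k (x_k - x0) x f_k A_k`.
#'
#' @param sample A [surface_sample()].
#' @param traction n x 3 traction density (N/m^2).
#' @param reference_point Length-3 reference point for the torque (m).
#' @return A list with `force` and `torque` (length-3 vectors, N and N m).
#' @export
total_force_torque <- function(sample, traction,
                               reference_point = c(0, 0, 0)) {
  tr <- as.matrix(traction)
  if (nrow(tr) != n_elements(sample) || ncol(tr) != 3L) {
    stop("`traction` must be an n x 3 matrix matching the sample.",
         call. = FALSE)
  }
  Fk <- tr * sample$areas
  r <- sweep(sample$points, 2, reference_point, "-")
  torque <- c(sum(r[, 2] * Fk[, 3] - r[, 3] * Fk[, 2]),
              sum(r[, 3] * Fk[, 1] - r[, 1] * Fk[, 3]),
              sum(r[, 1] * Fk[, 2] - r[, 2] * Fk[, 1]))
  list(force = colSums(Fk), torque = torque)
}

#' Rate of work exerted by a moving surface on the fluid
#'
#' The surface quadrature `sum_k v_k . f_k A_k`, which at zero Reynolds
#' number equals the instantaneous viscous dissipation in the bulk fluid.
#'
#' @inheritParams total_force_torque
#' @param velocities n x 3 surface velocities (m/s).
#' @return Scalar power (W).
#' @export
surface_power <- function(sample, velocities, traction) {
  sum(as.matrix(velocities) * as.matrix(traction) * sample$areas)
}
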