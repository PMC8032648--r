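# Force balance between active driving forces and generalized friction
# forces: Q = Gamma(q) qdot, integrated with precomputed friction tables.

#' Active driving forces
#'
#' Bundles one scalar driving-force function per generalized coordinate.
#' Each `Q_i` depends only on its own coordinate `q_i` (the driving force
#' coarse-grains internal active processes of unit `i`); load-dependent
#' driving is not implemented (a hook for it is reserved in the interface).
#'
#' @param funs A function or list of functions; `funs[[i]](q_i)` returns
#'   the driving force conjugate to coordinate `i`.
#' @param periodic Logical per coordinate: is `Q_i` 2-pi-periodic?
#' @return An object of class `driving_force`.
#' @export
driving_force <- function(funs, periodic = NULL) {
  if (is.function(funs)) funs <- list(funs)
  stopifnot(all(vapply(funs, is.function, logical(1))))
  if (is.null(periodic)) periodic <- rep(NA, length(funs))
  structure(list(funs = funs, periodic = periodic), class = "driving_force")
}

eval_driving <- function(Q, q) {
  vapply(seq_along(Q$funs), function(i) Q$funs[[i]](q[i]), numeric(1))
}

#' Equation of motion: solve the generalized force balance
#'
#' Solves `Gamma qdot = Q` by direct factorization (never an explicit
#' inverse) and checks the residual.
#'
#' @param Gamma n x n friction matrix (positive definite).
#' @param Q Length-n generalized force vector.
#' @param rtol Residual tolerance relative to `||Q||`.
#' @return Length-n generalized velocity vector.
#' @export
equation_of_motion <- function(Gamma, Q, rtol = 1e-10) {
  G <- unclass(Gamma)
  qdot <- tryCatch(
    solve(G, Q),
    error = function(e) {
      stop(paste0("singular friction matrix: the generalized friction ",
                  "matrix must be positive definite away from singular ",
                  "configurations (", conditionMessage(e), ")"),
           call. = FALSE)
    }
  )
  nq <- sqrt(sum(Q^2))
  if (nq > 0) {
    res <- sqrt(sum((G %*% qdot - Q)^2)) / nq
    if (res > rtol) {
      stop(sprintf("force-balance residual %.3g exceeds %.3g.", res, rtol),
           call. = FALSE)
    }
  }
  drop(qdot)
}

#' Calibrate the driving force of a phase oscillator
#'
#' For a single periodic coordinate (e.g. a cilium beat phase), requiring a
#' constant phase speed `phidot = omega0` in isolation fixes the driving
#' force uniquely: `Q(phi) = omega0 * Gamma_11(phi)`, with `Gamma_11` the
#' interpolated self-friction of the isolated unit.
#'
#' @param table One-coordinate periodic [build_friction_table()] of the
#'   isolated unit.
#' @param omega0 Intrinsic angular frequency (rad/s).
#' @return A [driving_force()] whose single function is
#'   `omega0 * Gamma_11(phi)`.
#' @export
calibrate_driving_force <- function(table, omega0) {
  if (table$n_coords != 1L || table$coord_roles[1] != "periodic") {
    stop("calibration requires a one-coordinate periodic friction table.",
         call. = FALSE)
  }
  force <- function(phi) {
    omega0 * interpolate_friction(table, phi)[1, 1]
  }
  driving_force(list(force), periodic = TRUE)
}

#' Integrate the force-balance equations of motion
#'
#' Evolves the generalized coordinates by `Gamma(q) qdot = Q(q)` with an
#' adaptive solver. Coordinates may be `free` (evolved by force balance),
#' `prescribed` (given trajectory; their force-balance rows are dropped and
#' their friction contribution moves to the right-hand side) or
#' `constrained` (`qdot = 0`; a special case of prescribed). For
#' non-free coordinates the conjugate generalized friction force `P_i`
#' (the external force required to impose the motion) is reported along the
#' trajectory, as is the instantaneous dissipation rate
#' `R = qdot . Gamma . qdot >= 0`.
#'
#' @param gamma_fun Either a `friction_table` or a function `q -> n x n`
#'   friction matrix.
#' @param Q A [driving_force()] (functions for free coordinates; entries
#'   for non-free coordinates are ignored and may be `function(q) 0`).
#' @param q0 Initial coordinates.
#' @param t_span Length-2 time interval (s).
#' @param roles Character per coordinate: `"free"`, `"prescribed"`,
#'   `"constrained"`. Default all free.
#' @param prescribed For each prescribed coordinate `i`, `prescribed[[i]]`
#'   is a list `list(f = function(t), fdot = function(t))`.
#' @param n_out Number of saved time points.
#' @param rtol,atol Integrator tolerances.
#' @return A tibble with columns `t`, `q<i>`, `qdot<i>`, `P<i>` for
#'   non-free coordinates, and `dissipation` (W).
#' @export
integrate_dynamics <- function(gamma_fun, Q, q0, t_span,
                               roles = NULL, prescribed = NULL,
                               n_out = 201L, rtol = 1e-8, atol = 1e-10) {
  gfun <- as_gamma_fun(gamma_fun)
  n <- length(q0)
  if (is.null(roles)) roles <- rep("free", n)
  stopifnot(length(roles) == n, all(roles %in% c("free", "prescribed",
                                                 "constrained")))
  free <- which(roles == "free")
  presc <- which(roles == "prescribed")
  times <- seq(t_span[1], t_span[2], length.out = n_out)
  if (length(free) == 0L) {
    # no dynamics to solve: all coordinates constrained or prescribed
    qmat <- matrix(q0, n_out, n, byrow = TRUE)
    qdmat <- matrix(0, n_out, n)
    for (r in seq_len(n_out)) {
      for (i in presc) {
        qmat[r, i] <- prescribed[[i]]$f(times[r])
        qdmat[r, i] <- prescribed[[i]]$fdot(times[r])
      }
    }
    return(traj_tibble(times, qmat, qdmat, gfun, Q, roles))
  }
  full_state <- function(t, y) {
    q <- q0
    q[free] <- y
    qd <- numeric(n)
    for (i in presc) {
      q[i] <- prescribed[[i]]$f(t)
      qd[i] <- prescribed[[i]]$fdot(t)
    }
    list(q = q, qd = qd)
  }
  rhs <- function(t, y, parms) {
    st <- full_state(t, y)
    G <- gfun(st$q)
    Qv <- numeric(n)
    Qv[free] <- vapply(free, function(i) Q$funs[[i]](st$q[i]), numeric(1))
    rhs_free <- Qv[free] -
      if (length(presc)) G[free, presc, drop = FALSE] %*% st$qd[presc] else 0
    qd_free <- solve(G[free, free, drop = FALSE], rhs_free)
    list(drop(qd_free))
  }
  sol <- deSolve::lsoda(q0[free], times, rhs, NULL, rtol = rtol, atol = atol)
  qmat <- matrix(q0, nrow(sol), n, byrow = TRUE)
  qdmat <- matrix(0, nrow(sol), n)
  for (r in seq_len(nrow(sol))) {
    st <- full_state(sol[r, 1], sol[r, -1])
    qmat[r, ] <- st$q
    qdmat[r, ] <- st$qd
    qdmat[r, free] <- rhs(sol[r, 1], sol[r, -1], NULL)[[1]]
  }
  traj_tibble(sol[, 1], qmat, qdmat, gfun, Q, roles)
}

as_gamma_fun <- function(gamma_fun) {
  if (inherits(gamma_fun, "friction_table")) {
    tab <- gamma_fun
    function(q) unclass(interpolate_friction(tab, q))
  } else if (is.function(gamma_fun)) {
    function(q) unclass(gamma_fun(q))
  } else {
    stop("`gamma_fun` must be a friction_table or a function.",
         call. = FALSE)
  }
}

traj_tibble <- function(times, qmat, qdmat, gfun, Q, roles) {
  n <- ncol(qmat)
  nonfree <- which(roles != "free")
  P <- matrix(NA_real_, length(times), length(nonfree))
  diss <- numeric(length(times))
  for (r in seq_along(times)) {
    G <- gfun(qmat[r, ])
    Pfull <- drop(G %*% qdmat[r, ])
    diss[r] <- sum(qdmat[r, ] * Pfull)
    if (length(nonfree)) P[r, ] <- Pfull[nonfree]
  }
  out <- tibble::tibble(t = as.numeric(times))
  for (i in seq_len(n)) out[[paste0("q", i)]] <- qmat[, i]
  for (i in seq_len(n)) out[[paste0("qdot", i)]] <- qdmat[, i]
  for (k in seq_along(nonfree)) out[[paste0("P", nonfree[k])]] <- P[, k]
  out$dissipation <- diss
  out
}

#' Measured beat period of a calibrated phase oscillator
#'
#' Integrates the single-phase equation of motion `phidot =
#' Q(phi)/Gamma_11(phi)` over `n_periods` nominal cycles with event
#' detection on the final phase crossing, and returns the mean period.
#'
#' @param table One-coordinate periodic friction table.
#' @param Q A [driving_force()] for the phase.
#' @param n_periods Number of cycles to integrate.
#' @param omega0_guess Frequency guess used only to bracket the event time.
#' @param rtol,atol Integrator tolerances.
#' @return Mean period (s).
#' @export
beat_period <- function(table, Q, n_periods = 10, omega0_guess = 2 * pi * 32,
                        rtol = 1e-11, atol = 1e-13) {
  target <- 2 * pi * n_periods
  rhs <- function(t, y, parms) {
    g <- interpolate_friction(table, y)[1, 1]
    list(Q$funs[[1]](y) / g)
  }
  root <- function(t, y, parms) y - target
  t_max <- 3 * target / omega0_guess
  sol <- deSolve::lsodar(0, c(0, t_max), rhs, NULL, rtol = rtol, atol = atol,
                         rootfunc = root)
  if (abs(sol[nrow(sol), 2] - target) > 1e-6) {
    stop("phase did not reach the target within the bracketing interval.",
         call. = FALSE)
  }
  unname(sol[nrow(sol), 1]) / n_periods
}
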