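# The cilia-pair application: friction tables for one and two wall-anchored
# cilia, coupled phase-oscillator dynamics, one-cycle Lyapunov exponents of
# the in-phase state, steady-state phase differences, and distance/direction
# scans with power-law fits of the far-field coupling.

#' Self-friction table of a single cilium
#'
#' Builds the one-coordinate friction table `Gamma_11(phi)` of an isolated
#' cilium on a uniform phase grid with Fourier interpolation.
#'
#' @param model A [cilium_shape_model()].
#' @param config A [kernel_config()] (half space).
#' @param m Number of phase grid nodes (>= 8).
#' @return A `friction_table`; all stored values are positive.
#' @export
single_cilium_table <- function(model, config, m = 24) {
  stopifnot(m >= 8)
  tab <- build_friction_table(model, m, config, interpolation = "fourier")
  if (any(tab$values <= 0)) {
    stop("non-positive self-friction encountered; discretization too ",
         "coarse?", call. = FALSE)
  }
  tab
}

#' Friction tables for an interacting cilia pair
#'
#' Builds the two-cilium friction matrix `Gamma(phi1, phi2)` on an `m x m`
#' phase grid, asserts the reciprocal-theorem symmetry
#' `Gamma_12 = Gamma_21` on the grid, and builds the single-cilium
#' self-friction table used in the equations of motion (the self-friction
#' of a cilium is virtually independent of the phase of the other cilium;
#' the approximation error is measured and stored).
#'
#' @param pattern A [synthetic_beat_pattern()].
#' @param pair A [cilia_pair_config()].
#' @param config A [kernel_config()] (half space).
#' @param m Phase grid nodes per coordinate.
#' @param radius,n_segments Cilium discretization.
#' @param cross_sym_tol Tolerance for `max|Gamma_12 - Gamma_21| /
#'   max|Gamma_12|` on the grid.
#' @return Object of class `cilia_pair_tables`: fields `single` (1-coord
#'   table), `pair` (2-coord table of the full 2 x 2 matrices), `config`
#'   (the pair configuration), `self_approx_error` (relative), and
#'   `cross_asymmetry`.
#' @export
pair_friction_tables <- function(pattern, pair, config, m = 24,
                                 radius = 1e-7,
                                 n_segments = pattern$n_segments,
                                 cross_sym_tol = 1e-4) {
  model2 <- cilia_pair_model(pattern, pair, radius, n_segments)
  check_pair_clearance(pattern, pair, radius, n_segments)
  # raw (unsymmetrized) cross-asymmetry is tracked across nodes
  grid <- 2 * pi * (seq_len(m) - 1L) / m
  vals <- array(NA_real_, dim = c(m, m, 2L, 2L))
  max_asym <- 0
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      G <- friction_matrix(model2, c(grid[a], grid[b]), config)
      vals[a, b, , ] <- unclass(G)
      max_asym <- max(max_asym, attr(G, "asymmetry_abs"))
    }
  }
  pair_tab <- new_friction_table(list(grid, grid), vals,
                                 c("periodic", "periodic"), c("rad", "rad"),
                                 "fourier", model2$id, config,
                                 solve_count = 2L * m * m)
  cross_scale <- max(abs(vals[, , 1, 2]))
  cross_asym <- if (cross_scale > 0) max_asym / cross_scale else 0
  if (cross_asym > cross_sym_tol) {
    warning(sprintf("cross-friction asymmetry %.3g exceeds %.3g",
                    cross_asym, cross_sym_tol), call. = FALSE)
  }
  model1 <- cilium_shape_model(pattern, c(0, 0, 0), radius, n_segments)
  single <- single_cilium_table(model1, config, m)
  # self-friction approximation error: Gamma_11(phi1, phi2) vs Gamma_11(phi1)
  err <- max(abs(sweep(vals[, , 1, 1], 1, single$values[, 1, 1], "-"))) /
    max(single$values[, 1, 1])
  structure(list(single = single, pair = pair_tab, config = pair,
                 kernel_config = config,
                 self_approx_error = err, cross_asymmetry = cross_asym),
            class = "cilia_pair_tables")
}

check_pair_clearance <- function(pattern, pair, radius, n_segments,
                                 n_phi = 8) {
  base2 <- c(pair$d * cos(pair$psi), pair$d * sin(pair$psi), 0)
  phis <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  bad <- list()
  for (p1 in phis) {
    r1 <- beat_centerline(pattern, p1, n_segments)
    for (p2 in phis) {
      r2 <- sweep(beat_centerline(pattern, p2, n_segments), 2, base2, "+")
      d2min <- min(outer(rowSums(r1^2), rowSums(r2^2), "+") -
                     2 * r1 %*% t(r2))
      if (d2min < (2 * radius)^2) bad[[length(bad) + 1L]] <- c(p1, p2)
    }
  }
  if (length(bad)) {
    stop("cilia intersect at (phi1, phi2) = ",
         paste(vapply(bad, function(x) sprintf("(%.2f, %.2f)", x[1], x[2]),
                      character(1)), collapse = " "),
         "; increase the separation distance.", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.cilia_pair_tables <- function(x, ...) {
  cat("<cilia_pair_tables> d =", format(x$config$d), "m, psi =",
      format(x$config$psi), "rad | grid",
      length(x$single$grids[[1]]), "| self-friction approx error",
      format(signif(x$self_approx_error, 3)), "\n")
  invisible(x)
}

# fast Fourier evaluators for the pair equations of motion
pair_evaluators <- function(tables) {
  c11 <- tables$single$fourier[, 1, 1]
  m1 <- length(c11)
  C12 <- tables$pair$fourier[, , 1, 2]
  m2 <- nrow(C12)
  g11 <- function(phi) Re(sum(c11 * fourier_basis(m1, phi)))
  g12 <- function(phi1, phi2) {
    Re(drop(t(fourier_basis(m2, phi1)) %*% C12 %*% fourier_basis(m2, phi2)))
  }
  list(g11 = g11, g12 = g12)
}

pair_rhs <- function(ev, omega0) {
  function(t, y, parms) {
    G11a <- ev$g11(y[1])
    G11b <- ev$g11(y[2])
    g12 <- ev$g12(y[1], y[2])
    # Q_i = omega0 * Gamma_11(phi_i); solve the 2x2 force balance
    det <- G11a * G11b - g12 * g12
    if (det <= 0) {
      stop("singular 2x2 force balance (|C1 C2| >= 1).", call. = FALSE)
    }
    Q1 <- omega0 * G11a
    Q2 <- omega0 * G11b
    list(c((G11b * Q1 - g12 * Q2) / det,
           (G11a * Q2 - g12 * Q1) / det))
  }
}

#' Integrate the coupled phase dynamics of a cilia pair
#'
#' Solves the 2 x 2 force balance
#' `Q_i(phi_i) = Gamma_11(phi_i) phidot_i + Gamma_12(phi_1, phi_2)
#' phidot_j` at every step (with `Q_i = omega0 Gamma_11(phi_i)`, the
#' calibrated driving force) and integrates `(phi1, phi2)` for a given
#' number of mean-phase cycles. The phase difference `delta = phi2 - phi1`
#' is sampled exactly at mean-phase multiples of 2 pi by event detection.
#'
#' @param tables A [pair_friction_tables()] result.
#' @param state0 Length-2 initial phases `(phi1, phi2)` (rad).
#' @param n_cycles Number of mean-phase cycles to integrate.
#' @param omega0 Intrinsic angular frequency (defaults to the pair
#'   config's).
#' @param save_per_cycle Dense output points per cycle in the returned
#'   trajectory.
#' @param rtol,atol Integrator tolerances.
#' @return A tibble `t, phi1, phi2, delta, phibar` (delta wrapped to
#'   `(-pi, pi]`), with attribute `"cycle_samples"`: a tibble of `cycle`,
#'   `t`, `delta` at `phibar = 2 pi k`.
#' @export
integrate_cilia_pair <- function(tables, state0, n_cycles = 10,
                                 omega0 = tables$config$omega0,
                                 save_per_cycle = 16, rtol = 1e-9,
                                 atol = 1e-11) {
  ev <- pair_evaluators(tables)
  rhs <- pair_rhs(ev, omega0)
  T0 <- 2 * pi / omega0
  y <- as.numeric(state0)
  tcur <- 0
  phibar0 <- mean(y)
  traj <- list()
  cyc <- list()
  for (k in seq_len(n_cycles)) {
    target <- phibar0 + 2 * pi * k
    root <- function(t, y, parms) (y[1] + y[2]) / 2 - target
    times <- seq(tcur, tcur + 1.6 * T0, length.out = save_per_cycle + 1L)
    sol <- deSolve::lsodar(y, times, rhs, NULL, rtol = rtol, atol = atol,
                           rootfunc = root)
    traj[[k]] <- sol[-1, , drop = FALSE]
    last <- sol[nrow(sol), ]
    if (abs((last[2] + last[3]) / 2 - target) > 1e-6) {
      stop("mean phase did not complete the cycle in the bracketing ",
           "window.", call. = FALSE)
    }
    tcur <- unname(last[1])
    y <- unname(last[2:3])
    cyc[[k]] <- c(cycle = k, t = tcur, delta = y[2] - y[1])
  }
  tr <- do.call(rbind, traj)
  out <- tibble::tibble(t = tr[, 1], phi1 = tr[, 2], phi2 = tr[, 3])
  out$delta <- wrap_pi(out$phi2 - out$phi1)
  out$phibar <- (out$phi1 + out$phi2) / 2
  cs <- do.call(rbind, cyc)
  attr(out, "cycle_samples") <- tibble::tibble(
    cycle = unname(cs[, 1]), t = unname(cs[, 2]),
    delta = unname(wrap_pi(cs[, 3])))
  out
}

# wrap an angle to (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}

#' One-cycle Lyapunov exponent of the in-phase state
#'
#' Starts the pair at `phi1 = -delta0/2`, `phi2 = +delta0/2`, integrates
#' until the mean phase completes one cycle (`phibar(T) = 2 pi`, located by
#' event detection), and returns the dimensionless exponent
#' `lambda = log|delta(T) / delta0|`. Negative values mean the in-phase
#' synchronized state is linearly stable.
#'
#' @param tables A [pair_friction_tables()] result.
#' @param delta0 Initial phase-difference perturbation (rad); must be
#'   small (default 1e-3).
#' @param omega0 Intrinsic angular frequency.
#' @param rtol,atol Integrator tolerances.
#' @return Scalar `lambda` with attribute `"delta1"` (the phase difference
#'   after one cycle). Warns if the perturbation leaves the linear regime
#'   (`|delta| > 0.1`) during the cycle.
#' @export
lyapunov_exponent <- function(tables, delta0 = 1e-3,
                              omega0 = tables$config$omega0,
                              rtol = 1e-10, atol = 1e-12) {
  if (delta0 == 0) stop("`delta0` must be nonzero.", call. = FALSE)
  tr <- integrate_cilia_pair(tables, c(-delta0 / 2, delta0 / 2),
                             n_cycles = 1, omega0 = omega0,
                             save_per_cycle = 32, rtol = rtol, atol = atol)
  if (max(abs(tr$delta)) > 0.1) {
    warning("perturbation grew beyond the linear regime (|delta| > 0.1); ",
            "shrink `delta0`.", call. = FALSE)
  }
  d1 <- unname(attr(tr, "cycle_samples")$delta[1])
  structure(log(abs(d1 / delta0)), delta1 = d1)
}

#' Steady-state phase difference of a cilia pair
#'
#' Integrates the pair from a fan of initial phase differences, sampling
#' `delta` at mean-phase multiples of 2 pi, until the per-cycle change
#' falls below `conv_tol` (or `max_cycles` is reached). Converged values
#' are clustered (circular distance below `cluster_tol`) into attractors.
#'
#' @param tables A [pair_friction_tables()] result.
#' @param initial_deltas Fan of initial `delta` values; default 8 values
#'   spanning `(-pi, pi]`.
#' @param max_cycles Cycle horizon per initial condition.
#' @param conv_tol Convergence threshold on `|delta_k - delta_{k-1}|`.
#' @param cluster_tol Clustering tolerance for attractor values (rad).
#' @param omega0 Intrinsic angular frequency.
#' @param rtol,atol Integrator tolerances.
#' @return A tibble with one row per initial condition: `delta0`,
#'   `delta_star`, `converged`, `neutral` (no measurable drift at all,
#'   e.g. vanishing coupling), `cycles`; attribute `"attractors"` is a
#'   tibble of clustered attractor values with basin counts.
#' @export
steady_state_phase_difference <- function(tables,
                                          initial_deltas =
                                            seq(-3, 4) * pi / 4,
                                          max_cycles = 200,
                                          conv_tol = 1e-4,
                                          cluster_tol = 0.05,
                                          omega0 = tables$config$omega0,
                                          rtol = 1e-9, atol = 1e-11) {
  ev <- pair_evaluators(tables)
  rhs <- pair_rhs(ev, omega0)
  T0 <- 2 * pi / omega0
  run_one <- function(d0) {
    y <- c(-d0 / 2, d0 / 2)
    tcur <- 0
    prev <- d0
    drift <- 0
    for (k in seq_len(max_cycles)) {
      target <- 2 * pi * k
      root <- function(t, y, parms) (y[1] + y[2]) / 2 - target
      sol <- deSolve::lsodar(y, c(tcur, tcur + 1.6 * T0), rhs, NULL,
                             rtol = rtol, atol = atol, rootfunc = root)
      tcur <- unname(sol[nrow(sol), 1])
      y <- unname(sol[nrow(sol), 2:3])
      cur <- y[2] - y[1]
      drift <- max(drift, abs(cur - d0))
      if (k == 6L && drift < conv_tol) {
        # no measurable drift at all: neutral coupling, not convergence
        return(list(delta_star = wrap_pi(d0), converged = FALSE,
                    neutral = TRUE, cycles = k))
      }
      if (k > 5 && abs(cur - prev) < conv_tol) {
        return(list(delta_star = wrap_pi(cur), converged = TRUE,
                    neutral = FALSE, cycles = k))
      }
      prev <- cur
    }
    list(delta_star = wrap_pi(prev), converged = FALSE, neutral = FALSE,
         cycles = max_cycles)
  }
  res <- purrr::map(initial_deltas, run_one)
  out <- tibble::tibble(
    delta0 = initial_deltas,
    delta_star = vapply(res, `[[`, numeric(1), "delta_star"),
    converged = vapply(res, `[[`, logical(1), "converged"),
    neutral = vapply(res, `[[`, logical(1), "neutral"),
    cycles = vapply(res, `[[`, numeric(1), "cycles")
  )
  conv <- dplyr::filter(out, .data$converged)
  attractors <- if (nrow(conv)) cluster_circular(conv$delta_star,
                                                 cluster_tol) else
    tibble::tibble(delta_star = numeric(0), n_basin = integer(0))
  attr(out, "attractors") <- attractors
  out
}

circ_dist <- function(a, b) abs(wrap_pi(a - b))

cluster_circular <- function(x, tol) {
  centers <- list()
  members <- list()
  for (v in x) {
    hit <- FALSE
    for (j in seq_along(centers)) {
      if (circ_dist(v, centers[[j]]) <= tol) {
        members[[j]] <- c(members[[j]], v)
        # circular mean of the cluster
        centers[[j]] <- atan2(mean(sin(members[[j]])),
                              mean(cos(members[[j]])))
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      centers[[length(centers) + 1L]] <- v
      members[[length(members) + 1L]] <- v
    }
  }
  tibble::tibble(delta_star = unlist(centers),
                 n_basin = vapply(members, length, integer(1)))
}

#' Scan cilia-pair coupling and synchronization over distance/direction
#'
#' For every combination of separation distance and direction, builds the
#' pair tables, records the grid L2 norm of the cross-friction coefficient
#' over the phase torus and the one-cycle Lyapunov exponent of the
#' in-phase state.
#'
#' @param pattern A [synthetic_beat_pattern()].
#' @param d Vector of separation distances (m).
#' @param psi Vector of separation directions (rad).
#' @param config A [kernel_config()] (half space).
#' @param m Phase grid nodes per coordinate.
#' @param omega0 Intrinsic angular frequency (rad/s).
#' @param delta0 Lyapunov perturbation (rad).
#' @param radius,n_segments Cilium discretization.
#' @return A tibble of class `pair_scan` with columns `d`, `psi`,
#'   `gamma12_norm` (N m s), `lambda`, `self_approx_error`.
#' @export
scan_cilia_pair <- function(pattern, d, psi, config, m = 16,
                            omega0 = 2 * pi * 32, delta0 = 1e-3,
                            radius = 1e-7,
                            n_segments = pattern$n_segments) {
  grid <- tidyr::expand_grid(d = d, psi = psi)
  rows <- purrr::pmap(grid, function(d, psi) {
    pair <- cilia_pair_config(d = d, psi = psi, omega0 = omega0)
    tab <- pair_friction_tables(pattern, pair, config, m = m,
                                radius = radius, n_segments = n_segments)
    g12 <- tab$pair$values[, , 1, 2]
    lam <- lyapunov_exponent(tab, delta0 = delta0)
    tibble::tibble(d = d, psi = psi,
                   gamma12_norm = sqrt(mean(g12^2)),
                   lambda = as.numeric(lam),
                   self_approx_error = tab$self_approx_error)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pair_scan", class(out))
  attr(out, "L") <- pattern$L
  out
}

#' Fit far-field power laws to a pair scan
#'
#' Least-squares slopes of `log(gamma12_norm)` and `log|lambda|` against
#' `log(d)`, per direction. Near-field distances (`d < 1.5 L`) are
#' excluded from the fit with a warning.
#'
#' @param scan A [scan_cilia_pair()] result.
#' @param min_d Far-field threshold (m); defaults to 1.5 cilium lengths.
#' @return A tibble with one row per `psi`: fitted `exponent_gamma12` and
#'   `exponent_lambda` (positive numbers for a `1/d^p` decay) and the
#'   number of distances used.
#' @export
fit_power_law <- function(scan, min_d = 1.5 * attr(scan, "L")) {
  thr <- min_d * (1 - 1e-9) # d = min_d itself is far field (inclusive)
  if (any(scan$d < thr)) {
    warning(sprintf("excluding %d near-field distances (d < %.3g m) from ",
                    sum(scan$d < thr), min_d), "the power-law fit",
            call. = FALSE)
  }
  far <- dplyr::filter(scan, .data$d >= thr)
  if (length(unique(far$d)) < 4L) {
    warning("fewer than 4 far-field distances in the fit.", call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(far), .data$psi),
    exponent_gamma12 =
      -stats::coef(stats::lm(log(.data$gamma12_norm) ~ log(.data$d)))[[2]],
    exponent_lambda =
      -stats::coef(stats::lm(log(abs(.data$lambda)) ~ log(.data$d)))[[2]],
    n_distances = dplyr::n(),
    .groups = "drop"
  )
}

#' Plot a pair scan
#'
#' Log-log decay of the cross-friction norm and Lyapunov-exponent
#' magnitude with distance, one curve per direction.
#'
#' @param object A `pair_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pair_scan
#' @export
autoplot.pair_scan <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object),
                  `|lambda|` = abs(.data$lambda),
                  `||Gamma12||` = .data$gamma12_norm,
                  lambda = NULL, gamma12_norm = NULL,
                  self_approx_error = NULL),
    cols = c("|lambda|", "||Gamma12||"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$value,
                                   colour = factor(round(.data$psi, 3)))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "separation d (m)", y = NULL, colour = "psi (rad)")
}
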