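# Synthetic three-dimensional cilium beat pattern above a no-slip wall.
#
# The centerline is generated from a traveling wave of the tangent angle:
# with arclength fraction u = s/L and phase phi, the polar angle from the
# wall normal is
#     theta(u, phi) = theta_mean + (amp_base + amp_tip * u) *
#                     cos(phi - wavenumber * u)
# and the out-of-plane azimuth is
#     chi(u, phi)   = asym * u * sin(phi - wavenumber * u - asym_lag),
# the unit tangent t = (sin th sin chi, sin th cos chi, cos th) being
# integrated from the wall-anchored base. The growing amplitude along the
# filament and the traveling-wave phase lag produce a non-reciprocal beat
# with an extended, fast effective stroke sweeping the +y half-space and a
# curled recovery stroke closer to the wall; `asym` breaks the yz mirror
# symmetry of the beat plane during recovery (a three-dimensional beat).
# Setting `asym = 0` gives a planar beat confined to the yz-plane.

#' Synthetic cilium beat pattern
#'
#' A 2-pi-periodic family of wall-anchored centerline shapes emulating a
#' Paramecium-like beat with distinct effective and recovery strokes (see
#' the package vignette for the construction). The effective stroke sweeps
#' in the `+y` half-space; `+y` is the stroke direction by convention.
#'
#' @param L Cilium length (m); default 10 micrometres.
#' @param n_segments Default discretization count.
#' @param theta_mean Mean tilt of the tangent from the wall normal towards
#'   `+y` (rad).
#' @param amp_base,amp_tip Tangent-angle oscillation amplitude at the base
#'   and its increase towards the tip (rad).
#' @param wavenumber Phase lag of the tangent wave from base to tip (rad);
#'   positive values make the wave travel tipwards (non-reciprocal beat).
#' @param asym Out-of-plane (x) tangent amplitude at the tip (rad); `0`
#'   gives a planar beat.
#' @param asym_lag Phase lag of the out-of-plane component (rad).
#' @param validate Check wall clearance and non-self-intersection across
#'   the cycle (error with a diagnostic on failure).
#' @return An object of class `beat_pattern`.
#' @export
synthetic_beat_pattern <- function(L = 10e-6, n_segments = 20,
                                   theta_mean = 0.45, amp_base = 0.35,
                                   amp_tip = 1.25, wavenumber = 1.8,
                                   asym = 0.35, asym_lag = 1.2,
                                   validate = TRUE) {
  stopifnot(L > 0, n_segments >= 10)
  pat <- structure(
    list(L = L, n_segments = as.integer(n_segments),
         theta_mean = theta_mean, amp_base = amp_base, amp_tip = amp_tip,
         wavenumber = wavenumber, asym = asym, asym_lag = asym_lag,
         stroke_direction = c(0, 1, 0)),
    class = "beat_pattern")
  if (validate) validate_beat_pattern(pat)
  pat
}

#' @export
print.beat_pattern <- function(x, ...) {
  cat("<beat_pattern> L =", format(x$L), "m,", x$n_segments,
      "segments, effective stroke along +y\n")
  invisible(x)
}

beat_angles <- function(pattern, phi, u) {
  th <- pattern$theta_mean +
    (pattern$amp_base + pattern$amp_tip * u) *
      cos(phi - pattern$wavenumber * u)
  ch <- pattern$asym * u * sin(phi - pattern$wavenumber * u -
                                 pattern$asym_lag)
  list(theta = th, chi = ch)
}

#' Evaluate a beat-pattern centerline
#'
#' Returns the positions of `n` material points at arclengths
#' `s_k = (k - 1/2) L / n` (segment midpoints), integrated from the
#' wall-anchored base at the origin by the midpoint rule on the unit
#' tangent. Exactly 2-pi-periodic in `phi`.
#'
#' @param pattern A [synthetic_beat_pattern()].
#' @param phi Phase (rad).
#' @param n Number of points (defaults to the pattern's segment count).
#' @return n x 3 matrix of positions (m); base at the origin, wall at
#'   `z = 0`.
#' @export
beat_centerline <- function(pattern, phi, n = pattern$n_segments) {
  ds <- pattern$L / n
  u <- (seq_len(n) - 0.5) / n
  a <- beat_angles(pattern, phi, u)
  tx <- sin(a$theta) * sin(a$chi)
  ty <- sin(a$theta) * cos(a$chi)
  tz <- cos(a$theta)
  cbind(cumsum(tx) * ds, cumsum(ty) * ds, cumsum(tz) * ds)
}

#' Analytic phase derivative of the centerline
#'
#' `d r / d phi` at the same material points as [beat_centerline()],
#' obtained by differentiating the tangent construction in closed form.
#' Used as the oracle for finite-difference velocity bases.
#'
#' @inheritParams beat_centerline
#' @return n x 3 matrix (m/rad).
#' @export
beat_centerline_dphi <- function(pattern, phi, n = pattern$n_segments) {
  ds <- pattern$L / n
  u <- (seq_len(n) - 0.5) / n
  a <- beat_angles(pattern, phi, u)
  dth <- -(pattern$amp_base + pattern$amp_tip * u) *
    sin(phi - pattern$wavenumber * u)
  dch <- pattern$asym * u * cos(phi - pattern$wavenumber * u -
                                  pattern$asym_lag)
  dtx <- cos(a$theta) * sin(a$chi) * dth + sin(a$theta) * cos(a$chi) * dch
  dty <- cos(a$theta) * cos(a$chi) * dth - sin(a$theta) * sin(a$chi) * dch
  dtz <- -sin(a$theta) * dth
  cbind(cumsum(dtx) * ds, cumsum(dty) * ds, cumsum(dtz) * ds)
}

validate_beat_pattern <- function(pattern, n_phi = 32, n = 60) {
  phis <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  ds <- pattern$L / n
  for (phi in phis) {
    r <- beat_centerline(pattern, phi, n)
    if (min(r[, 3]) <= 0) {
      stop(sprintf(paste0("beat pattern penetrates the wall at phi = %.3f ",
                          "(min z = %.3g m); adjust theta_mean/amplitudes"),
                   phi, min(r[, 3])), call. = FALSE)
    }
    D <- as.matrix(stats::dist(r))
    D[abs(row(D) - col(D)) <= 1L] <- Inf
    if (min(D) < ds) {
      stop(sprintf("beat pattern self-intersects at phi = %.3f", phi),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Shape model of a single wall-anchored cilium
#'
#' Discretizes the beat-pattern centerline into a chain of equally spaced
#' blob elements (slender-filament discretization): one periodic
#' generalized coordinate, the beat phase.
#'
#' @param pattern A [synthetic_beat_pattern()].
#' @param base Length-3 base point on the wall plane (`z = 0`).
#' @param radius Cilium radius = blob radius (m); default 0.1 micrometres.
#' @param n_segments Number of blob elements.
#' @return A [shape_model()] with one periodic coordinate.
#' @export
cilium_shape_model <- function(pattern, base = c(0, 0, 0), radius = 1e-7,
                               n_segments = pattern$n_segments) {
  if (base[3] != 0) {
    stop("cilium base must lie on the wall plane z = 0.", call. = FALSE)
  }
  ds <- pattern$L / n_segments
  if (ds < 2 * radius) {
    stop(sprintf(paste0("segment spacing %.3g m below the element diameter ",
                        "%.3g m; reduce `n_segments` or `radius`"),
                 ds, 2 * radius), call. = FALSE)
  }
  area <- 2 * pi * radius * ds # lateral surface area per segment
  gen <- function(q) {
    pts <- sweep(beat_centerline(pattern, q[1], n_segments), 2, base, "+")
    surface_sample(pts, rep(area, n_segments), rep(radius, n_segments))
  }
  shape_model(gen, 1L, coord_roles = "periodic", coord_units = "rad",
              fd_step = 1e-6,
              id = sprintf("cilium[base=%s]",
                           paste(signif(base, 8), collapse = ",")))
}

#' Configuration of an interacting cilia pair
#'
#' @param d Base-point separation (m).
#' @param psi Separation direction, angle from the `+x` axis (rad); the
#'   effective stroke of both cilia points along `+y`.
#' @param omega0 Intrinsic beat angular frequency (rad/s); default
#'   `2 pi * 32` (a 32 Hz beat).
#' @return Object of class `cilia_pair_config`.
#' @export
cilia_pair_config <- function(d = 18e-6, psi = 5 * pi / 6,
                              omega0 = 2 * pi * 32) {
  stopifnot(d > 0)
  structure(list(d = d, psi = psi %% (2 * pi), omega0 = omega0),
            class = "cilia_pair_config")
}

#' Shape model of two interacting cilia
#'
#' Two identical cilia beating in the same direction: cilium 1 anchored at
#' the origin, cilium 2 at distance `d` along direction `psi`. Two
#' periodic coordinates `(phi1, phi2)`.
#'
#' @param pattern A [synthetic_beat_pattern()].
#' @param pair A [cilia_pair_config()].
#' @param radius,n_segments As in [cilium_shape_model()].
#' @return A [shape_model()] with two periodic coordinates; elements of
#'   cilium 1 first.
#' @export
cilia_pair_model <- function(pattern, pair, radius = 1e-7,
                             n_segments = pattern$n_segments) {
  base2 <- c(pair$d * cos(pair$psi), pair$d * sin(pair$psi), 0)
  ds <- pattern$L / n_segments
  if (ds < 2 * radius) {
    stop("segment spacing below element diameter.", call. = FALSE)
  }
  area <- 2 * pi * radius * ds
  gen <- function(q) {
    r1 <- beat_centerline(pattern, q[1], n_segments)
    r2 <- sweep(beat_centerline(pattern, q[2], n_segments), 2, base2, "+")
    surface_sample(rbind(r1, r2), rep(area, 2L * n_segments),
                   rep(radius, 2L * n_segments))
  }
  shape_model(gen, 2L, coord_roles = c("periodic", "periodic"),
              coord_units = c("rad", "rad"), fd_step = c(1e-6, 1e-6),
              id = sprintf("cilia_pair[d=%.4g,psi=%.6g]", pair$d, pair$psi))
}

#' Plot a beat pattern
#'
#' Projections of the centerline over one beat cycle, colored by phase.
#'
#' @param object A `beat_pattern`.
#' @param n_phi Number of phases drawn.
#' @param plane `"yz"` (side view, stroke plane) or `"xy"` (top view).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot beat_pattern
#' @export
autoplot.beat_pattern <- function(object, n_phi = 16, plane = c("yz", "xy"),
                                  ...) {
  plane <- match.arg(plane)
  phis <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  df <- purrr::map_dfr(phis, function(p) {
    r <- beat_centerline(object, p, 50)
    tibble::tibble(phi = p, x = r[, 1], y = r[, 2], z = r[, 3])
  })
  ax <- if (plane == "yz") c("y", "z") else c("x", "y")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                   group = .data$phi,
                                   colour = .data$phi)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c(name = "phase (rad)") +
    ggplot2::labs(x = paste(ax[1], "(m)"), y = paste(ax[2], "(m)"))
}
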