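# Hydrodynamic kernels: regularized Stokeslet (free space) and the Blake
# image system (half space above a plane no-slip wall at z = 0).
#
# Conventions: SI units throughout (m, s, Pa s, N). Kernels return mobility
# tensors, i.e. velocity per unit *force* (not force density); quadrature
# weights (element areas) are applied by the callers.

#' Kernel configuration for zero-Reynolds-number flow
#'
#' Bundles the fluid and domain parameters used by every hydrodynamic
#' computation in the package: the dynamic viscosity, the flow domain
#' (unbounded fluid, or the half space `z > 0` above a rigid no-slip wall),
#' and the blob regularization length used for the singular self-interaction
#' of collocation points.
#'
#' The free-space kernel is the regularized Stokeslet of the standard smooth
#' blob \eqn{\phi_\epsilon(r) = 15\epsilon^4 / (8\pi (r^2+\epsilon^2)^{7/2})},
#' for which the velocity due to a point force \eqn{F} is
#' \deqn{u_i = \frac{F_j}{8\pi\mu} \left[ \delta_{ij}
#'   \frac{r^2 + 2\epsilon^2}{(r^2+\epsilon^2)^{3/2}} +
#'   \frac{r_i r_j}{(r^2+\epsilon^2)^{3/2}} \right].}
#' In the half space the image system of Blake is added: an image Stokeslet
#' of opposite sign plus a potential (source) doublet and a Stokeslet
#' doublet at the mirror point. Only the primary Stokeslet is regularized;
#' the image singularities sit a distance `2h` below the wall and are never
#' approached by admissible field points, so the no-slip condition on the
#' wall holds exactly as `eps_reg -> 0` and to `O(eps_reg^2/h^2)` otherwise.
#'
#' @param viscosity Dynamic viscosity \eqn{\mu} in Pa s. Default `1e-3`
#'   (water at room temperature).
#' @param domain `"free_space"` or `"half_space_wall"`. In the latter case
#'   the no-slip plane is fixed at `z = 0` and all source points must lie
#'   strictly above it.
#' @param eps_reg Default blob radius in metres, used when a surface sample
#'   does not carry per-element radii.
#' @return An object of class `kernel_config`.
#' @examples
#' cfg <- kernel_config(domain = "half_space_wall")
#' mobility_kernel(c(0, 0, 1e-6), c(2e-6, 0, 1e-6), cfg)
#' @export
kernel_config <- function(viscosity = 1e-3,
                          domain = c("free_space", "half_space_wall"),
                          eps_reg = 1e-7) {
  domain <- match.arg(domain)
  if (!is.numeric(viscosity) || length(viscosity) != 1L || viscosity <= 0) {
    stop("`viscosity` must be a single positive number (Pa s).", call. = FALSE)
  }
  if (!is.numeric(eps_reg) || length(eps_reg) != 1L || eps_reg <= 0) {
    stop("`eps_reg` must be a single positive length (m).", call. = FALSE)
  }
  structure(
    list(viscosity = viscosity, domain = domain,
         wall_plane = if (domain == "half_space_wall") 0 else NULL,
         eps_reg = eps_reg),
    class = "kernel_config"
  )
}

#' @export
print.kernel_config <- function(x, ...) {
  cat("<kernel_config> mu =", format(x$viscosity), "Pa s |", x$domain,
      "| eps_reg =", format(x$eps_reg), "m\n")
  invisible(x)
}

#' Mobility tensor of a (regularized) point force
#'
#' Velocity response at `field` to a unit point force at `source`:
#' the regularized Oseen tensor in free space, or the Blake image system in
#' the half space above the no-slip wall `z = 0`.
#'
#' @param source,field Numeric length-3 positions (m).
#' @param config A [kernel_config()].
#' @param eps Blob radius for this source (m); defaults to `config$eps_reg`.
#'   `eps = 0` requests the singular kernel, allowed only for
#'   `source != field`.
#' @return A 3 x 3 matrix, units m/s per N.
#' @export
mobility_kernel <- function(source, field, config, eps = config$eps_reg) {
  stopifnot(length(source) == 3L, length(field) == 3L)
  if (config$domain == "half_space_wall") {
    if (source[3] <= 0) {
      stop("source point must lie strictly above the no-slip wall (z > 0).",
           call. = FALSE)
    }
    if (field[3] < 0) {
      stop("field point below the no-slip wall.", call. = FALSE)
    }
  }
  if (eps == 0 && sum((source - field)^2) == 0) {
    stop("singular kernel (eps = 0) evaluated at field == source.",
         call. = FALSE)
  }
  G <- mobility_matrix(rbind(source), config, eps = eps,
                       field_points = rbind(field))
  matrix(G, 3L, 3L)
}

# Dense mobility matrix between source points (with per-source blob radii)
# and field points. Returns a (3*nf) x (3*ns) matrix mapping interleaved
# point forces (Fx1, Fy1, Fz1, Fx2, ...) to interleaved velocities.
# Fully vectorized over all source/field pairs.
mobility_matrix <- function(points, config, eps = NULL, field_points = NULL) {
  pts <- as.matrix(points)
  fp <- if (is.null(field_points)) pts else as.matrix(field_points)
  ns <- nrow(pts)
  nf <- nrow(fp)
  if (is.null(eps)) eps <- rep(config$eps_reg, ns)
  if (length(eps) == 1L) eps <- rep(eps, ns)
  mu <- config$viscosity
  half <- config$domain == "half_space_wall"
  if (half && any(pts[, 3] <= 0)) {
    stop("all source points must lie strictly above the wall (z > 0).",
         call. = FALSE)
  }

  dx <- outer(fp[, 1], pts[, 1], "-")
  dy <- outer(fp[, 2], pts[, 2], "-")
  dz <- outer(fp[, 3], pts[, 3], "-")
  E2 <- matrix(eps^2, nf, ns, byrow = TRUE)
  r2 <- dx * dx + dy * dy + dz * dz
  d3 <- (r2 + E2)^1.5
  c1 <- (r2 + 2 * E2) / d3
  cr <- list(dx, dy, dz)

  if (half) {
    # image point at (y1, y2, -h); R = field - image
    Rz <- outer(fp[, 3], pts[, 3], "+")
    H <- matrix(pts[, 3], nf, ns, byrow = TRUE) # source heights
    R2 <- dx * dx + dy * dy + Rz * Rz
    Rn1 <- sqrt(R2)
    Rn3 <- R2 * Rn1
    Rn5 <- R2 * Rn3
    cR <- list(dx, dy, Rz)
  }

  M <- matrix(0, 3L * nf, 3L * ns)
  for (i in 1:3) {
    rows <- seq(i, 3L * nf, by = 3L)
    for (k in 1:3) {
      cols <- seq(k, 3L * ns, by = 3L)
      B <- cr[[i]] * cr[[k]] / d3
      if (i == k) B <- B + c1
      if (half) {
        BI <- cR[[i]] * cR[[k]] / Rn3
        if (i == k) BI <- BI + 1 / Rn1
        Ri <- cR[[i]]; Rk <- cR[[k]]; R3 <- cR[[3]]
        D <- H * ((i == k) / Rn3 - 3 * Ri * Rk / Rn5) +
          (i == 3) * Rk / Rn3 -
          ((i == k) * R3 + (k == 3) * Ri) / Rn3 +
          3 * Ri * R3 * Rk / Rn5
        Dk <- if (k < 3) 1 else -1
        B <- B - BI + 2 * H * Dk * D
      }
      M[rows, cols] <- B
    }
  }
  M / (8 * pi * mu)
}

# interleave an n x 3 matrix of vectors into a 3n vector (x1,y1,z1,x2,...)
vec3 <- function(V) as.vector(t(V))
# inverse of vec3
mat3 <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Flow induced by a surface force distribution
#'
#' Superposes the mobility kernel over all elements of a surface sample:
#' \eqn{u(x) = \sum_k G(x, x_k)\, f_k A_k}, the discrete convolution of the
#' fundamental solution with the force distribution. Linear in
#' `force_density`.
#'
#' @param sample A [surface_sample()].
#' @param force_density n x 3 matrix of tractions (N/m^2), one row per
#'   element.
#' @param field_points m x 3 matrix of evaluation points.
#' @param config A [kernel_config()].
#' @return An m x 3 matrix of velocities (m/s).
#' @export
induced_flow <- function(sample, force_density, field_points, config) {
  fd <- as.matrix(force_density)
  if (nrow(fd) != nrow(sample$points) || ncol(fd) != 3L) {
    stop("`force_density` must be an n x 3 matrix matching the sample.",
         call. = FALSE)
  }
  fp <- as.matrix(field_points)
  if (ncol(fp) != 3L) stop("`field_points` must be m x 3.", call. = FALSE)
  M <- mobility_matrix(sample$points, config, eps = sample$element_radius,
                       field_points = fp)
  forces <- fd * sample$areas # point forces per element
  mat3(M %*% vec3(forces))
}
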