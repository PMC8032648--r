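# Precomputed friction tables: Gamma(q) sampled on a coordinate grid plus
# an interpolation rule (truncated Fourier series on periodic coordinates,
# so grid nodes are reproduced exactly and periodicity is built in).

#' Build a friction look-up table on a coordinate grid
#'
#' Evaluates the generalized friction matrix at every node of a tensor-
#' product grid over the generalized coordinates. With `m_i` values per
#' coordinate the resistance problem is solved `n * prod(m_i)` times in
#' total (n solves per node, sharing one factorization of the collocation
#' matrix per node); the count is stored in the table.
#'
#' @param model A [shape_model()].
#' @param grid_spec Either a single integer (number of nodes per
#'   coordinate) or a list with one entry per coordinate: an integer `m`
#'   (periodic coordinates get `m` uniform nodes on `[0, 2 pi)`, the
#'   duplicate endpoint excluded) or an explicit sorted numeric vector of
#'   nodes (required for non-periodic coordinates).
#' @param config A [kernel_config()].
#' @param interpolation `"fourier"` (default, periodic coordinates),
#'   `"cubic_spline"` or `"polynomial"` (single-coordinate tables).
#' @param node_budget Refuse (with a cost estimate) if the total node count
#'   exceeds this.
#' @return An object of class `friction_table`.
#' @export
build_friction_table <- function(model, grid_spec, config,
                                 interpolation = c("fourier", "cubic_spline",
                                                   "polynomial"),
                                 node_budget = 20000L) {
  interpolation <- match.arg(interpolation)
  n <- model$n_coords
  if (!is.list(grid_spec)) grid_spec <- rep(list(grid_spec), n)
  if (length(grid_spec) != n) {
    stop("`grid_spec` must have one entry per coordinate.", call. = FALSE)
  }
  grids <- vector("list", n)
  for (i in seq_len(n)) {
    g <- grid_spec[[i]]
    if (length(g) == 1L && g == round(g)) {
      if (model$coord_roles[i] != "periodic") {
        stop(paste0("a bare node count is only meaningful for periodic ",
                    "coordinates; give explicit nodes for coordinate ", i),
             call. = FALSE)
      }
      grids[[i]] <- 2 * pi * (seq_len(g) - 1L) / g
    } else {
      g <- as.numeric(g)
      if (is.unsorted(g, strictly = TRUE)) {
        stop("grid nodes must be strictly increasing.", call. = FALSE)
      }
      grids[[i]] <- g
    }
  }
  m <- vapply(grids, length, integer(1))
  nodes <- prod(m)
  if (nodes > node_budget) {
    stop(sprintf(paste0("grid has %d nodes (%d resistance solves), over ",
                        "the budget of %d nodes; shrink the grid or raise ",
                        "`node_budget`"), nodes, n * nodes, node_budget),
         call. = FALSE)
  }
  values <- array(NA_real_, dim = c(m, n, n))
  idx_grid <- as.matrix(expand.grid(lapply(m, seq_len)))
  for (r in seq_len(nrow(idx_grid))) {
    ii <- idx_grid[r, ]
    q <- vapply(seq_len(n), function(d) grids[[d]][ii[d]], numeric(1))
    G <- tryCatch(
      friction_matrix(model, q, config),
      error = function(e) {
        stop(sprintf("friction solve failed at node (%s): %s",
                     paste(signif(q, 6), collapse = ", "),
                     conditionMessage(e)), call. = FALSE)
      }
    )
    values[cbind(matrix(ii, n * n, n, byrow = TRUE),
                 as.matrix(expand.grid(seq_len(n), seq_len(n))))] <- c(G)
  }
  new_friction_table(grids, values, model$coord_roles, model$coord_units,
                     interpolation, model$id, config,
                     solve_count = n * nodes)
}

new_friction_table <- function(grids, values, coord_roles, coord_units,
                               interpolation, model_id, config,
                               solve_count = NA_integer_) {
  n <- length(dim(values)) - 2L
  tab <- structure(
    list(grids = grids, values = values, coord_roles = coord_roles,
         coord_units = coord_units, interpolation = interpolation,
         n_coords = n, model_id = model_id,
         config = config[c("viscosity", "domain", "eps_reg")],
         config_hash = rlang::hash(config[c("viscosity", "domain",
                                            "eps_reg")]),
         solve_count = solve_count),
    class = "friction_table")
  if (interpolation == "fourier") {
    tab$fourier <- fourier_coefficients(tab)
  }
  tab
}

#' @export
print.friction_table <- function(x, ...) {
  cat("<friction_table>", x$model_id, "|", x$n_coords, "coordinate(s), grid",
      paste(vapply(x$grids, length, integer(1)), collapse = " x "),
      "|", x$interpolation, "interpolation |", x$solve_count,
      "resistance solves\n")
  invisible(x)
}

# ---- Fourier machinery (uniform periodic grids) ------------------------

# integer frequencies for an m-point uniform grid; the Nyquist mode of an
# even grid is treated as a pure cosine so that interpolants are real and
# reproduce nodes exactly
fourier_freqs <- function(m) {
  if (m %% 2L == 0L) c(0:(m / 2), -(m / 2 - 1):-1) else
    c(0:((m - 1) / 2), -((m - 1) / 2):-1)
}

fourier_basis <- function(m, x) {
  k <- fourier_freqs(m)
  e <- exp(1i * k * x)
  if (m %% 2L == 0L) e[m / 2 + 1] <- cos(k[m / 2 + 1] * x)
  e
}

# per-entry multidimensional FFT coefficients of the value array
fourier_coefficients <- function(tab) {
  dims <- dim(tab$values)
  n <- tab$n_coords
  m <- dims[seq_len(n)]
  cf <- array(0i, dim = dims)
  ent <- as.matrix(expand.grid(seq_len(n), seq_len(n)))
  for (r in seq_len(nrow(ent))) {
    sl <- do.call(`[`, c(list(tab$values),
                         rep(list(quote(expr = )), n),
                         list(ent[r, 1], ent[r, 2]), list(drop = FALSE)))
    sl <- array(sl, dim = m)
    cf_r <- stats::fft(sl) / prod(m)
    cf <- do.call(`[<-`, c(list(cf), rep(list(quote(expr = )), n),
                           list(ent[r, 1], ent[r, 2]), list(cf_r)))
  }
  cf
}

# contract the first margin of a complex array with a vector
contract_first <- function(arr, v) {
  d <- dim(arr)
  mat <- matrix(arr, d[1], prod(d[-1]))
  res <- drop(t(v) %*% mat)
  if (length(d) > 1L) array(res, dim = d[-1]) else res
}

fourier_eval_table <- function(tab, q) {
  n <- tab$n_coords
  arr <- tab$fourier
  for (d in seq_len(n)) {
    e <- fourier_basis(length(tab$grids[[d]]), q[d])
    arr <- contract_first(arr, e)
  }
  matrix(Re(arr), n, n)
}

# ---- interpolation ------------------------------------------------------

wrap_periodic <- function(x) x %% (2 * pi)

#' Interpolate a friction table at arbitrary coordinates
#'
#' Entrywise interpolation of the stored symmetric matrices by the table's
#' rule. Periodic coordinates are wrapped; Fourier interpolation uses all
#' `m` modes so stored nodes are reproduced exactly and the interpolant is
#' 2-pi-periodic by construction. Extrapolation beyond the grid of a
#' non-periodic coordinate is a domain error.
#'
#' @param table A [build_friction_table()] result.
#' @param q Coordinate vector.
#' @return An n x n `friction_matrix`.
#' @export
interpolate_friction <- function(table, q) {
  stopifnot(length(q) == table$n_coords)
  n <- table$n_coords
  for (d in seq_len(n)) {
    if (table$coord_roles[d] == "periodic") {
      q[d] <- wrap_periodic(q[d])
    } else {
      rg <- range(table$grids[[d]])
      if (q[d] < rg[1] || q[d] > rg[2]) {
        stop(sprintf(paste0("coordinate %d = %.6g outside the table domain ",
                            "[%.6g, %.6g] (non-periodic coordinate)"),
                     d, q[d], rg[1], rg[2]), call. = FALSE)
      }
    }
  }
  G <- switch(table$interpolation,
    fourier = fourier_eval_table(table, q),
    cubic_spline = spline_eval_table(table, q),
    polynomial = poly_eval_table(table, q)
  )
  G <- (G + t(G)) / 2
  structure(G, class = c("friction_matrix", "matrix"), q = q,
            coord_units = table$coord_units, model_id = table$model_id)
}

spline_eval_table <- function(tab, q) {
  if (tab$n_coords != 1L) {
    stop("cubic_spline interpolation is implemented for one-coordinate ",
         "tables only; use fourier for multi-coordinate tables.",
         call. = FALSE)
  }
  g <- tab$grids[[1]]
  n <- 1L
  periodic <- tab$coord_roles[1] == "periodic"
  y <- tab$values[, 1, 1]
  if (periodic) {
    f <- stats::splinefun(c(g, g[1] + 2 * pi), c(y, y[1]),
                          method = "periodic")
  } else {
    f <- stats::splinefun(g, y, method = "fmm")
  }
  matrix(f(q), 1, 1)
}

poly_eval_table <- function(tab, q) {
  if (tab$n_coords != 1L) {
    stop("polynomial interpolation is implemented for one-coordinate ",
         "tables only.", call. = FALSE)
  }
  g <- tab$grids[[1]]
  y <- tab$values[, 1, 1]
  # Lagrange interpolation (exact at nodes); sensible for small m only
  val <- sum(vapply(seq_along(g), function(j) {
    lj <- prod((q - g[-j]) / (g[j] - g[-j]))
    y[j] * lj
  }, numeric(1)))
  matrix(val, 1, 1)
}

# ---- serialization ------------------------------------------------------

#' Write / read a friction table as JSON
#'
#' Plain-text serialization with exact float round-trip (17 significant
#' digits). The payload carries a provenance hash (model id,
#' kernel configuration, grids and values) that is recomputed and checked
#' on load. Rebuilding a table from an identical configuration yields a
#' byte-identical file.
#'
#' @param table A `friction_table`.
#' @param path File path (conventionally `.json`).
#' @return `read_friction_table()` returns the `friction_table`;
#'   `write_friction_table()` returns `path` invisibly.
#' @export
write_friction_table <- function(table, path) {
  payload <- list(
    format = "stokeslets/friction_table",
    model_id = table$model_id,
    config = table$config,
    config_hash = table$config_hash,
    coord_roles = table$coord_roles,
    coord_units = table$coord_units,
    interpolation = table$interpolation,
    grids = table$grids,
    dims = dim(table$values),
    values = as.vector(table$values),
    solve_count = table$solve_count
  )
  payload$payload_hash <- rlang::hash(payload[c("grids", "dims", "values",
                                                "config")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = I(17), pretty = FALSE)
  invisible(path)
}

#' @rdname write_friction_table
#' @export
read_friction_table <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "stokeslets/friction_table")) {
    stop("not a friction table file: ", path, call. = FALSE)
  }
  grids <- if (is.list(p$grids)) lapply(p$grids, as.numeric) else
    list(as.numeric(p$grids))
  chk <- rlang::hash(list(grids = grids, dims = as.integer(p$dims),
                          values = as.numeric(p$values),
                          config = list(viscosity = p$config$viscosity,
                                        domain = p$config$domain,
                                        eps_reg = p$config$eps_reg)))
  if (!identical(chk, p$payload_hash)) {
    stop("friction table provenance hash mismatch (corrupt or edited file).",
         call. = FALSE)
  }
  values <- array(as.numeric(p$values), dim = as.integer(p$dims))
  cfg <- kernel_config(p$config$viscosity, p$config$domain, p$config$eps_reg)
  new_friction_table(grids, values, p$coord_roles, p$coord_units,
                     p$interpolation, p$model_id, cfg,
                     solve_count = as.integer(p$solve_count))
}

# ---- broom-style accessors ----------------------------------------------

#' Tidy a friction table into a long tibble
#'
#' One row per grid node and matrix entry, with the node coordinates, the
#' entry indices and the friction value.
#'
#' @param x A `friction_table`.
#' @param ... Unused.
#' @return A tibble with columns `q1..qn`, `i`, `j`, `gamma`.
#' @method tidy friction_table
#' @export
tidy.friction_table <- function(x, ...) {
  n <- x$n_coords
  # column-major array layout: grid dimensions first, then (i, j)
  v <- as.vector(x$values)
  grid_df <- expand.grid(x$grids)
  per_entry <- nrow(grid_df)
  res <- dplyr::bind_rows(lapply(seq_len(n * n), function(r) {
    i <- ((r - 1L) %% n) + 1L
    j <- ((r - 1L) %/% n) + 1L
    d <- tibble::as_tibble(stats::setNames(grid_df,
                                           paste0("q", seq_len(n))))
    d$i <- i
    d$j <- j
    d$gamma <- v[(r - 1L) * per_entry + seq_len(per_entry)]
    d
  }))
  res
}

#' One-line summary of a friction table
#'
#' @param x A `friction_table`.
#' @param ... Unused.
#' @return A one-row tibble: coordinate count, grid sizes, node and solve
#'   counts, interpolation rule, model id.
#' @method glance friction_table
#' @export
glance.friction_table <- function(x, ...) {
  tibble::tibble(
    n_coords = x$n_coords,
    grid = paste(vapply(x$grids, length, integer(1)), collapse = "x"),
    nodes = prod(vapply(x$grids, length, integer(1))),
    solve_count = x$solve_count,
    interpolation = x$interpolation,
    model_id = x$model_id
  )
}

#' Plot a friction table
#'
#' One-coordinate tables are drawn as curves Gamma_ij(q); multi-coordinate
#' tables as a raster of one entry over the first two coordinates.
#'
#' @param object A `friction_table`.
#' @param entry Length-2 integer: which matrix entry to plot (default the
#'   cross-friction `(1, 2)` when available, else `(1, 1)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot friction_table
#' @export
autoplot.friction_table <- function(object, entry = NULL, ...) {
  td <- tidy.friction_table(object)
  if (object$n_coords == 1L) {
    td$entry <- paste0("Gamma[", td$i, td$j, "]")
    ggplot2::ggplot(td, ggplot2::aes(x = .data$q1, y = .data$gamma,
                                     colour = .data$entry)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "coordinate", y = "generalized friction",
                    colour = NULL)
  } else {
    if (is.null(entry)) entry <- c(1L, 2L)
    sel <- dplyr::filter(td, .data$i == entry[1], .data$j == entry[2])
    ggplot2::ggplot(sel, ggplot2::aes(x = .data$q1, y = .data$q2,
                                      fill = .data$gamma)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient2() +
      ggplot2::labs(x = "coordinate 1", y = "coordinate 2",
                    fill = sprintf("Gamma[%d%d]", entry[1], entry[2]))
  }
}
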