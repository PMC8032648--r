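test_that("table build reports the n m^n solve count", {
  tab1 <- test_single_table(m = 12)
  expect_equal(tab1$solve_count, 12)
  expect_equal(dim(tab1$values), c(12, 1, 1))

  pat <- test_pattern()
  mod2 <- cilia_pair_model(pat, cilia_pair_config(), n_segments = 10)
  tab2 <- build_friction_table(mod2, 6, kernel_wall())
  expect_equal(tab2$solve_count, 2 * 6 * 6) # n m^n with n = 2, m = 6
  expect_equal(dim(tab2$values), c(6, 6, 2, 2))
})

test_that("node budget refusals carry a cost estimate", {
  pat <- test_pattern()
  mod <- cilia_pair_model(pat, cilia_pair_config())
  expect_error(build_friction_table(mod, 200, kernel_wall()),
               "40000 nodes .80000 resistance solves.")
})

test_that("rebuilding with identical configuration is deterministic", {
  pat <- test_pattern()
  mod <- cilium_shape_model(pat, n_segments = 12)
  t1 <- build_friction_table(mod, 8, kernel_wall())
  t2 <- build_friction_table(mod, 8, kernel_wall())
  expect_identical(t1$values, t2$values)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_friction_table(t1, f1)
  write_friction_table(t2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("interpolation reproduces stored nodes", {
  tab <- test_single_table(m = 12)
  for (k in c(1, 5, 12)) {
    G <- interpolate_friction(tab, tab$grids[[1]][k])
    expect_equal(G[1, 1], tab$values[k, 1, 1], tolerance = 1e-13)
  }
  # cubic spline variant
  pat <- test_pattern()
  mod <- cilium_shape_model(pat, n_segments = 12)
  tsp <- build_friction_table(mod, 8, kernel_wall(),
                              interpolation = "cubic_spline")
  for (k in c(2, 7)) {
    G <- interpolate_friction(tsp, tsp$grids[[1]][k])
    expect_equal(G[1, 1], tsp$values[k, 1, 1], tolerance = 1e-12)
  }
})

test_that("band-limited functions are interpolated to machine precision", {
  # synthetic 2-coordinate table with <= m/2 harmonics per coordinate
  m <- 12
  g <- 2 * pi * (seq_len(m) - 1) / m
  f11 <- function(a, b) 3 + cos(a) + 0.5 * sin(2 * a) + 0.2 * cos(3 * b)
  f12 <- function(a, b) 0.1 * sin(a - 2 * b) + 0.05 * cos(4 * a)
  vals <- array(NA_real_, c(m, m, 2, 2))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    vals[i, j, , ] <- matrix(c(f11(g[i], g[j]), f12(g[i], g[j]),
                               f12(g[i], g[j]), f11(g[j], g[i])), 2, 2)
  }
  tab <- stokeslets:::new_friction_table(
    list(g, g), vals, c("periodic", "periodic"), c("rad", "rad"),
    "fourier", "synthetic", kernel_free())
  set.seed(41)
  for (k in 1:25) {
    q <- runif(2, 0, 2 * pi)
    G <- interpolate_friction(tab, q)
    expect_equal(G[1, 1], f11(q[1], q[2]), tolerance = 1e-10)
    expect_equal(G[1, 2], f12(q[1], q[2]), tolerance = 1e-10)
  }
})

test_that("doubling the grid at least halves the interpolation error", {
  pat <- test_pattern()
  mod <- cilium_shape_model(pat, n_segments = 12)
  cfg <- kernel_wall()
  ref <- build_friction_table(mod, 48, cfg)
  probe <- 2 * pi * (0:40) / 41
  maxerr <- function(m) {
    tab <- build_friction_table(mod, m, cfg)
    max(vapply(probe, function(p) {
      abs(interpolate_friction(tab, p)[1, 1] -
            interpolate_friction(ref, p)[1, 1])
    }, numeric(1)))
  }
  e8 <- maxerr(8)
  e16 <- maxerr(16)
  expect_lt(e16, e8 / 2)
})

test_that("interpolant is periodic and stays symmetric positive definite", {
  tabs <- test_pair_tables(m = 12)
  set.seed(42)
  for (k in 1:50) {
    q <- runif(2, -10, 10)
    G <- interpolate_friction(tabs$pair, q)
    Gp <- interpolate_friction(tabs$pair, q + c(2 * pi, 0))
    expect_identical(unclass(G), unclass(Gp))
    expect_equal(G[1, 2], G[2, 1])
    expect_true(is_positive_definite(G))
  }
})

test_that("extrapolation on a non-periodic coordinate is a domain error", {
  g <- seq(0, 1, length.out = 5)
  vals <- array(g^2 + 1, c(5, 1, 1))
  tab <- stokeslets:::new_friction_table(
    list(g), vals, "linear", "m", "cubic_spline", "toy", kernel_free())
  expect_equal(interpolate_friction(tab, 0.5)[1, 1], 0.25 + 1,
               tolerance = 1e-2)
  expect_error(interpolate_friction(tab, 1.2), "outside the table domain")
})

test_that("tables round-trip through JSON with provenance checking", {
  tab <- test_single_table(m = 12)
  path <- tempfile(fileext = ".json")
  write_friction_table(tab, path)
  back <- read_friction_table(path)
  expect_identical(back$values, tab$values)
  expect_identical(back$grids, tab$grids)
  expect_equal(back$config$viscosity, tab$config$viscosity)
  expect_identical(back$config_hash, tab$config_hash)
  q <- 1.234
  expect_equal(interpolate_friction(back, q)[1, 1],
               interpolate_friction(tab, q)[1, 1], tolerance = 1e-14)
  # tampering is detected
  txt <- readLines(path, warn = FALSE)
  txt <- sub("\"model_id\":\"cilium", "\"model_id\":\"cilium-x", txt)
  p2 <- tempfile(fileext = ".json")
  writeLines(txt, p2)
  expect_no_error(read_friction_table(p2)) # model id not in payload hash
  txt2 <- readLines(path, warn = FALSE)
  txt2 <- sub("(\"values\":\\[)([-0-9.e]+)", "\\10.0", txt2)
  p3 <- tempfile(fileext = ".json")
  writeLines(txt2, p3)
  expect_error(read_friction_table(p3), "hash mismatch")
})

test_that("tidy and glance summarize tables", {
  tab <- test_single_table(m = 12)
  td <- tidy(tab)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 12)
  expect_named(td, c("q1", "i", "j", "gamma"))
  expect_equal(td$gamma, tab$values[, 1, 1])
  gl <- glance(tab)
  expect_equal(gl$nodes, 12)
  expect_equal(gl$solve_count, 12)
  tabs <- test_pair_tables(m = 12)
  td2 <- tidy(tabs$pair)
  expect_equal(nrow(td2), 12 * 12 * 4)
})
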