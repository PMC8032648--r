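# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, make(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

kernel_free <- function() kernel_config(domain = "free_space")
kernel_wall <- function() kernel_config(domain = "half_space_wall")

test_pattern <- function() fixture("pattern", function() {
  synthetic_beat_pattern()
})

# small single-cilium self-friction table (default pattern, 20 segments)
test_single_table <- function(m = 12) {
  fixture(paste0("single_m", m), function() {
    single_cilium_table(cilium_shape_model(test_pattern()),
                        kernel_wall(), m = m)
  })
}

# pair tables at the default geometry d = 18 um, psi = 5 pi / 6
test_pair_tables <- function(m = 12, psi = 5 * pi / 6) {
  fixture(sprintf("pair_m%d_psi%.4f", m, psi), function() {
    pair_friction_tables(test_pattern(),
                         cilia_pair_config(psi = psi),
                         kernel_wall(), m = m)
  })
}

# pair tables with the cross-friction zeroed out (uncoupled oscillators)
uncoupled_pair_tables <- function(m = 12) {
  fixture(paste0("uncoupled_m", m), function() {
    tabs <- test_pair_tables(m)
    vals <- tabs$pair$values
    vals[, , 1, 2] <- 0
    vals[, , 2, 1] <- 0
    tabs$pair <- stokeslets:::new_friction_table(
      tabs$pair$grids, vals, tabs$pair$coord_roles, tabs$pair$coord_units,
      "fourier", tabs$pair$model_id, kernel_wall())
    tabs
  })
}

# shape model of a rigid sphere with three translation coordinates
sphere_translation_model <- function(n = 300, a = 1e-6) {
  shape_model(
    function(q) sphere_sample(n, a, center = q),
    n_coords = 3,
    coord_roles = rep("rigid_translation", 3),
    coord_axes = list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    coord_units = rep("m", 3),
    id = "sphere_translations"
  )
}

stokes_drag <- function(mu = 1e-3, a = 1e-6) 6 * pi * mu * a

# standard four-phase non-reciprocal arm cycle of the three-sphere swimmer
three_sphere_cycle <- function(D = 6e-6, amp = 1.5e-6) {
  function(s) {
    s <- s %% 1
    if (s < 0.25) c(D - amp * (s / 0.25), D)
    else if (s < 0.5) c(D - amp, D - amp * ((s - 0.25) / 0.25))
    else if (s < 0.75) c(D - amp * (1 - (s - 0.5) / 0.25), D - amp)
    else c(D, D - amp * (1 - (s - 0.75) / 0.25))
  }
}

# ---- study-scale fixtures for the headline checks ----------------------

# distance scan at the study conditions: 20 segments, 16x16 phase grid,
# 5 distances spanning 15-60 um at the default direction psi = 5 pi / 6
acceptance_scan <- function() {
  fixture("acceptance_scan", function() {
    scan_cilia_pair(test_pattern(),
                    d = c(15, 22, 32, 45, 60) * 1e-6,
                    psi = 5 * pi / 6,
                    kernel_wall(), m = 16)
  })
}

# lambda over 12 separation directions at d = 18 um
direction_scan <- function(m = 16) {
  fixture(paste0("direction_scan_m", m), function() {
    psis <- 2 * pi * (0:11) / 12
    purrr::map_dfr(psis, function(psi) {
      tabs <- pair_friction_tables(test_pattern(),
                                   cilia_pair_config(psi = psi),
                                   kernel_wall(), m = m)
      tibble::tibble(psi = psi,
                     lambda = as.numeric(lyapunov_exponent(tabs)),
                     tables = list(tabs))
    })
  })
}
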