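test_that("a pure-vacuum scene lets photons escape untouched", {
  sc <- mc_scene(box_region(1, "ghost", -1, 1, -1, 1, -1, 1, "vacuum"),
                 world_bounds = c(-5, 5, -5, 5, -5, 5),
                 world_material = "vacuum")
  src <- source_spec("isotropic_point", c(0, 0, 0), 30, n_histories = 500)
  run <- run_transport(sc, src, seed = 4)
  expect_equal(run$deposited_keV, 0)
  expect_equal(run$escaped_keV, run$emitted_keV)
  expect_equal(run$n_zero_interaction_escapes, 500)
})

test_that("energy is conserved per history to machine precision", {
  run <- slab_case("water", 2, 30, 2e4, seed = 6, primaries_only = FALSE)
  expect_lt(run$max_conservation_err_keV, 1e-9)
  expect_equal(run$emitted_keV, run$deposited_keV + run$escaped_keV,
               tolerance = 1e-12)
  # and in a heterogeneous phantom with air world
  scn <- build_breast_phantom(phantom_spec(), screen_spec("lead_acrylic"))
  src <- phantom_source(phantom_spec(), 30, 5e3)
  run2 <- run_transport(scn, src, n_histories = 5e3, seed = 12)
  expect_lt(run2$max_conservation_err_keV, 1e-9)
})

test_that("uncollided fraction through a thin slab matches exp(-mu t)", {
  t <- 0.5
  mu <- linear_mu("water", 30)
  res <- slab_primary_fraction("water", t, 30, 1e5, seed = 21)
  expect_lt(abs(res$p - exp(-mu * t)), 3 * res$se)
})

test_that("disabling coherent scattering renormalizes the physics", {
  # primary transmission then reflects only photoelectric + incoherent
  t <- 1
  cfg <- transport_config(coherent_enabled = FALSE)
  scn <- mc_scene(box_region(1, "slab", -30, 30, -30, 30, 0, t, "water"),
                  world_bounds = c(-31, 31, -31, 31, -1, 3),
                  world_material = "vacuum")
  src <- source_spec("collimated_pyramid", c(0, 0, 2), 30,
                     footprint = c(-1e-4, 1e-4, -1e-4, 1e-4, t))
  pl <- plane_tally("back", "z", -0.5, -30, 30, -30, 30, primaries_only = TRUE)
  run <- run_transport(scn, src, planes = pl, config = cfg,
                       n_histories = 1e5, seed = 22)
  mu_nc <- linear_mu("water", 30, "photoelectric") +
    linear_mu("water", 30, "incoherent")
  p <- run$planes$count / 1e5
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(p - exp(-mu_nc * t)), 3 * se)
})

test_that("identical seed and configuration reproduce tallies bit for bit", {
  r1 <- slab_case("skin", 1, 25, 5e3, seed = 33, primaries_only = FALSE)
  r2 <- slab_case("skin", 1, 25, 5e3, seed = 33, primaries_only = FALSE)
  expect_identical(r1$cells$dep_sum_keV, r2$cells$dep_sum_keV)
  expect_identical(r1$cells$dep_sumsq_keV2, r2$cells$dep_sumsq_keV2)
  expect_identical(r1$planes$count, r2$planes$count)
  r3 <- slab_case("skin", 1, 25, 5e3, seed = 34, primaries_only = FALSE)
  expect_false(identical(r1$cells$dep_sum_keV, r3$cells$dep_sum_keV))
})

test_that("cutoff terminates histories with local deposition", {
  cfg <- transport_config(cutoff_keV = 25)   # brutal cutoff below 30 keV
  run <- slab_case("water", 5, 30, 2e3, seed = 41)
  run_cut <- {
    scn <- mc_scene(box_region(1, "slab", -30, 30, -30, 30, 0, 5, "water"),
                    world_bounds = c(-31, 31, -31, 31, -1, 7),
                    world_material = "vacuum")
    src <- source_spec("collimated_pyramid", c(0, 0, 6), 30,
                       footprint = c(-1e-4, 1e-4, -1e-4, 1e-4, 5))
    run_transport(scn, src, config = cfg, n_histories = 2e3, seed = 41)
  }
  # harsher cutoff cannot decrease the deposited energy, and conservation
  # still closes exactly
  expect_gte(run_cut$deposited_keV, run$deposited_keV - 1e-9)
  expect_lt(run_cut$max_conservation_err_keV, 1e-9)
})

test_that("the interaction cap aborts runaway histories gracefully", {
  cfg <- transport_config(max_interactions = 1L)
  run <- slab_case("water", 10, 30, 2e3, seed = 51)
  scn <- mc_scene(box_region(1, "slab", -30, 30, -30, 30, 0, 10, "water"),
                  world_bounds = c(-31, 31, -31, 31, -1, 12),
                  world_material = "vacuum")
  src <- source_spec("collimated_pyramid", c(0, 0, 11), 30,
                     footprint = c(-1e-4, 1e-4, -1e-4, 1e-4, 10))
  run1 <- run_transport(scn, src, config = cfg, n_histories = 2e3, seed = 51)
  expect_gt(run1$n_aborted, 0)
  expect_lt(run1$max_conservation_err_keV, 1e-9)
})
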