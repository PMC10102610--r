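test_that("phantom construction is deterministic with the documented ids", {
  ids <- phantom_cell_ids()
  sc <- build_breast_phantom(phantom_spec())
  sc2 <- build_breast_phantom(phantom_spec())
  expect_identical(as.data.frame(sc), as.data.frame(sc2))
  # 2 breasts x (3 layers + 5 skin slabs) + body = 17 boxes, no screen
  expect_equal(nrow(sc), 17)
  expect_setequal(unique(sc$region_id[grepl("left_skin", sc$label)]),
                  c(9L, 10L, 11L))
  expect_setequal(unique(sc$region_id), c(1:7, 9:14))

  scr <- build_breast_phantom(phantom_spec(), screen_spec("c40"))
  expect_equal(nrow(scr), 18)
  expect_equal(scr$material[scr$region_id == ids$screen], "c40")
  # identical apart from the screen row and the body volume correction
  no_screen <- scr[scr$region_id != ids$screen, ]
  cols <- setdiff(names(sc), "volume_cm3")
  expect_identical(as.data.frame(no_screen[, cols]),
                   as.data.frame(sc[, cols]))
  # the screen displaces part of the body block
  expect_lt(scr$volume_cm3[scr$region_id == ids$body],
            sc$volume_cm3[sc$region_id == ids$body])
})

test_that("phantom rejects a screen that cannot fit the gap", {
  expect_error(build_breast_phantom(phantom_spec(gap = 1),
                                    screen_spec(thickness = 1.2)),
               "overlap")
})

test_that("scenario runs are deterministic and ordered sensibly", {
  a <- run_scenario(screens = c("none", "c40"), energies = c(25, 35),
                    n_histories = 3e4, seed = 5)
  b <- run_scenario(screens = c("none", "c40"), energies = c(25, 35),
                    n_histories = 3e4, seed = 5)
  expect_identical(glance(a), glance(b))
  expect_identical(tidy(a), tidy(b))

  s <- glance(a)
  # shielding: left-breast dose with the screen below the unshielded dose
  for (en in c(25, 35)) {
    expect_lt(s$left_total_eV[s$screen == "c40" & s$energy_keV == en],
              s$left_total_eV[s$screen == "none" & s$energy_keV == en])
  }
  # the screen leaves the exposed breast untouched within combined 3 sigma
  for (en in c(25, 35)) {
    d <- abs(s$right_total_eV[s$screen == "c40" & s$energy_keV == en] -
             s$right_total_eV[s$screen == "none" & s$energy_keV == en])
    se <- sqrt(s$right_se_eV[s$screen == "c40" & s$energy_keV == en]^2 +
               s$right_se_eV[s$screen == "none" & s$energy_keV == en]^2)
    expect_lt(d, 3 * se)
  }
  # scatter leakage into the unshielded contralateral breast grows with
  # energy (forward-peaked scattering and deeper penetration)
  none <- s[s$screen == "none", ]
  expect_true(all(diff(none$left_total_eV[order(none$energy_keV)]) > 0))
  # every layer of the unshielded left breast receives a measurable dose
  ids <- phantom_cell_ids()
  doses <- tidy(a)
  lay <- doses[doses$screen == "none" & doses$region_id %in% ids$left_layers, ]
  expect_true(all(lay$mean_eV > 0))
})

test_that("dose reduction percentages propagate their uncertainties", {
  expect_equal(dose_reduction(10, 10)$reduction_pct, 0)
  expect_equal(dose_reduction(10, 0)$reduction_pct, 100)
  expect_error(dose_reduction(0, 5), "positive")
  # invariant under common normalization of both inputs
  r1 <- dose_reduction(8, 5, 0.4, 0.3)
  r2 <- dose_reduction(8 / 2.5, 5 / 2.5, 0.4 / 2.5, 0.3 / 2.5)
  expect_equal(r1$reduction_pct, r2$reduction_pct)
  expect_equal(r1$se_pct, r2$se_pct)
  # first-order propagation formula
  expect_equal(r1$se_pct,
               100 * sqrt((0.3 / 8)^2 + (5 * 0.4 / 64)^2))
})

test_that("lead equivalence is self-consistent and linear", {
  expect_equal(lead_equivalence("lead", 1.2, 30), 12, tolerance = 1e-9)
  expect_equal(lead_equivalence("lead_acrylic", 0.6, 30),
               lead_equivalence("lead_acrylic", 1.2, 30) / 2,
               tolerance = 1e-9)
  # the calibrated screen: 12 mm of lead-acrylic ~ 0.5 mm of lead at 30 keV
  expect_equal(lead_equivalence("lead_acrylic", 1.2, 30), 0.5,
               tolerance = 0.1)
})

test_that("TF pilot shares primaries across materials and ranks screens", {
  tf <- tf_pilot(c("vacuum", "lead_acrylic", "c40"), energies = c(30, 40),
                 n_histories = 5e4, seed = 9)
  tb <- tidy(tf)
  for (en in c(30, 40)) {
    prim <- tb$primary[tb$energy_keV == en]
    expect_true(all(prim == prim[1]))   # identical seeds, identical primaries
  }
  expect_true(all(tb$tf[tb$material == "vacuum"] > 0.995))
  # the glass screen never transmits more than lead-acrylic
  for (en in c(30, 40)) {
    expect_lte(tb$tf[tb$material == "c40" & tb$energy_keV == en],
               tb$tf[tb$material == "lead_acrylic" & tb$energy_keV == en])
  }
})

test_that("reference-phantom validation degrades gracefully when unconfigured", {
  expect_error(tg195_validation(), "not configured")
  expect_error(tg195_validation(list(phantom_dim = c(10, 10, 5))), "missing")
  # the 80/20 adipose-to-glandular mixture carries 20% glandular by weight
  m <- tg195_breast_material(0.2)
  adipose <- c(H = 11.4, C = 59.8, N = 0.7, O = 27.8)
  glandular <- c(H = 10.6, C = 33.2, N = 3.0, O = 52.7)
  want <- normalize_composition(0.8 * adipose + 0.2 * glandular)
  expect_equal(m$composition$fraction, want$fraction, tolerance = 1e-9)
  # a configured run executes and is consistent when histories double
  cfg <- list(phantom_dim = c(10, 10, 5), source_distance = 60,
              energy_keV = 30, n_histories = 5e3, seed = 3)
  v1 <- tg195_validation(cfg)
  cfg$n_histories <- 1e4
  v2 <- tg195_validation(cfg)
  se <- sqrt((v1$mean_eV_per_photon * v1$rel_error)^2 +
             (v2$mean_eV_per_photon * v2$rel_error)^2)
  expect_lt(abs(v1$mean_eV_per_photon - v2$mean_eV_per_photon), 2 * se)
})

test_that("study configuration round-trips through YAML", {
  cfg <- default_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(source = list(energies_keV = c(25, 30),
                                      n_histories = 100, seed = 2)), path)
  got <- read_config(path)
  expect_equal(got$source$energies_keV, c(25, 30))
  expect_equal(got$phantom$gap, cfg$phantom$gap)    # defaults preserved
  lib <- library_from_config(default_config())
  expect_s3_class(lib$c40, "mc_material")
})
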