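test_that("relative error estimator handles degenerate and known cases", {
  # constant per-history scores: zero relative error
  n <- 100; d <- 3.2
  expect_equal(as.numeric(mc_relative_error(n * d, n * d^2, n)), 0)
  # zero mean: degenerate, reported as 1
  re0 <- mc_relative_error(0, 0, 50)
  expect_equal(as.numeric(re0), 1)
  expect_true(attr(re0, "degenerate"))
  # Bernoulli scoring at p = 0.5: closed form sqrt((1-p)/(np))
  set.seed(2)
  x <- rbinom(1e4, 1, 0.5)
  re <- as.numeric(mc_relative_error(sum(x), sum(x^2), 1e4))
  expect_equal(re, sqrt(0.5 / (1e4 * 0.5)), tolerance = 0.2)
  expect_error(mc_relative_error(1, 1, 1), "at least 2")
})

test_that("relative error shrinks like one over root n", {
  res <- sapply(c(1, 4, 16), function(f) {
    run <- slab_case("water", 1, 30, 4000 * f, seed = 61,
                     primaries_only = FALSE)
    tally_report(run)$rel_error[1]
  })
  expect_equal(res[1] / res[2], 2, tolerance = 0.35)
  expect_equal(res[2] / res[3], 2, tolerance = 0.35)
})

test_that("transmission factor behaves at its limits", {
  expect_equal(transmission_factor(1000, 0)$tf, 0)
  expect_equal(transmission_factor(500, 500)$tf, 1)
  expect_error(transmission_factor(0, 10), "primary")
  # vacuum absorber: TF = 1 within MC error
  tfv <- tf_pilot("vacuum", energies = 30, n_histories = 2e4, seed = 2)
  expect_gt(tfv$tf, 0.995)
})

test_that("narrow-beam TF matches the analytic attenuation oracle", {
  for (en in c(20, 40)) {
    mu <- linear_mu("pmma", en)
    t <- 1 / mu
    res <- slab_primary_fraction("pmma", t, en, 5e4, seed = 70 + en)
    expect_lt(abs(res$p - exp(-1)), 3 * res$se)
  }
})

test_that("TF decreases with thickness and with attenuation", {
  en <- 30
  tfs <- sapply(c(0.5, 1, 2), function(t) {
    slab_primary_fraction("water", t, en, 3e4, seed = 81)$p
  })
  expect_true(all(diff(tfs) < 0))
  # at fixed thickness, a denser absorber transmits less
  weak <- slab_primary_fraction("water", 1, en, 3e4, seed = 82)$p
  strong <- slab_primary_fraction("skin", 1, en, 3e4, seed = 82)$p
  expect_lt(strong, weak)
})

test_that("skin-dose aggregation sums cells with quadrature errors", {
  rep <- tibble::tibble(region_id = c(9L, 10L, 11L),
                        mean_eV = c(1, 1, 1), rel_error = c(0.1, 0.1, 0.1))
  got <- total_skin_dose(rep, c(9, 10, 11))
  expect_equal(got$mean_eV, 3)
  expect_equal(got$se_eV, sqrt(3 * 0.1^2))
  # order does not matter, empty list sums to zero, missing ids error
  expect_equal(total_skin_dose(rep, c(11, 9, 10))$mean_eV, 3)
  expect_equal(total_skin_dose(rep, integer())$mean_eV, 0)
  expect_error(total_skin_dose(rep, c(9, 99)), "missing")
})

test_that("global energy bookkeeping closes over all regions", {
  run <- slab_case("skin", 1, 35, 1e4, seed = 91, primaries_only = FALSE)
  expect_equal(sum(run$cells$dep_sum_keV) + run$escaped_keV,
               run$emitted_keV, tolerance = 1e-12)
  rep <- tally_report(run)
  expect_true(all(rep$rel_error >= 0 & rep$rel_error <= 1))
  expect_equal(rep$mean_eV_per_g[rep$region_id == 1],
               rep$mean_eV[rep$region_id == 1] /
                 (rep$volume_cm3[rep$region_id == 1] * 1.090),
               tolerance = 1e-12)
})
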