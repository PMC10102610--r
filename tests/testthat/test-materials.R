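test_that("composition normalization preserves printed ratios", {
  # skin row: printed weight percentages sum to 99.3
  skin <- normalize_composition(c(H = 9.8, C = 17.8, N = 5, O = 66.7))
  expect_equal(sum(skin$fraction), 1, tolerance = 1e-12)
  expect_equal(skin$fraction[skin$symbol == "H"], 9.8 / 99.3,
               tolerance = 1e-12)
  # ratios preserved
  expect_equal(skin$fraction[skin$symbol == "C"] /
                 skin$fraction[skin$symbol == "O"], 17.8 / 66.7,
               tolerance = 1e-12)

  expect_equal(normalize_composition(c(H = 50))$fraction, 1)

  gf25 <- normalize_composition(c(H = 11, C = 51, N = 2.1, O = 35.7))
  expect_equal(sum(gf25$fraction), 1, tolerance = 1e-12)

  expect_error(normalize_composition(c(H = -1, O = 2)), "positive")
  expect_error(normalize_composition(data.frame()), "non-empty")
})

test_that("material constructor validates inputs", {
  expect_error(material("x", -1, c(H = 1)), "density")
  expect_error(material("x", 1, c(Xx = 1)), "not in the embedded table")
  m <- material("w", 1, c(H = 11.19, O = 88.81))
  expect_s3_class(m, "mc_material")
  expect_equal(sum(m$composition$fraction), 1, tolerance = 1e-12)
})

test_that("default library contains the study materials", {
  lib <- material_library()
  expect_true(all(c("gf25", "gf50", "gf75", "skin", "soft_tissue",
                    "lead_acrylic", "c40", "vacuum", "air") %in% names(lib)))
  expect_equal(lib$skin$density, 1.090)
  expect_equal(lib$gf25$density, 0.955)
  # overrides replace entries
  lib2 <- library_with(lib, c40 = material("c40", 6.0, c(Te = 100)))
  expect_equal(lib2$c40$density, 6.0)
})

test_that("mixture rule is linear and matches direct element evaluation", {
  # pure single-element material at a grid energy equals the tabulated total
  et <- element_table()
  eg <- et$energy_keV[et$element == "O"][40]
  pure_o <- material("pure_o", 1, c(O = 100))
  expect_equal(mu_rho(pure_o, eg), et$total[et$element == "O"][40],
               tolerance = 1e-9)

  # 50/50 two-element blend is the average of the pure values
  mix <- material("mix", 1, c(H = 50, O = 50))
  expect_equal(mu_rho(mix, 30),
               0.5 * element_xs("H", 30) + 0.5 * element_xs("O", 30),
               tolerance = 1e-12)

  # water from its elemental fractions, direct spreadsheet-style evaluation
  expect_equal(mu_rho("water", 30),
               0.1119 * element_xs("H", 30) + 0.8881 * element_xs("O", 30),
               tolerance = 1e-6)

  # per-mass blend of two materials: mu_rho is linear in the mixing weight
  w <- 0.3
  water_f <- c(H = 0.1119, O = 0.8881)
  pmma_f <- c(H = 0.0805, C = 0.5998, O = 0.3196)
  blend_f <- w * water_f[c("H", "O")] +
    (1 - w) * c(H = pmma_f[["H"]], O = pmma_f[["O"]])
  blend_f["C"] <- (1 - w) * pmma_f[["C"]]
  blend <- material("blend", 1, 100 * blend_f / sum(blend_f))
  expect_equal(mu_rho(blend, 25),
               w * mu_rho("water", 25) + (1 - w) * mu_rho("pmma", 25),
               tolerance = 1e-3)
})

test_that("tissue attenuation decreases monotonically over 10-50 keV", {
  en <- seq(10, 50, by = 2)
  for (m in c("gf25", "gf50", "gf75", "skin")) {
    v <- mu_rho(m, en)
    expect_true(all(v > 0))
    expect_true(all(diff(v) < 0), label = paste(m, "monotone decreasing"))
  }
})

test_that("linear_mu scales with density", {
  e <- c(20, 30, 40)
  m1 <- material("a", 1.0, c(O = 100))
  m2 <- material("b", 2.0, c(O = 100))
  expect_equal(linear_mu(m1, e), mu_rho(m1, e))
  expect_equal(linear_mu(m2, e), 2 * linear_mu(m1, e))
  expect_equal(linear_mu("skin", e), 1.090 * mu_rho("skin", e))
})

test_that("energies outside the embedded grid are refused", {
  expect_error(element_xs("O", 0.5), "outside")
  expect_error(mu_rho("water", 1e4), "outside")
})

test_that("vacuum streams: zero attenuation at any energy", {
  expect_equal(mu_rho("vacuum", c(10, 50)), c(0, 0))
  expect_equal(linear_mu("vacuum", 30), 0)
})
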