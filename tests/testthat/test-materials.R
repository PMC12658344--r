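test_that("formula parsing gives standard stoichiometric mass fractions", {
  bi2o3 <- parse_formula("Bi2O3")
  expect_equal(bi2o3$fraction[bi2o3$element == "Bi"], 0.8970, tolerance = 1e-3)
  expect_equal(sum(bi2o3$fraction), 1, tolerance = 1e-9)
  pvc <- parse_formula("PVC")
  expect_equal(pvc$fraction[pvc$element == "Cl"], 0.567, tolerance = 1e-3)
  w <- parse_formula("W")
  expect_equal(w$fraction, 1)
  expect_error(parse_formula("Xx2O3"), class = "leadequiv_formula_error")
  expect_error(parse_formula("W0"), class = "leadequiv_formula_error")
})

test_that("registry reproduces all 18 compositions and densities exactly", {
  reg <- load_registry()
  expect_identical(nrow(reg), 18L)
  for (i in seq_len(nrow(reg))) {
    comp <- reg$composite[[i]]
    expect_equal(sum(comp$components), 100, tolerance = 1e-9)
    expect_identical(unname(comp$components["PVC"]), 22)  # polymer share
    filler <- comp$components[names(comp$components) != "PVC"]
    expect_equal(sum(filler), 78, tolerance = 1e-9)
  }
  pbpvc <- registry_composite("Pb-PVC")
  expect_identical(pbpvc$density, 3.46)
  expect_identical(unname(pbpvc$components["Pb"]), 78)
  biba <- registry_composite("Bi-Ba")
  expect_identical(biba$density, 2.886)
  expect_equal(sort(names(biba$components)), c("BaSO4", "Bi2O3", "PVC"))
  expect_identical(unname(biba$components[c("BaSO4", "Bi2O3")]), c(39, 39))
  wsngd <- registry_composite("W-Sn-Gd")
  expect_identical(wsngd$density, 3.288)
  expect_identical(unname(wsngd$components[c("W", "Sn", "Gd2O3")]), c(26, 26, 26))
  expect_error(registry_composite("unobtainium"),
               class = "leadequiv_unknown_material")
})

test_that("elemental fractions conserve mass and expand the mixture", {
  reg <- load_registry()
  for (i in seq_len(nrow(reg))) {
    fr <- elemental_fractions(reg$composite[[i]])
    expect_equal(sum(fr$fraction), 1, tolerance = 1e-9)
  }
  bigd <- elemental_fractions(registry_composite("Bi-Gd"))
  expect_equal(bigd$fraction[bigd$element == "Bi"], 0.39 * 0.8970,
               tolerance = 1e-3)
  pbpvc <- elemental_fractions(registry_composite("Pb-PVC"))
  expect_equal(pbpvc$fraction[pbpvc$element == "Pb"], 0.78, tolerance = 1e-12)
})

test_that("mixture rule is linear and reduces to the element for pure slabs", {
  e <- c(20, 45, 60, 88.005, 100, 140)
  pure <- composite("pure-Pb", c(Pb = 100), density = 11.35)
  expect_equal(composite_mu_rho(pure, e), mu_rho("Pb", e), tolerance = 1e-12)
  # 50:50 blend of two registry composites averages their coefficients
  a <- registry_composite("W-Sn-Gd"); b <- registry_composite("Bi-Ba")
  blend <- composite("blend", c(a$components / 2, b$components / 2),
                     density = 3)
  expect_equal(composite_mu_rho(blend, e),
               (composite_mu_rho(a, e) + composite_mu_rho(b, e)) / 2,
               tolerance = 1e-9)
  # two-term mixture identity for Pb-PVC
  pbpvc <- registry_composite("Pb-PVC")
  pvc <- composite("pvc", c(PVC = 100), density = 1.4)
  expect_equal(composite_mu_rho(pbpvc, e),
               0.78 * mu_rho("Pb", e) + 0.22 * composite_mu_rho(pvc, e),
               tolerance = 1e-9)
})

test_that("shrinking a component's weight moves the mixture continuously", {
  base <- composite("w-pvc", c(W = 78, PVC = 22), density = 3.4)
  eps <- composite("w-sn-pvc", c(W = 78 - 1e-6, Sn = 1e-6, PVC = 22),
                   density = 3.4)
  expect_lt(abs(composite_mu_rho(eps, 60) - composite_mu_rho(base, 60)), 1e-6)
})

test_that("K edges of constituents appear in the composite coefficient", {
  pbpvc <- registry_composite("Pb-PVC")
  expect_gt(composite_mu_rho(pbpvc, 88.005) / composite_mu_rho(pbpvc, 88.004), 2)
  wgd <- registry_composite("W-Gd")
  expect_gt(composite_mu_rho(wgd, 50.239) / composite_mu_rho(wgd, 50.238), 1.5)
})

test_that("linear attenuation is density times the mass coefficient", {
  m <- registry_composite("W-Sn")
  expect_equal(linear_mu(m, 50), 3.406 * composite_mu_rho(m, 50),
               tolerance = 1e-12)
})

test_that("registry export mirrors the composition table", {
  tab <- registry_table()
  expect_identical(nrow(tab), 18L)
  expect_true(all(c("W", "Sn", "Bi2O3", "PVC", "density_g_cm3") %in% names(tab)))
  w <- tab[tab$abbreviation == "W-Sn-Gd", ]
  expect_identical(c(w$W, w$Sn, w$Gd2O3, w$PVC), c(26, 26, 26, 22))
})
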