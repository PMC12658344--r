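test_that("element tables load with correct metadata and grid structure", {
  for (sym in supported_elements()) {
    tab <- load_element_table(sym)
    e <- tab$energy_keV
    expect_gte(min(e), 1)
    expect_lte(max(e), 150)
    d <- diff(e)
    expect_true(all(d >= 0))                     # ascending, duplicates allowed
    expect_lte(max(d), 1 + 1e-9)                 # grid spacing at most 1 keV
    expect_true(all(tab$photoelectric > 0))
    expect_true(all(tab$incoherent > 0))
    expect_true(all(tab$coherent > 0))
  }
  expect_identical(attr(load_element_table("W"), "Z"), 74)
  expect_equal(attr(load_element_table("Pb"), "k_edge"), 88.005)
  expect_equal(attr(load_element_table("Gd"), "k_edge"), 50.239, tolerance = 1e-6)
  expect_error(load_element_table("Xx"), class = "leadequiv_unsupported_element")
})

test_that("total equals the sum of components within 1% everywhere", {
  set.seed(7)
  for (sym in supported_elements()) {
    tab <- load_element_table(sym)
    expect_lt(max(abs(tab$total /
                        (tab$photoelectric + tab$incoherent + tab$coherent) - 1)),
              0.01)
    e <- runif(1000, 1, 150)
    tot <- mu_rho(tab, e, "total")
    parts <- mu_rho(tab, e, "photoelectric") + mu_rho(tab, e, "incoherent") +
      mu_rho(tab, e, "coherent")
    expect_lt(max(abs(tot / parts - 1)), 0.01)
  }
})

test_that("total coefficient decreases with energy between edges", {
  for (sym in supported_elements()) {
    tab <- load_element_table(sym)
    at_edge <- duplicated(tab$energy_keV)       # above-edge rows
    rising <- which(diff(tab$total) > 0)
    expect_true(all(at_edge[rising + 1L]),
                info = sprintf("%s: non-edge rise in total", sym))
  }
})

test_that("photoelectric coefficient jumps upward across the K edge", {
  for (sym in c("Sn", "Sb", "Ba", "Gd", "W", "Pb", "Bi")) {
    tab <- load_element_table(sym)
    ek <- attr(tab, "k_edge")
    below <- mu_rho(tab, ek - 1e-6, "photoelectric")
    above <- mu_rho(tab, ek, "photoelectric")   # exact edge -> above-edge value
    expect_gt(above, below)
    expect_gt(above / below, 3)                 # K jump is a large discontinuity
  }
})

test_that("interpolation reproduces grid points and handles edges and bounds", {
  tab <- load_element_table("Pb")
  # non-edge grid points are reproduced exactly
  mid <- !(tab$energy_keV %in% tab$energy_keV[duplicated(tab$energy_keV)])
  idx <- which(mid)[c(5, 50, 120)]
  expect_equal(mu_rho(tab, tab$energy_keV[idx]), tab$total[idx], tolerance = 1e-12)
  # at the exact K-edge energy the above-edge value is returned
  ek <- attr(tab, "k_edge")
  i_above <- max(which(tab$energy_keV == ek))
  expect_equal(mu_rho(tab, ek), tab$total[i_above], tolerance = 1e-12)
  expect_error(mu_rho(tab, 0.5), class = "leadequiv_energy_range")
  expect_error(mu_rho(tab, 151), class = "leadequiv_energy_range")
  # interpolation is log-log between neighbouring grid points
  expect_equal(mu_rho(tab, 100), 5.549, tolerance = 2e-2)
})

test_that("repeated loads return the identical cached table", {
  a <- load_element_table("Gd")
  b <- load_element_table("Gd")
  expect_identical(a, b)
})

test_that("air energy-absorption table loads and interpolates", {
  tab <- load_air_table()
  expect_true(all(tab$muen_over_rho > 0))
  i <- 12
  expect_equal(air_muen_rho(tab$energy_keV[i]), tab$muen_over_rho[i], tolerance = 1e-12)
  expect_error(air_muen_rho(200), class = "leadequiv_energy_range")
  # diagnostic-range air kerma factors decrease to the Compton plateau
  expect_gt(air_muen_rho(10), air_muen_rho(60))
})
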