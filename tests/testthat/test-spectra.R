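test_that("generated spectra respect the tube potential cutoff", {
  s80 <- generate_spectrum(tube_config(80))
  expect_true(all(s80$fluence[s80$energy_keV > 80] == 0))
  expect_true(any(s80$fluence > 0))
  expect_true(all(s80$fluence >= 0))
})

test_that("tungsten K lines appear only above the W K edge", {
  s120 <- generate_spectrum(tube_config(120))
  near_ka <- abs(s120$energy_keV - 59.3) < 0.5
  cont <- s120$energy_keV > 54 & s120$energy_keV < 56
  expect_gt(max(s120$fluence[near_ka]), 2 * max(s120$fluence[cont]))
  s60 <- generate_spectrum(tube_config(60))
  # below the K edge the continuum is smooth: no bin towers over neighbours
  expect_lt(max(s60$fluence / stats::filter(s60$fluence, c(.5, 0, .5)),
                na.rm = TRUE), 1.5)
})

test_that("mean energy hardens with filtration and rises with potential", {
  me <- function(kvp, filt) {
    spectrum_mean_energy(generate_spectrum(tube_config(kvp, filtration_mm_al = filt)))
  }
  expect_gt(me(80, 4), me(80, 2.5))
  expect_gt(me(80, 2.5), me(80, 1))
  expect_gt(me(120, 2.5), me(100, 2.5))
  expect_gt(me(100, 2.5), me(80, 2.5))
})

test_that("invalid tube configurations are rejected", {
  expect_error(tube_config(30), class = "leadequiv_config_error")
  expect_error(tube_config(100, anode_angle_deg = 0),
               class = "leadequiv_config_error")
  expect_error(tube_config(100, bin_width_keV = -1),
               class = "leadequiv_config_error")
})

test_that("spectrum CSV round-trips within float formatting", {
  s <- generate_spectrum(tube_config(100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  s2 <- read_spectrum(path)
  expect_equal(s2$energy_keV, s$energy_keV, tolerance = 1e-9)
  expect_equal(s2$fluence, s$fluence, tolerance = 1e-9)
  expect_equal(attr(s2, "kvp"), attr(s, "kvp"), tolerance = 0.01)
})

test_that("malformed spectrum files are rejected", {
  bad1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("energy_keV,fluence", "10,1", "20,-0.5"), bad1)
  expect_error(read_spectrum(bad1), class = "leadequiv_format_error")
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("energy_keV,fluence", "20,1", "10,2"), bad2)
  expect_error(read_spectrum(bad2), class = "leadequiv_format_error")
  bad3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "10,1"), bad3)
  expect_error(read_spectrum(bad3), class = "leadequiv_format_error")
})

test_that("vendored reference spectra load and respect their potential", {
  for (kvp in c(80, 100, 120)) {
    s <- reference_spectrum(kvp)
    expect_lte(max(s$energy_keV[s$fluence > 0]), kvp)
    expect_true(any(s$fluence > 0))
  }
  expect_error(reference_spectrum(90), class = "leadequiv_config_error")
})

test_that("similarity metrics are zero for identical spectra", {
  s <- reference_spectrum(100)
  r <- spectrum_similarity(s, s)
  expect_identical(r$peak_offset_keV, 0)
  expect_lt(r$nrmse, 1e-12)
  expect_lt(r$mean_energy_diff_keV, 1e-12)
})

test_that("generated spectra agree with the vendored references", {
  # regression bound frozen at the first computation of these metrics
  for (kvp in c(80, 100, 120)) {
    r <- spectrum_similarity(generate_spectrum(tube_config(kvp)),
                             reference_spectrum(kvp))
    expect_lt(r$nrmse, 1e-3)
    expect_lte(r$peak_offset_keV, 0.5)   # within one bin
    expect_lt(r$mean_energy_diff_keV, 0.5)
  }
})

test_that("disjoint energy supports raise an error", {
  a <- make_monoenergetic(20)
  b <- make_monoenergetic(100)
  expect_error(spectrum_similarity(a, b), class = "leadequiv_format_error")
})

test_that("strict spectrum validation flags mismatched potentials", {
  rep <- validate_spectrum_report(80, 120)
  expect_gt(rep$mean_energy_diff_keV, 5)
  expect_error(validate_spectrum_report(80, 120, strict = TRUE,
                                        nrmse_bound = 1e-4),
               class = "leadequiv_validation_error")
})
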