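test_that("lead reference transmission has closed monoenergetic form", {
  mono <- make_monoenergetic(100)
  ref <- pb_reference_transmission(mono, 0.5)
  expect_equal(as.numeric(ref), exp(-mu_rho("Pb", 100) * 11.35 * 0.05),
               tolerance = 1e-12)
  expect_identical(as.numeric(pb_reference_transmission(mono, 0)), 1)
  # thicker lead always transmits less
  for (kvp in c(80, 100, 120)) {
    s <- reference_spectrum(kvp)
    expect_lt(as.numeric(pb_reference_transmission(s, 0.5)),
              as.numeric(pb_reference_transmission(s, 0.35)))
  }
})

test_that("engine mismatch between curve and reference is a hard error", {
  s <- tri_line_spectrum()
  curve <- build_curve(s, registry_composite("W-Sn"))
  fit <- fit_curve(curve)
  ref <- pb_reference_transmission(s, 0.35, engine = "mc",
                                   mc = mc_config(n_histories = 2e4, seed = 1))
  expect_error(solve_t_eq(fit, ref), class = "leadequiv_engine_mismatch")
})

test_that("single-exponential fitting recovers an exact exponential", {
  t <- c(0.1, 0.2, 0.5, 1, 1.5, 2, 2.5, 3)
  curve <- tibble::tibble(thickness_mm = t, transmission = exp(-2.5 * t),
                          stderr = 0)
  class(curve) <- c("transmission_curve", class(curve))
  fit <- fit_curve(curve, kind = "exp1")
  expect_equal(tidy(fit)$estimate[tidy(fit)$term == "rate"], 2.5,
               tolerance = 1e-6)
  expect_equal(tidy(fit)$estimate[tidy(fit)$term == "A"], 1, tolerance = 1e-6)
})

test_that("bi-exponential fitting recovers noisy synthetic parameters", {
  curve <- make_noisy_curve(c(0.7, 0.3), c(8, 1.5), sigma = 0.005, seed = 1)
  fit <- fit_curve(curve, kind = "exp2")
  est <- tidy(fit)$estimate
  expect_equal(est, c(0.7, 8, 0.3, 1.5), tolerance = 0.05)
  expect_true(glance(fit)$within_3se)
})

test_that("the default interpolant passes exactly through the knots", {
  s <- reference_spectrum(100)
  curve <- build_curve(s, registry_composite("Bi-Sb"))
  fit <- fit_curve(curve)
  expect_equal(predict(fit, curve$thickness_mm), curve$transmission,
               tolerance = 1e-9)
})

test_that("non-monotone curves beyond the noise tolerance are rejected", {
  curve <- tibble::tibble(thickness_mm = c(0.5, 1, 2),
                          transmission = c(0.5, 0.7, 0.3), stderr = 0)
  class(curve) <- c("transmission_curve", class(curve))
  expect_error(fit_curve(curve), class = "leadequiv_fit_error")
})

test_that("root finding inverts the fitted curve and refuses extrapolation", {
  s <- reference_spectrum(120)
  curve <- build_curve(s, registry_composite("W-Gd-Sb"))
  fit <- fit_curve(curve)
  target <- predict(fit, 1.5)
  expect_equal(solve_t_eq(fit, target), 1.5, tolerance = 1e-6)
  expect_error(solve_t_eq(fit, predict(fit, 0.05)),
               class = "leadequiv_bracket_error")
  expect_error(solve_t_eq(fit, predict(fit, 3.5)),
               class = "leadequiv_bracket_error")
})

test_that("monoenergetic pipeline equals the closed-form thickness ratio", {
  mono <- make_monoenergetic(100)
  m <- registry_composite("Pb-PVC")
  res <- lead_equivalence(mono, m, 0.5)
  t_exact <- analytic_t_eq(linear_mu(m, 100), mu_rho("Pb", 100) * 11.35, 0.5)
  expect_equal(res$t_eq_mm, t_exact, tolerance = 1e-6)
  expect_equal(res$t_eq_mm, 2.08, tolerance = 0.01)
})

test_that("areal mass is density times equivalent thickness", {
  expect_identical(areal_mass(3.46, 0), 0)
  expect_equal(areal_mass(3.46, 2.07), 7.16, tolerance = 1e-2)
  expect_equal(areal_mass(registry_composite("W-Sn-Gd"), 1.62), 5.33,
               tolerance = 1e-2)
})

test_that("equivalent thickness is insensitive to refining the grid", {
  s <- reference_spectrum(100)
  m <- registry_composite("Bi-Sn-Gd")
  g1 <- c(0.1, 0.2, 0.5, 1, 1.5, 2, 2.5, 3)
  g2 <- sort(unique(c(g1, g1[-length(g1)] + diff(g1) / 2)))
  t1 <- lead_equivalence(s, m, 0.5, thicknesses = g1)$t_eq_mm
  t2 <- lead_equivalence(s, m, 0.5, thicknesses = g2)$t_eq_mm
  expect_lt(abs(t1 / t2 - 1), 0.01)
})

test_that("raising the filler loading lowers the equivalent thickness", {
  s <- reference_spectrum(100)
  lo <- composite("w78", c(W = 78, PVC = 22), density = 3.4)
  hi <- composite("w90", c(W = 90, PVC = 10), density = 3.4)
  expect_lt(lead_equivalence(s, hi, 0.5)$t_eq_mm,
            lead_equivalence(s, lo, 0.5)$t_eq_mm)
})

test_that("fitted-curve and point-interpolation intersections agree", {
  # the two intersection routes: fitted interpolant vs linear log-points
  s <- reference_spectrum(80)
  m <- registry_composite("W-Sb")
  curve <- build_curve(s, m)
  ref <- pb_reference_transmission(s, 0.5)
  t_fit <- solve_t_eq(fit_curve(curve), ref)
  lin <- stats::approxfun(log(curve$transmission), curve$thickness_mm)
  t_lin <- lin(log(as.numeric(ref)))
  expect_lt(abs(t_fit - t_lin), 0.02)
})
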