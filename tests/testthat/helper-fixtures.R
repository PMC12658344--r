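# Shared fixtures built in code.

# deterministic set of toy materials with constant mass attenuation
random_toy_materials <- function(n, seed = 101) {
  set.seed(seed)
  purrr::map(seq_len(n), function(i) {
    toy_material(sprintf("toy%02d", i),
                 mu_rho = runif(1, 0.2, 30),
                 density = runif(1, 1, 8))
  })
}

# a small polyenergetic test spectrum (three lines), cheap to transport
tri_line_spectrum <- function() {
  s <- tibble::tibble(energy_keV = c(40, 60, 90), fluence = c(0.3, 0.5, 0.2))
  attr(s, "kvp") <- 90
  class(s) <- c("xray_spectrum", class(s))
  s
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
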