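# Synthetic inputs with analytically known answers: monoenergetic beams,
# toy materials with prescribed coefficients, noisy pseudo-simulation
# transmission curves, and the closed-form lead-equivalence oracle.

#' Monoenergetic spectrum
#'
#' A single positive fluence bin; under it every material attenuates as a
#' pure exponential and the lead-equivalent thickness has the closed form
#' [analytic_t_eq()].
#'
#' @param energy Photon energy in keV, 1-150.
#' @return A spectrum tibble with one bin.
#' @export
make_monoenergetic <- function(energy) {
  .check_energy_range(energy)
  stopifnot(length(energy) == 1)
  .new_spectrum(energy, 1, kvp = energy)
}

#' Toy material with prescribed attenuation
#'
#' A fictitious material whose mass attenuation coefficient is a constant, a
#' function of energy, or a small lookup table; it behaves like a
#' [composite()] for every downstream operation (transmission, curves,
#' equivalence).
#'
#' @param name Label.
#' @param mu_rho Constant (cm^2/g), function of energy, or data frame with
#'   columns `energy_keV`, `mu_rho`.
#' @param density Density in g/cm^3.
#' @return Object of class `toy_material`.
#' @examples
#' toy_material("gray-stuff", mu_rho = 0.8, density = 2)
#' @export
toy_material <- function(name, mu_rho, density) {
  stopifnot(is.numeric(density), density > 0)
  f <- if (is.function(mu_rho)) {
    mu_rho
  } else if (is.data.frame(mu_rho)) {
    stopifnot(all(c("energy_keV", "mu_rho") %in% names(mu_rho)),
              all(mu_rho$mu_rho > 0))
    local({
      tab <- mu_rho
      function(e) .loglog_lookup(tab$energy_keV, tab$mu_rho, e)
    })
  } else {
    stopifnot(length(mu_rho) == 1, mu_rho > 0)
    local({
      v <- mu_rho
      function(e) rep(v, length(e))
    })
  }
  structure(list(name = name, abbreviation = name, mu_fun = f,
                 density = density),
            class = "toy_material")
}

#' @export
material_mu_rho.toy_material <- function(material, energy, component = "total") {
  .check_energy_range(energy)
  v <- material$mu_fun(energy)
  if (any(v <= 0)) abort("toy material coefficient must be positive")
  if (component %in% c("incoherent", "coherent")) return(0 * v)
  v  # "photoelectric" and "total": all interaction lumped as absorption
}

#' @export
print.toy_material <- function(x, ...) {
  cat(sprintf("<toy_material> %s, density %.3f g/cm^3\n", x$name, x$density))
  invisible(x)
}

#' Noisy pseudo-simulation transmission curve
#'
#' Generates an 8-point-style transmission curve from a known
#' multi-exponential model \eqn{T(t) = \sum_i a_i e^{-r_i t}} with
#' multiplicative lognormal noise (median 1, log-sd `sigma`), emulating the
#' per-point statistical uncertainty of a Monte Carlo run.  Seed-
#' deterministic.
#'
#' @param amplitudes Component amplitudes, summing to 1.
#' @param rates Decay rates (1/mm), positive, same length as `amplitudes`.
#' @param thicknesses Thickness grid in mm (default the 8-point study grid).
#' @param sigma Relative noise level (default 0.01, mirroring a sub-1%
#'   simulation uncertainty target); 0 gives exact model values.
#' @param seed RNG seed.
#' @return A `transmission_curve` with attribute `model` holding the exact
#'   model function and parameters.
#' @export
make_noisy_curve <- function(amplitudes, rates,
                             thicknesses = .DEFAULT_THICKNESS_GRID,
                             sigma = 0.01, seed = 1) {
  stopifnot(length(amplitudes) == length(rates), all(rates > 0), sigma >= 0,
            abs(sum(amplitudes) - 1) < 1e-9)
  model <- function(t) {
    vapply(t, function(tt) sum(amplitudes * exp(-rates * tt)), numeric(1))
  }
  tr <- model(thicknesses)
  if (sigma > 0) {
    set.seed(seed)
    tr <- tr * exp(sigma * rnorm(length(thicknesses)))
  }
  curve <- tibble(thickness_mm = thicknesses, transmission = tr,
                  stderr = rep(sigma, length(thicknesses)))
  attr(curve, "engine") <- "synthetic"
  attr(curve, "model") <- list(fun = model, amplitudes = amplitudes,
                               rates = rates)
  attr(curve, "seed") <- seed
  class(curve) <- c("transmission_curve", class(curve))
  curve
}

#' Closed-form lead-equivalent thickness (monoenergetic limit)
#'
#' For a single photon energy, Beer-Lambert algebra gives
#' \eqn{t_{eq} = \mu_{Pb} t_{Pb} / \mu_{mat}} with linear attenuation
#' coefficients in 1/cm and thicknesses in mm.
#'
#' @param material_mu Linear attenuation coefficient of the material (1/cm).
#' @param pb_mu Linear attenuation coefficient of lead (1/cm).
#' @param pb_thickness_mm Lead reference thickness in mm.
#' @return Equivalent thickness in mm.
#' @export
analytic_t_eq <- function(material_mu, pb_mu, pb_thickness_mm) {
  if (any(material_mu <= 0) || any(pb_mu <= 0)) {
    abort("linear attenuation coefficients must be positive",
          class = "leadequiv_config_error")
  }
  pb_mu * pb_thickness_mm / material_mu
}

#' Write synthetic fixtures in the pipeline CSV dialects
#'
#' Convenience writer emitting a synthetic spectrum and/or curve with the
#' same formats the real pipeline reads and writes.
#'
#' @param dir Output directory.
#' @param spectrum Optional spectrum tibble.
#' @param curve Optional `transmission_curve`.
#' @return Invisibly, the written paths.
#' @export
write_synthetic_fixtures <- function(dir, spectrum = NULL, curve = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(spectrum)) {
    p <- file.path(dir, "synthetic_spectrum.csv")
    write_spectrum(spectrum, p); paths <- c(paths, p)
  }
  if (!is.null(curve)) {
    p <- file.path(dir, "synthetic_curve.csv")
    write_curve(curve, p); paths <- c(paths, p)
  }
  invisible(paths)
}
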