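# Diagnostic tungsten-anode x-ray spectra: an analytic generator
# (Kramers-form continuum with target self-filtration, added aluminium
# filtration and W K characteristic lines), CSV round-trip, and similarity
# metrics against the vendored reference spectra.

.W_K_EDGE <- 69.525
# tungsten K lines: energy (keV) and relative intensity
.W_K_LINES <- tibble::tribble(
  ~energy, ~intensity,
  59.32, 100,   # K-alpha-1
  57.98, 57.6,  # K-alpha-2
  67.24, 33,    # K-beta-1 (+3)
  69.07, 8.7    # K-beta-2
)
.AL_DENSITY <- 2.699   # g/cm^3
.W_DENSITY <- 19.3

#' Tube configuration for the spectrum generator
#'
#' Defaults are typical diagnostic tube values: 12 degree anode angle,
#' 2.5 mm Al total filtration, 0.5 keV bins.
#'
#' @param kvp Tube potential in kV, 40-150.
#' @param anode_angle_deg Anode angle in degrees.
#' @param filtration_mm_al Total aluminium-equivalent filtration in mm.
#' @param bin_width_keV Energy bin width in keV.
#' @return An object of class `tube_config`.
#' @export
tube_config <- function(kvp, anode_angle_deg = 12, filtration_mm_al = 2.5,
                        bin_width_keV = 0.5) {
  if (!is.numeric(kvp) || length(kvp) != 1 || kvp < 40 || kvp > 150) {
    abort("kvp must be a scalar in [40, 150]", class = "leadequiv_config_error")
  }
  if (anode_angle_deg <= 0 || filtration_mm_al < 0 || bin_width_keV <= 0) {
    abort("invalid tube configuration", class = "leadequiv_config_error")
  }
  structure(list(kvp = kvp, anode_angle_deg = anode_angle_deg,
                 filtration_mm_al = filtration_mm_al,
                 bin_width_keV = bin_width_keV),
            class = "tube_config")
}

.new_spectrum <- function(energy, fluence, kvp) {
  s <- tibble(energy_keV = energy, fluence = fluence)
  attr(s, "kvp") <- kvp
  class(s) <- c("xray_spectrum", class(s))
  s
}

#' Generate an analytic tube spectrum
#'
#' Bremsstrahlung continuum of Kramers form \eqn{(E_0-E)/E}, attenuated by
#' tungsten target self-filtration (mean exit path shrinking linearly with
#' photon energy) and the configured aluminium filtration, plus tungsten K
#' characteristic lines when the tube potential exceeds the W K edge
#' (69.5 keV).  The K-line yield grows as \eqn{(E_0/E_K - 1)^{1.67}}.
#' Deterministic for a fixed configuration; the absolute scale is arbitrary
#' (all consumers are normalisation-invariant).
#'
#' @param config A [tube_config()].
#' @return A spectrum tibble (`energy_keV`, `fluence`) with attribute `kvp`.
#' @examples
#' s <- generate_spectrum(tube_config(100))
#' spectrum_mean_energy(s)
#' @export
generate_spectrum <- function(config) {
  if (!inherits(config, "tube_config")) {
    abort("config must be a tube_config", class = "leadequiv_config_error")
  }
  kvp <- config$kvp; dE <- config$bin_width_keV
  n <- floor((kvp - .E_MIN) / dE)
  e <- .E_MIN + dE * (seq_len(n) - 0.5)
  atten <- .tube_filtration(e, kvp, config)
  fl <- (kvp - e) / e * atten
  if (kvp > .W_K_EDGE) {
    # total line fluence relative to the (filtered) continuum
    frac <- 0.25 * (kvp / .W_K_EDGE - 1)^1.67
    lines <- .W_K_LINES
    lw <- lines$intensity * .tube_filtration(lines$energy, kvp, config)
    lw <- lw / sum(lw) * frac * sum(fl)
    idx <- pmin(pmax(findInterval(lines$energy, e - dE / 2), 1L), n)
    fl[idx] <- fl[idx] + lw
  }
  .new_spectrum(e, fl, kvp)
}

# target self-filtration + added Al filtration
.tube_filtration <- function(e, kvp, config) {
  w_path <- 3e-4 * pmax(1 - e / kvp, 0) / tan(config$anode_angle_deg * pi / 180)
  mu_w <- mu_rho("W", e) * .W_DENSITY
  mu_al <- mu_rho("Al", e) * .AL_DENSITY
  exp(-mu_w * w_path - mu_al * config$filtration_mm_al / 10)
}

#' Load a vendored reference spectrum
#'
#' Reference spectra at 80, 100 and 120 kVp shipped as CSV fixtures.  They
#' are synthetic references produced once by the package's own spectrum
#' model at a fixed reference tube configuration (see the package vignette);
#' they are the default beam input of the equivalence pipeline.
#'
#' @param kvp One of 80, 100, 120.
#' @return A spectrum tibble.
#' @export
reference_spectrum <- function(kvp) {
  if (!kvp %in% c(80, 100, 120)) {
    abort("reference spectra are vendored for 80, 100 and 120 kVp only",
          class = "leadequiv_config_error")
  }
  path <- system.file("extdata", "spectra",
                      sprintf("spectrum_ref_%03d.csv", kvp),
                      package = "leadequiv", mustWork = TRUE)
  read_spectrum(path, kvp = kvp)
}

#' Read / write a spectrum CSV
#'
#' Two-column CSV `energy_keV,fluence`; `#` comment lines are ignored.
#' Energies must be strictly ascending and fluence non-negative.
#'
#' @param path File path.
#' @param kvp Optional tube potential; defaults to the maximum energy with
#'   positive fluence.
#' @return A spectrum tibble.
#' @export
read_spectrum <- function(path, kvp = NULL) {
  d <- read.csv(path, comment.char = "#")
  if (!all(c("energy_keV", "fluence") %in% names(d))) {
    abort("spectrum CSV must have columns energy_keV,fluence",
          class = "leadequiv_format_error")
  }
  if (any(diff(d$energy_keV) <= 0)) {
    abort("spectrum energies must be strictly ascending",
          class = "leadequiv_format_error")
  }
  if (any(d$fluence < 0) || !any(d$fluence > 0)) {
    abort("spectrum fluence must be non-negative with at least one positive bin",
          class = "leadequiv_format_error")
  }
  if (is.null(kvp)) kvp <- max(d$energy_keV[d$fluence > 0])
  .new_spectrum(d$energy_keV, d$fluence, kvp)
}

#' @rdname read_spectrum
#' @param spectrum A spectrum tibble.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  writeLines(sprintf("# x-ray spectrum, kvp=%g", attr(spectrum, "kvp")), path)
  suppressWarnings(write.table(
    data.frame(energy_keV = spectrum$energy_keV, fluence = spectrum$fluence),
    path, sep = ",", row.names = FALSE, quote = FALSE, append = TRUE))
  invisible(path)
}

#' Mean energy of a spectrum
#'
#' @param spectrum A spectrum tibble.
#' @return Fluence-weighted mean energy in keV.
#' @export
spectrum_mean_energy <- function(spectrum) {
  sum(spectrum$energy_keV * spectrum$fluence) / sum(spectrum$fluence)
}

#' Compare two spectra
#'
#' Both spectra are rebinned onto a common grid over the overlap of their
#' energy supports and normalised to unit area; the report contains the
#' root-mean-square difference normalised by the peak of the reference
#' (`nrmse`), the offset of the fluence peak (`peak_offset_keV`) and the
#' absolute difference in mean energy (`mean_energy_diff_keV`).  All three
#' are zero for identical spectra.
#'
#' @param a,b Spectrum tibbles (`b` is the reference).
#' @param bin_width_keV Common grid width; defaults to the coarser of the
#'   two native bin widths.
#' @return One-row tibble with the three metrics.
#' @export
spectrum_similarity <- function(a, b, bin_width_keV = NULL) {
  lo <- max(min(a$energy_keV), min(b$energy_keV))
  hi <- min(max(a$energy_keV), max(b$energy_keV))
  if (hi <= lo) {
    abort("spectra have non-overlapping energy supports",
          class = "leadequiv_format_error")
  }
  if (is.null(bin_width_keV)) {
    bw <- function(s) if (nrow(s) > 1) stats::median(diff(s$energy_keV)) else 1
    bin_width_keV <- max(bw(a), bw(b))
  }
  edges <- seq(lo - bin_width_keV / 2, hi + bin_width_keV, by = bin_width_keV)
  rebin <- function(s) {
    i <- findInterval(s$energy_keV, edges)
    keep <- i >= 1 & i < length(edges)
    f <- tapply(s$fluence[keep], factor(i[keep], levels = seq_len(length(edges) - 1)),
                sum, default = 0)
    f <- as.numeric(f)
    f / (sum(f) * bin_width_keV)
  }
  fa <- rebin(a); fb <- rebin(b)
  centers <- edges[-length(edges)] + bin_width_keV / 2
  tibble(
    nrmse = sqrt(mean((fa - fb)^2)) / max(fb),
    peak_offset_keV = abs(centers[which.max(fa)] - centers[which.max(fb)]),
    mean_energy_diff_keV = abs(spectrum_mean_energy(a) - spectrum_mean_energy(b))
  )
}
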