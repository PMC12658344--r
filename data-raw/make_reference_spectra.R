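# Generate the vendored reference spectra (inst/extdata/spectra/), the
# default beam input of the equivalence pipeline.
#
# These are synthetic references: produced once by the package's own
# Kramers-form tungsten-anode model at the fixed reference configuration
# (12 degree anode, 2.5 mm Al total filtration, 0.5 keV bins), but with the
# continuum integrated over 0.1 keV sub-bins rather than evaluated at bin
# centers, so they are not bit-identical to generate_spectrum() output.
#
# Run from the package root after installing the package:
#   Rscript data-raw/make_reference_spectra.R

library(leadequiv)

ref_spectrum <- function(kvp, bin = 0.5, sub = 0.1) {
  cfg <- tube_config(kvp, anode_angle_deg = 12, filtration_mm_al = 2.5,
                     bin_width_keV = bin)
  nf <- floor((kvp - 1) / sub)
  ef <- 1 + sub * (seq_len(nf) - 0.5)
  filt <- leadequiv:::.tube_filtration(ef, kvp, cfg)
  flf <- (kvp - ef) / ef * filt
  n <- floor((kvp - 1) / bin)
  centers <- 1 + bin * (seq_len(n) - 0.5)
  idx <- pmin(pmax(floor((ef - 1) / bin) + 1L, 1L), n)
  fl <- as.numeric(tapply(flf, factor(idx, levels = seq_len(n)), sum, default = 0)) *
    sub / bin
  if (kvp > 69.525) {
    lines <- tibble::tribble(~energy, ~intensity,
                             59.32, 100, 57.98, 57.6, 67.24, 33, 69.07, 8.7)
    frac <- 0.25 * (kvp / 69.525 - 1)^1.67
    lw <- lines$intensity * leadequiv:::.tube_filtration(lines$energy, kvp, cfg)
    lw <- lw / sum(lw) * frac * sum(fl)
    li <- pmin(pmax(findInterval(lines$energy, centers - bin / 2), 1L), n)
    fl[li] <- fl[li] + lw
  }
  fl <- fl / max(fl)
  s <- tibble::tibble(energy_keV = centers, fluence = signif(fl, 6))
  attr(s, "kvp") <- kvp
  class(s) <- c("xray_spectrum", class(s))
  s
}

dir.create("inst/extdata/spectra", showWarnings = FALSE, recursive = TRUE)
for (kvp in c(80, 100, 120)) {
  s <- ref_spectrum(kvp)
  path <- sprintf("inst/extdata/spectra/spectrum_ref_%03d.csv", kvp)
  writeLines(c(sprintf("# synthetic reference spectrum, %d kVp tungsten anode", kvp),
               "# 12 deg anode, 2.5 mm Al total filtration, 0.5 keV bins",
               "# produced by data-raw/make_reference_spectra.R"), path)
  suppressWarnings(write.table(as.data.frame(s), path, sep = ",",
                               row.names = FALSE, quote = FALSE, append = TRUE))
  cat(sprintf("%d kVp: %d bins, mean energy %.2f keV\n", kvp, nrow(s),
              spectrum_mean_energy(s)))
}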