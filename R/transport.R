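# Slab transmission engines.  The deterministic narrow-beam engine is the
# pipeline default; the analog Monte Carlo broad-beam engine (mc.R)
# reproduces the source / slab / detector geometry and bounds the
# sensitivity of the lead-equivalence results to scatter build-up.

.DEFAULT_THICKNESS_GRID <- c(0.1, 0.2, 0.5, 1, 1.5, 2, 2.5, 3)

#' Broad-beam geometry specification
#'
#' Source at the origin, slab front face at `source_to_shield_cm`, detector
#' disc behind the slab.  Photon directions are sampled in the cone
#' subtending the shield half-width.
#'
#' @param source_to_shield_cm Source to shield distance (default 100 cm).
#' @param shield_lateral_halfwidth_cm Lateral half-width of the field at the
#'   shield.
#' @param detector_radius_cm Radius of the detector disc.
#' @param shield_to_detector_cm Gap between slab exit face and detector.
#' @return Object of class `geometry_spec`.
#' @export
geometry_spec <- function(source_to_shield_cm = 100,
                          shield_lateral_halfwidth_cm = 10,
                          detector_radius_cm = 5,
                          shield_to_detector_cm = 10) {
  vals <- c(source_to_shield_cm, shield_lateral_halfwidth_cm,
            detector_radius_cm, shield_to_detector_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("geometry dimensions must be positive", class = "leadequiv_config_error")
  }
  structure(list(source_to_shield_cm = source_to_shield_cm,
                 shield_lateral_halfwidth_cm = shield_lateral_halfwidth_cm,
                 detector_radius_cm = detector_radius_cm,
                 shield_to_detector_cm = shield_to_detector_cm),
            class = "geometry_spec")
}

#' Monte Carlo run configuration
#'
#' @param n_histories Number of photon histories per transmission point.
#' @param seed RNG seed; identical seed and configuration give bit-identical
#'   tallies.
#' @param coherent_enabled Sample coherent (Thomson-like) scattering.
#' @param energy_cutoff_keV Photons falling below this energy are absorbed.
#' @param tally `"fluence"` (photon count) or `"energy"` (air-kerma-weighted
#'   energy deposition).
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(n_histories = 1e6, seed = 1, coherent_enabled = TRUE,
                      energy_cutoff_keV = 1, tally = "fluence") {
  tally <- arg_match0(tally, c("fluence", "energy"))
  if (n_histories < 1 || energy_cutoff_keV < 1) {
    abort("n_histories must be >= 1 and energy_cutoff_keV >= 1",
          class = "leadequiv_config_error")
  }
  structure(list(n_histories = as.integer(n_histories), seed = as.integer(seed),
                 coherent_enabled = isTRUE(coherent_enabled),
                 energy_cutoff_keV = energy_cutoff_keV, tally = tally),
            class = "mc_config")
}

#' Deterministic narrow-beam transmission
#'
#' Polyenergetic Beer-Lambert transmission of a slab,
#' \deqn{T(t) = \frac{\sum_E w(E)\, q(E)\, e^{-\mu(E) t}}{\sum_E w(E)\, q(E)},}
#' with \eqn{q(E) = 1} for fluence weighting and
#' \eqn{q(E) = E \,(\mu_{en}/\rho)_{air}(E)} for air-kerma weighting.
#' Invariant to rescaling of the spectrum.
#'
#' @param spectrum A spectrum tibble.
#' @param material A [composite()] or [toy_material()].
#' @param thickness_mm Slab thickness in mm (vectorised).
#' @param weighting `"fluence"` (default) or `"kerma"`.
#' @return Transmission fraction(s) in (0, 1].
#' @examples
#' narrow_beam_transmission(make_monoenergetic(100), pb_material(), 0.5)
#' @export
narrow_beam_transmission <- function(spectrum, material, thickness_mm,
                                     weighting = "fluence") {
  weighting <- arg_match0(weighting, c("fluence", "kerma"))
  if (any(thickness_mm < 0)) {
    abort("thickness must be non-negative", class = "leadequiv_config_error")
  }
  keep <- spectrum$fluence > 0
  e <- spectrum$energy_keV[keep]
  w <- spectrum$fluence[keep]
  if (weighting == "kerma") w <- w * e * air_muen_rho(e)
  mu <- linear_mu(material, e)          # 1/cm
  vapply(thickness_mm,
         function(t) sum(w * exp(-mu * t / 10)) / sum(w),
         numeric(1))
}

#' Build a transmission curve
#'
#' Transmission at a grid of slab thicknesses for one material and spectrum,
#' using either the deterministic narrow-beam engine or the Monte Carlo
#' broad-beam engine.
#'
#' @inheritParams narrow_beam_transmission
#' @param thicknesses Ascending thickness grid in mm (default the 8-point
#'   grid 0.1, 0.2, 0.5, 1, 1.5, 2, 2.5, 3).
#' @param engine `"deterministic"` (default) or `"mc"`.
#' @param geometry,mc Geometry and Monte Carlo configuration (MC engine).
#' @param primaries_only MC engine: discard scattered photons (narrow-beam
#'   emulation).
#' @return A `transmission_curve` tibble with columns `thickness_mm`,
#'   `transmission`, `stderr` and provenance attributes (`material`, `kvp`,
#'   `engine`, `weighting`, and for MC runs `seed`/`n_histories`).
#' @export
build_curve <- function(spectrum, material, thicknesses = .DEFAULT_THICKNESS_GRID,
                        engine = "deterministic", weighting = "fluence",
                        geometry = geometry_spec(), mc = mc_config(),
                        primaries_only = FALSE) {
  engine <- arg_match0(engine, c("deterministic", "mc"))
  weighting <- arg_match0(weighting, c("fluence", "kerma"))
  if (is.unsorted(thicknesses, strictly = TRUE)) {
    abort("thicknesses must be strictly ascending", class = "leadequiv_config_error")
  }
  if (engine == "deterministic") {
    tr <- narrow_beam_transmission(spectrum, material, thicknesses, weighting)
    se <- rep(0, length(thicknesses))
    extra <- list()
  } else {
    # the curve label follows the MC tally
    weighting <- if (mc$tally == "energy") "kerma" else "fluence"
    res <- purrr::map(thicknesses, function(t) {
      mc_transmission(spectrum, material, t, geometry = geometry, mc = mc,
                      primaries_only = primaries_only)
    })
    tr <- purrr::map_dbl(res, "transmission")
    se <- purrr::map_dbl(res, "stderr")
    extra <- list(seed = mc$seed, n_histories = mc$n_histories)
  }
  curve <- tibble(thickness_mm = thicknesses, transmission = tr, stderr = se)
  attr(curve, "material") <- material$name
  attr(curve, "density") <- material$density
  attr(curve, "kvp") <- attr(spectrum, "kvp")
  attr(curve, "engine") <- engine
  attr(curve, "weighting") <- weighting
  for (nm in names(extra)) attr(curve, nm) <- extra[[nm]]
  class(curve) <- c("transmission_curve", class(curve))
  curve
}

#' Write a transmission curve as CSV
#'
#' @param curve A `transmission_curve`.
#' @param path Output path.
#' @export
write_curve <- function(curve, path) {
  writeLines(sprintf("# transmission curve: material=%s kvp=%s engine=%s weighting=%s",
                     attr(curve, "material"), attr(curve, "kvp"),
                     attr(curve, "engine"), attr(curve, "weighting")), path)
  suppressWarnings(write.table(as.data.frame(curve), path, sep = ",",
                               row.names = FALSE, quote = FALSE, append = TRUE))
  invisible(path)
}
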