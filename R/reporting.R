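# End-to-end run configuration, output writing and provenance.  These
# functions back the thin command-line wrapper in inst/cli/leadequiv.R.

#' Validated run configuration
#'
#' Collects every knob of the equivalence pipeline, validates it up front
#' and serialises it into the provenance block of every output file.
#'
#' @param spectra Tube potentials resolved via [reference_spectrum()]
#'   (default `c(80, 100, 120)`) or a character vector of spectrum CSV paths.
#' @param materials `NULL` for the full registry, or a vector of registry
#'   names/abbreviations.
#' @param engine `"deterministic"` or `"mc"`.
#' @param weighting `"fluence"` or `"kerma"`.
#' @param targets Lead reference thicknesses in mm.
#' @param thicknesses Curve thickness grid in mm.
#' @param fit_kind Curve model, see [fit_curve()].
#' @param histories,seed Monte Carlo knobs (MC engine only).
#' @param out_dir Output directory for [run_table_pipeline()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(spectra = c(80, 100, 120), materials = NULL,
                       engine = "deterministic", weighting = "fluence",
                       targets = c(0.35, 0.5),
                       thicknesses = .DEFAULT_THICKNESS_GRID,
                       fit_kind = "log_interp",
                       histories = 1e6, seed = 1, out_dir = ".") {
  engine <- arg_match0(engine, c("deterministic", "mc"))
  weighting <- arg_match0(weighting, c("fluence", "kerma"))
  fit_kind <- arg_match0(fit_kind, c("log_interp", "exp1", "exp2"))
  if (!length(targets) || any(!is.finite(targets)) || any(targets <= 0)) {
    abort("targets must be positive lead thicknesses in mm",
          class = "leadequiv_config_error")
  }
  if (any(diff(thicknesses) <= 0) || any(thicknesses <= 0)) {
    abort("thicknesses must be a positive ascending grid",
          class = "leadequiv_config_error")
  }
  if (is.numeric(spectra) && !all(spectra %in% c(80, 100, 120))) {
    abort("numeric spectra must be reference potentials 80/100/120",
          class = "leadequiv_config_error")
  }
  structure(list(spectra = spectra, materials = materials, engine = engine,
                 weighting = weighting, targets = targets,
                 thicknesses = thicknesses, fit_kind = fit_kind,
                 histories = histories, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after reading.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
          class = "leadequiv_config_error")
  }
  vals <- utils::modifyList(vals, list(...))
  do.call(run_config, vals)
}

.config_spectra <- function(config) {
  if (is.numeric(config$spectra)) {
    purrr::map(config$spectra, reference_spectrum)
  } else {
    purrr::map(config$spectra, read_spectrum)
  }
}

.config_registry <- function(config) {
  reg <- load_registry()
  if (is.null(config$materials)) return(reg)
  idx <- purrr::map_int(config$materials, function(m) {
    comp <- registry_composite(m, reg)
    which(reg$abbreviation == comp$abbreviation)
  })
  reg[idx, ]
}

.provenance <- function(config) {
  c(unclass(config)[setdiff(names(unclass(config)), "out_dir")],
    list(package_version = as.character(utils::packageVersion("leadequiv")),
         pb_density_g_cm3 = .PB_DENSITY))
}

#' Run the full tabulation pipeline and write outputs
#'
#' Computes the equivalence summary for the configuration and writes
#' `table2.csv` (equivalent thicknesses, standard layout), `mass.csv`
#' (areal masses), `scatter.csv` (mass-vs-thickness export) and
#' `provenance.json` (the serialised configuration) into the output
#' directory.  Deterministic-engine runs are bit-reproducible.
#'
#' @param config A [run_config()].
#' @return The `shield_summary`, invisibly.
#' @export
run_table_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- build_summary(
    registry = .config_registry(config),
    spectra = .config_spectra(config),
    targets = config$targets, engine = config$engine,
    weighting = config$weighting, thicknesses = config$thicknesses,
    fit_kind = config$fit_kind,
    mc = mc_config(n_histories = config$histories, seed = config$seed,
                   tally = if (config$weighting == "kerma") "energy" else "fluence"))
  utils::write.csv(thickness_table(summary),
                   file.path(config$out_dir, "table2.csv"), row.names = FALSE)
  utils::write.csv(mass_table(summary),
                   file.path(config$out_dir, "mass.csv"), row.names = FALSE)
  sc <- mass_thickness_scatter(summary)
  utils::write.csv(as.data.frame(sc),
                   file.path(config$out_dir, "scatter.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(.provenance(config), list(scatter_trend = as.list(attr(sc, "trend")))),
    file.path(config$out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Single-cell equivalence report
#'
#' @param material Registry name or abbreviation.
#' @param kvp Tube potential.
#' @param target Lead reference thickness in mm.
#' @param config A [run_config()] supplying engine/weighting/grid.
#' @return A list (JSON-serialisable) with the equivalence result, fit
#'   diagnostics and the provenance block.
#' @export
equivalence_report <- function(material, kvp, target, config = run_config()) {
  comp <- registry_composite(material)
  spec <- if (is.numeric(config$spectra)) reference_spectrum(kvp) else {
    specs <- .config_spectra(config)
    kv <- purrr::map_dbl(specs, ~ attr(.x, "kvp"))
    specs[[which.min(abs(kv - kvp))]]
  }
  mcc <- mc_config(n_histories = config$histories, seed = config$seed,
                   tally = if (config$weighting == "kerma") "energy" else "fluence")
  curve <- build_curve(spec, comp, config$thicknesses, engine = config$engine,
                       weighting = config$weighting, mc = mcc)
  ref <- pb_reference_transmission(spec, target, engine = config$engine,
                                   weighting = attr(curve, "weighting"), mc = mcc)
  fit <- fit_curve(curve, kind = config$fit_kind)
  t_eq <- solve_t_eq(fit, ref)
  list(material = comp$abbreviation, kvp = kvp, pb_target_mm = target,
       target_transmission = as.numeric(ref),
       t_eq_mm = t_eq, areal_mass_kg_m2 = areal_mass(comp, t_eq),
       fit = as.list(glance(fit)), provenance = .provenance(config))
}

#' Spectrum validation report
#'
#' Compares a generated (or user-supplied) spectrum against a vendored
#' reference and reports the similarity metrics.
#'
#' @param spectrum A spectrum tibble, or a tube potential (the analytic
#'   generator is used).
#' @param reference_kvp Reference potential (80/100/120).
#' @param strict If `TRUE`, error when `nrmse` exceeds `nrmse_bound`.
#' @param nrmse_bound Regression bound on the normalised RMSE.
#' @return One-row tibble of similarity metrics.
#' @export
validate_spectrum_report <- function(spectrum, reference_kvp,
                                     strict = FALSE, nrmse_bound = 0.05) {
  if (is.numeric(spectrum) && length(spectrum) == 1) {
    spectrum <- generate_spectrum(tube_config(spectrum))
  }
  ref <- reference_spectrum(reference_kvp)
  rep <- spectrum_similarity(spectrum, ref)
  if (strict && rep$nrmse > nrmse_bound) {
    abort(sprintf("spectrum validation failed: nrmse %.4f > bound %.4f",
                  rep$nrmse, nrmse_bound),
          class = "leadequiv_validation_error")
  }
  rep
}
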