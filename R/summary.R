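# Study-level summaries: the full material x spectrum x lead-target table,
# areal-mass rankings, range statistics and the mass-vs-thickness export.

#' Build the full equivalence summary
#'
#' Runs [lead_equivalence()] for every combination of registry material,
#' spectrum and lead reference target under one consistent engine and
#' weighting (the default study layout: 18 materials x 3 tube potentials x
#' 2 targets = 108 results).
#'
#' @param registry Registry tibble from [load_registry()] (or a subset).
#' @param spectra A list of spectrum tibbles, or a numeric vector of tube
#'   potentials resolved through [reference_spectrum()].  Default
#'   `c(80, 100, 120)`.
#' @param targets Lead reference thicknesses in mm (default 0.35 and 0.5).
#' @inheritParams lead_equivalence
#' @return A `shield_summary` tibble (one row per cell) with provenance
#'   attributes `engine`, `weighting`, `fit_kind`, `thicknesses`.
#' @export
build_summary <- function(registry = load_registry(),
                          spectra = c(80, 100, 120),
                          targets = c(0.35, 0.5),
                          engine = "deterministic", weighting = "fluence",
                          thicknesses = .DEFAULT_THICKNESS_GRID,
                          fit_kind = "log_interp",
                          geometry = geometry_spec(), mc = mc_config()) {
  if (is.numeric(spectra)) spectra <- purrr::map(spectra, reference_spectrum)
  if (any(targets <= 0)) {
    abort("lead reference targets must be positive", class = "leadequiv_config_error")
  }
  rows <- list()
  for (s in spectra) {
    for (i in seq_len(nrow(registry))) {
      for (tg in targets) {
        row <- tryCatch(
          lead_equivalence(s, registry$composite[[i]], tg, engine = engine,
                           weighting = weighting, thicknesses = thicknesses,
                           fit_kind = fit_kind, geometry = geometry, mc = mc),
          error = function(e) {
            abort(sprintf("equivalence failed for %s at %s kVp, %.2f mm Pb: %s",
                          registry$abbreviation[i], attr(s, "kvp"), tg,
                          conditionMessage(e)),
                  class = "leadequiv_cell_error")
          })
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- bind_rows(rows)
  attr(out, "engine") <- engine
  attr(out, "weighting") <- weighting
  attr(out, "fit_kind") <- fit_kind
  attr(out, "thicknesses") <- thicknesses
  class(out) <- c("shield_summary", class(out))
  out
}

#' Equivalent-thickness table in the standard layout
#'
#' Rows are materials, columns tube potential x lead target (0.5 mm before
#' 0.35 mm within each potential), values equivalent thickness in mm
#' rounded to 2 decimals.
#'
#' @param summary A `shield_summary`.
#' @param digits Decimal places for reporting (default 2).
#' @return A tibble, one row per material.
#' @export
thickness_table <- function(summary, digits = 2) {
  .wide_table(summary, "t_eq_mm", digits)
}

#' Areal-mass table in the standard layout
#'
#' @inheritParams thickness_table
#' @return A tibble of areal masses (kg/m^2), layout as [thickness_table()].
#' @export
mass_table <- function(summary, digits = 2) {
  .wide_table(summary, "areal_mass_kg_m2", digits)
}

.wide_table <- function(summary, value_col, digits) {
  d <- summary %>%
    mutate(col = sprintf("kvp%g_pb%g", .data$kvp, .data$pb_target_mm),
           value = round(.data[[value_col]], digits)) %>%
    select("material", "col", "value")
  ord <- d %>%
    mutate(kvp = as.numeric(sub("kvp([0-9.]+)_.*", "\\1", .data$col)),
           pb = as.numeric(sub(".*_pb([0-9.]+)", "\\1", .data$col))) %>%
    arrange(.data$kvp, desc(.data$pb)) %>%
    pull("col") %>% unique()
  tidyr::pivot_wider(d, names_from = "col", values_from = "value") %>%
    select(all_of(c("material", ord)))
}

#' Range statistics of the equivalent thicknesses
#'
#' Minimum and maximum computed equivalent thickness per lead target across
#' all materials and spectra.
#'
#' @param summary A `shield_summary`.
#' @return Tibble with columns `pb_target_mm`, `min_t_eq_mm`, `max_t_eq_mm`,
#'   `min_material`, `max_material`.
#' @export
summary_ranges <- function(summary) {
  summary %>%
    group_by(.data$pb_target_mm) %>%
    summarise(min_t_eq_mm = min(.data$t_eq_mm),
              max_t_eq_mm = max(.data$t_eq_mm),
              min_material = .data$material[which.min(.data$t_eq_mm)],
              max_material = .data$material[which.max(.data$t_eq_mm)],
              .groups = "drop")
}

#' Percent areal-mass increase between lead targets
#'
#' Per material and tube potential, the percent increase in areal mass when
#' moving from the lighter to the heavier lead-equivalence target (for a
#' fixed material this equals the thickness ratio).
#'
#' @param summary A `shield_summary` containing both targets.
#' @param from,to The two lead targets in mm (defaults 0.35 and 0.5).
#' @return Tibble `material`, `kvp`, `percent_increase`.
#' @export
percent_mass_increase <- function(summary, from = 0.35, to = 0.5) {
  a <- summary %>% filter(.data$pb_target_mm == from) %>%
    select("material", "kvp", mass_from = "areal_mass_kg_m2")
  b <- summary %>% filter(.data$pb_target_mm == to) %>%
    select("material", "kvp", mass_to = "areal_mass_kg_m2")
  left_join(a, b, by = c("material", "kvp")) %>%
    mutate(percent_increase = 100 * (.data$mass_to - .data$mass_from) /
             .data$mass_from) %>%
    select("material", "kvp", "percent_increase")
}

#' Rank materials by areal mass
#'
#' @param summary A `shield_summary`.
#' @param kvp Tube potential to rank at.
#' @param target Lead target in mm.
#' @return Tibble ordered lightest first; ties broken alphabetically.
#' @export
rank_by_mass <- function(summary, kvp, target) {
  d <- summary %>%
    filter(.data$kvp == !!kvp, .data$pb_target_mm == !!target)
  if (!nrow(d)) {
    abort("summary has no rows for the requested potential and target",
          class = "leadequiv_config_error")
  }
  d %>%
    arrange(.data$areal_mass_kg_m2, .data$material) %>%
    mutate(rank = seq_len(n())) %>%
    select("rank", "material", "t_eq_mm", "areal_mass_kg_m2")
}

#' Mass-versus-thickness export
#'
#' Scatter export for the mass/thickness comparison across all cells, with
#' the least-squares linear trend of the non-lead materials.
#'
#' @param summary A `shield_summary`.
#' @return Tibble `thickness_mm`, `mass_kg_m2`, `material`, `kvp`,
#'   `pb_target_mm`, `is_lead`, with the trend coefficients in attribute
#'   `trend` (`intercept`, `slope`).
#' @export
mass_thickness_scatter <- function(summary) {
  d <- summary %>%
    mutate(is_lead = .data$material == "Pb-PVC") %>%
    select(thickness_mm = "t_eq_mm", mass_kg_m2 = "areal_mass_kg_m2",
           "material", "kvp", "pb_target_mm", "is_lead")
  nl <- d %>% filter(!.data$is_lead)
  trend <- if (nrow(nl) >= 2) {
    fit <- lm(mass_kg_m2 ~ thickness_mm, data = nl)
    c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
  } else {
    c(intercept = NA_real_, slope = NA_real_)
  }
  attr(d, "trend") <- trend
  d
}

#' @export
glance.shield_summary <- function(x, ...) {
  pmi <- percent_mass_increase(x)
  tibble(n_cells = nrow(x),
         n_materials = length(unique(x$material)),
         n_kvp = length(unique(x$kvp)),
         min_t_eq_mm = min(x$t_eq_mm), max_t_eq_mm = max(x$t_eq_mm),
         min_mass_increase_pct = min(pmi$percent_increase),
         median_mass_increase_pct = stats::median(pmi$percent_increase),
         max_mass_increase_pct = max(pmi$percent_increase))
}
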