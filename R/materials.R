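# Shielding materials: chemical formula parsing, the built-in registry of
# filler/polymer composites, and mixture-rule attenuation coefficients.

# "PVC" in component lists is shorthand for the vinyl chloride repeat unit.
.PVC_FORMULA <- "C2H3Cl"
.PB_DENSITY <- 11.35  # g/cm^3, pure lead reference slabs

#' Parse a chemical formula into elemental mass fractions
#'
#' Formulas use element symbols with optional integer counts, e.g. `"Bi2O3"`,
#' `"BaSO4"`, `"C2H3Cl"`.  The shorthand `"PVC"` is accepted for the vinyl
#' chloride repeat unit C2H3Cl.  Mass fractions are computed from standard
#' atomic masses.
#'
#' @param formula Chemical formula string.
#' @return Tibble with columns `element`, `count`, `fraction`; fractions sum
#'   to one.
#' @examples
#' parse_formula("Bi2O3")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  if (identical(formula, "PVC")) formula <- .PVC_FORMULA
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != formula) {
    abort(sprintf("cannot parse formula '%s'", formula),
          class = "leadequiv_formula_error")
  }
  sym <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
  cnt[is.na(cnt)] <- 1L
  if (any(cnt == 0)) {
    abort(sprintf("zero count in formula '%s'", formula),
          class = "leadequiv_formula_error")
  }
  unknown <- setdiff(sym, .ELEMENT_INFO$symbol)
  if (length(unknown)) {
    abort(sprintf("unknown element(s) %s in formula '%s'",
                  paste(unknown, collapse = ", "), formula),
          class = "leadequiv_formula_error")
  }
  agg <- tapply(cnt, sym, sum)
  sym <- names(agg); cnt <- as.numeric(agg)
  mass <- .ELEMENT_INFO$atomic_mass[match(sym, .ELEMENT_INFO$symbol)]
  w <- cnt * mass
  tibble(element = sym, count = cnt, fraction = w / sum(w)) %>%
    arrange(.data$element)
}

#' Define a shielding composite
#'
#' A composite is a named mixture of compounds (weight percent summing to
#' 100) with a bulk density.  The registry composites pair 78 wt% of
#' high-Z filler compounds with 22 wt% PVC.
#'
#' @param name Canonical name.
#' @param components Named numeric vector of weight percents; names are
#'   chemical formulas (`"PVC"` allowed).
#' @param density Bulk density in g/cm^3.
#' @param abbreviation Optional short label (defaults to `name`).
#' @return An object of class `composite`.
#' @examples
#' composite("Pb-PVC", c(Pb = 78, PVC = 22), density = 3.46)
#' @export
composite <- function(name, components, density, abbreviation = name) {
  stopifnot(is.numeric(components), !is.null(names(components)),
            all(nzchar(names(components))))
  if (abs(sum(components) - 100) > 1e-6) {
    abort(sprintf("component weight percents must sum to 100 (got %g)",
                  sum(components)),
          class = "leadequiv_composite_error")
  }
  if (any(components <= 0)) {
    abort("component weight percents must be positive",
          class = "leadequiv_composite_error")
  }
  if (!is.numeric(density) || length(density) != 1 || density <= 0) {
    abort("density must be a positive scalar (g/cm^3)",
          class = "leadequiv_composite_error")
  }
  structure(list(name = name, abbreviation = abbreviation,
                 components = components, density = density),
            class = "composite")
}

#' @export
print.composite <- function(x, ...) {
  cat(sprintf("<composite> %s (%s), density %.3f g/cm^3\n",
              x$name, x$abbreviation, x$density))
  cat(paste(sprintf("  %s: %g%%", names(x$components), x$components),
            collapse = "\n"), "\n")
  invisible(x)
}

# registry rows: abbreviation, filler compounds with wt%, density
.REGISTRY_ROWS <- list(
  list("Bi2O3-BaSO4-PVC",       "Bi-Ba",    c(BaSO4 = 39, Bi2O3 = 39), 2.886),
  list("Bi2O3-Gd2O3-PVC",       "Bi-Gd",    c(Bi2O3 = 39, Gd2O3 = 39), 3.2),
  list("Bi2O3-Gd2O3-BaSO4-PVC", "Bi-Gd-Ba", c(BaSO4 = 26, Bi2O3 = 26, Gd2O3 = 26), 2.946),
  list("Bi2O3-Sb2O3-PVC",       "Bi-Sb",    c(Bi2O3 = 39, Sb2O3 = 39), 2.986),
  list("Bi2O3-Sb2O3-Gd2O3-PVC", "Bi-Sb-Gd", c(Bi2O3 = 26, Sb2O3 = 26, Gd2O3 = 26), 3.015),
  list("Bi2O3-Sn-PVC",          "Bi-Sn",    c(Sn = 39, Bi2O3 = 39), 3.193),
  list("Bi2O3-Sn-Gd2O3-PVC",    "Bi-Sn-Gd", c(Sn = 26, Bi2O3 = 26, Gd2O3 = 26), 3.152),
  list("Bi2O3-W-BaSO4-PVC",     "Bi-W-Ba",  c(W = 26, BaSO4 = 26, Bi2O3 = 26), 3.146),
  list("Bi2O3-W-Sb2O3-PVC",     "Bi-W-Sb",  c(W = 26, Bi2O3 = 26, Sb2O3 = 26), 3.225),
  list("Bi2O3-W-Sn-PVC",        "Bi-W-Sn",  c(W = 26, Sn = 26, Bi2O3 = 26), 3.382),
  list("Pb-PVC",                "Pb-PVC",   c(Pb = 78), 3.46),
  list("W-BaSO4-PVC",           "W-Ba",     c(W = 39, BaSO4 = 39), 3.059),
  list("W-Gd2O3-PVC",           "W-Gd",     c(W = 39, Gd2O3 = 39), 3.414),
  list("W-Gd2O3-BaSO4-PVC",     "W-Gd-Ba",  c(W = 26, BaSO4 = 26, Gd2O3 = 26), 3.064),
  list("W-Gd2O3-Sb2O3-PVC",     "W-Gd-Sb",  c(W = 26, Sb2O3 = 26, Gd2O3 = 26), 3.139),
  list("W-Sb2O3-PVC",           "W-Sb",     c(W = 39, Sb2O3 = 39), 3.172),
  list("W-Sn-PVC",              "W-Sn",     c(W = 39, Sn = 39), 3.406),
  list("W-Sn-Gd2O3-PVC",        "W-Sn-Gd",  c(W = 26, Sn = 26, Gd2O3 = 26), 3.288)
)

#' Load the built-in composite registry
#'
#' The 18 modelled flexible shields: every entry combines 78 wt% of one to
#' three high-Z filler compounds (equal shares) with 22 wt% PVC; densities
#' are the modelled bulk values and are treated as given constants.
#'
#' @return Tibble with columns `name`, `abbreviation`, `density_g_cm3` and a
#'   list-column `composite` of [composite()] objects.
#' @examples
#' load_registry()
#' @export
load_registry <- function() {
  rows <- purrr::map(.REGISTRY_ROWS, function(r) {
    comp <- composite(r[[1]], c(r[[3]], PVC = 100 - sum(r[[3]])),
                      density = r[[4]], abbreviation = r[[2]])
    tibble(name = r[[1]], abbreviation = r[[2]], density_g_cm3 = r[[4]],
           composite = list(comp))
  })
  bind_rows(rows)
}

#' Fetch one registry composite by name or abbreviation
#'
#' Matching ignores case and treats `-`, en dashes and whitespace as
#' equivalent separators.
#'
#' @param label Composite name or abbreviated name (e.g. `"W-Sn-Gd"`).
#' @param registry Registry tibble, defaults to [load_registry()].
#' @return A [composite()] object.
#' @export
registry_composite <- function(label, registry = load_registry()) {
  norm <- function(x) tolower(gsub("[‐-―\\s-]+", "", x, perl = TRUE))
  hit <- which(norm(registry$abbreviation) == norm(label) |
                 norm(registry$name) == norm(label))
  if (length(hit) != 1) {
    abort(sprintf("unknown composite '%s'", label),
          class = "leadequiv_unknown_material")
  }
  registry$composite[[hit]]
}

#' The pure-lead reference material
#'
#' @param density Density of lead in g/cm^3 (default 11.35).
#' @return A [composite()] object representing a pure Pb slab.
#' @export
pb_material <- function(density = .PB_DENSITY) {
  composite("Pb", c(Pb = 100), density = density, abbreviation = "Pb")
}

#' Elemental mass fractions of a composite
#'
#' Expands the compound weight percents through [parse_formula()] into
#' per-element mass fractions: \eqn{w_e = \sum_c (p_c/100)\, f_{c,e}}.
#'
#' @param x A [composite()] object.
#' @return Tibble with columns `element`, `fraction` (summing to one).
#' @examples
#' elemental_fractions(registry_composite("Pb-PVC"))
#' @export
elemental_fractions <- function(x) {
  stopifnot(inherits(x, "composite"))
  parts <- purrr::imap(x$components, function(pct, f) {
    parse_formula(f) %>% mutate(fraction = .data$fraction * pct / 100)
  })
  bind_rows(parts) %>%
    group_by(.data$element) %>%
    summarise(fraction = sum(.data$fraction), .groups = "drop") %>%
    arrange(.data$element)
}

#' Mass attenuation coefficient of a material (mixture rule)
#'
#' For composites, applies the mixture rule
#' \eqn{(\mu/\rho)_{mix} = \sum_e w_e (\mu/\rho)_e} over the elemental mass
#' fractions; toy materials return their own coefficient.
#'
#' @param material A [composite()] or [toy_material()].
#' @param energy Photon energy in keV (vectorised), 1-150 keV.
#' @param component Interaction component, as in [mu_rho()].
#' @return Mass attenuation coefficient(s) in cm^2/g.
#' @export
material_mu_rho <- function(material, energy, component = "total") {
  UseMethod("material_mu_rho")
}

#' @export
material_mu_rho.composite <- function(material, energy, component = "total") {
  fr <- .composite_fractions_cached(material)
  out <- 0
  for (i in seq_len(nrow(fr))) {
    out <- out + fr$fraction[i] * mu_rho(fr$element[i], energy, component)
  }
  out
}

# memoise elemental fractions on the composite object environment-free way
.composite_fractions_cached <- function(material) {
  if (!is.null(material$.fractions)) return(material$.fractions)
  elemental_fractions(material)
}

#' @rdname material_mu_rho
#' @export
composite_mu_rho <- function(material, energy, component = "total") {
  material_mu_rho(material, energy, component)
}

#' Linear attenuation coefficient of a material
#'
#' @inheritParams material_mu_rho
#' @return Linear attenuation coefficient(s) in 1/cm
#'   (density times [material_mu_rho()]).
#' @export
linear_mu <- function(material, energy, component = "total") {
  material$density * material_mu_rho(material, energy, component)
}

#' Export the registry in tabular form
#'
#' One row per composite with compound weight-percent columns, mirroring the
#' registry definition.
#'
#' @param registry Registry tibble, defaults to [load_registry()].
#' @return A plain tibble (no list columns), writable with `write.csv()`.
#' @export
registry_table <- function(registry = load_registry()) {
  rows <- purrr::map(registry$composite, function(comp) {
    w <- as.list(comp$components)
    tibble(name = comp$name, abbreviation = comp$abbreviation,
           !!!w, density_g_cm3 = comp$density)
  })
  bind_rows(rows) %>%
    mutate(across(-c("name", "abbreviation", "density_g_cm3"),
                  ~ ifelse(is.na(.x), 0, .x)))
}
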