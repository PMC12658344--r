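# Vendored elemental photon-interaction coefficient tables and the air mass
# energy-absorption table, with the K-edge-aware log-log interpolation rule
# shared by every consumer.

# Supported element inventory.  Atomic masses are IUPAC standard values; the
# K edges listed here mirror the vendored fixture headers (edges below 1 keV
# are outside the tabulated range and recorded as NA).
.ELEMENT_INFO <- tibble::tribble(
  ~symbol, ~Z, ~atomic_mass, ~k_edge,
  "H",      1,   1.008,  NA,
  "C",      6,  12.011,  NA,
  "N",      7,  14.007,  NA,
  "O",      8,  15.999,  NA,
  "Al",    13,  26.982,  NA,
  "S",     16,  32.06,   2.472,
  "Cl",    17,  35.45,   2.822,
  "Ar",    18,  39.948,  3.206,
  "Sn",    50, 118.71,  29.200,
  "Sb",    51, 121.76,  30.491,
  "Ba",    56, 137.327, 37.441,
  "Gd",    64, 157.25,  50.239,
  "W",     74, 183.84,  69.525,
  "Pb",    82, 207.2,   88.005,
  "Bi",    83, 208.980, 90.526
)

.XS_COMPONENTS <- c("photoelectric", "incoherent", "coherent", "total")
.E_MIN <- 1
.E_MAX <- 150

.xs_cache <- new.env(parent = emptyenv())

#' Supported element symbols
#'
#' Elements for which a vendored photon-interaction coefficient table is
#' shipped with the package: the composite constituents of the shielding
#' registry (H, C, Cl from PVC; S, O from the oxide/sulfate fillers; Sn, Sb,
#' Ba, Gd, W, Pb, Bi), the air constituents (N, O, Ar, C) and aluminium
#' (beam filtration).
#'
#' @return Character vector of element symbols.
#' @export
supported_elements <- function() .ELEMENT_INFO$symbol

#' Load a vendored elemental coefficient table
#'
#' Reads the per-element CSV fixture of photon mass interaction coefficients
#' (cm^2/g) on a 1-150 keV grid.  Grid energies are strictly ascending except
#' for exact duplicates at absorption edges, where the first row carries the
#' below-edge value and the second the above-edge value.  Tables are cached
#' after the first read.
#'
#' @param symbol Element symbol, one of [supported_elements()].
#' @return A tibble with columns `energy_keV`, `photoelectric`, `incoherent`,
#'   `coherent`, `total` and attributes `symbol`, `Z`, `atomic_mass`,
#'   `k_edge` (keV, `NA` when the K edge lies below the tabulated range).
#' @examples
#' pb <- load_element_table("Pb")
#' attr(pb, "k_edge")
#' @export
load_element_table <- function(symbol) {
  stopifnot(is.character(symbol), length(symbol) == 1)
  if (!symbol %in% .ELEMENT_INFO$symbol) {
    abort(sprintf("unsupported element '%s'; see supported_elements()", symbol),
          class = "leadequiv_unsupported_element")
  }
  if (!is.null(.xs_cache[[symbol]])) return(.xs_cache[[symbol]])
  path <- system.file("extdata", "xs", paste0(symbol, ".csv"),
                      package = "leadequiv", mustWork = TRUE)
  tab <- as_tibble(read.csv(path, comment.char = "#"))
  info <- .ELEMENT_INFO[.ELEMENT_INFO$symbol == symbol, ]
  attr(tab, "symbol") <- symbol
  attr(tab, "Z") <- info$Z
  attr(tab, "atomic_mass") <- info$atomic_mass
  attr(tab, "k_edge") <- info$k_edge
  class(tab) <- c("element_table", class(tab))
  .xs_cache[[symbol]] <- tab
  tab
}

#' Load the air mass energy-absorption table
#'
#' Mass energy-absorption coefficient of dry air (cm^2/g), used as the
#' air-kerma weighting factor for transmitted spectra.
#'
#' @return Tibble with columns `energy_keV`, `muen_over_rho`.
#' @export
load_air_table <- function() {
  if (!is.null(.xs_cache[["__air__"]])) return(.xs_cache[["__air__"]])
  path <- system.file("extdata", "air_muen.csv", package = "leadequiv",
                      mustWork = TRUE)
  tab <- as_tibble(read.csv(path, comment.char = "#"))
  .xs_cache[["__air__"]] <- tab
  tab
}

# Log-log linear interpolation on a grid that may contain duplicated edge
# energies (below-edge row first).  At an exact duplicated energy the
# above-edge value is returned; exact non-edge grid energies return the
# tabulated value.
.loglog_lookup <- function(e_grid, v_grid, energy) {
  i <- findInterval(energy, e_grid)
  # findInterval returns the last index with e_grid[i] <= x, which at a
  # duplicated edge energy is the above-edge row
  i[i >= length(e_grid)] <- length(e_grid) - 1L
  e_lo <- e_grid[i]; e_hi <- e_grid[i + 1L]
  exact <- energy == e_lo
  w <- ifelse(exact, 0, log(energy / e_lo) / log(e_hi / e_lo))
  exp((1 - w) * log(v_grid[i]) + w * log(v_grid[i + 1L]))
}

.check_energy_range <- function(energy) {
  if (any(!is.finite(energy)) || any(energy < .E_MIN) || any(energy > .E_MAX)) {
    abort(sprintf("energy outside the tabulated range [%g, %g] keV",
                  .E_MIN, .E_MAX),
          class = "leadequiv_energy_range")
  }
}

#' Interpolate an elemental mass interaction coefficient
#'
#' Log-log linear interpolation of a vendored element table.  At an exact
#' absorption-edge energy the above-edge value is returned; exact grid
#' energies reproduce the tabulated value; no extrapolation outside
#' 1-150 keV.
#'
#' @param table An element table from [load_element_table()] (or an element
#'   symbol, which is loaded for convenience).
#' @param energy Photon energy in keV (vectorised).
#' @param component One of `"total"` (default), `"photoelectric"`,
#'   `"incoherent"`, `"coherent"`.
#' @return Mass interaction coefficient(s) in cm^2/g.
#' @examples
#' mu_rho(load_element_table("Pb"), 100)
#' @export
mu_rho <- function(table, energy, component = "total") {
  if (is.character(table)) table <- load_element_table(table)
  component <- arg_match0(component, .XS_COMPONENTS)
  .check_energy_range(energy)
  if (component == "total") {
    # the total is the sum of the interpolated partial coefficients, so that
    # component additivity holds exactly off-grid as well as on it (the
    # tabulated total column is the exact sum at every grid point)
    return(.loglog_lookup(table$energy_keV, table$photoelectric, energy) +
             .loglog_lookup(table$energy_keV, table$incoherent, energy) +
             .loglog_lookup(table$energy_keV, table$coherent, energy))
  }
  .loglog_lookup(table$energy_keV, table[[component]], energy)
}

#' Air mass energy-absorption coefficient
#'
#' @param energy Photon energy in keV (vectorised), 1-150 keV.
#' @return \eqn{(\mu_{en}/\rho)_{air}} in cm^2/g.
#' @export
air_muen_rho <- function(energy) {
  .check_energy_range(energy)
  tab <- load_air_table()
  .loglog_lookup(tab$energy_keV, tab$muen_over_rho, energy)
}
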