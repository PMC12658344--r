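---
title: "Methods: lead equivalence of flexible lead-free shielding composites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lead equivalence of flexible lead-free shielding composites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leadequiv)
```

## The problem

Protective aprons for diagnostic radiology are specified by *lead
equivalence*: a shield is "0.5 mm Pb" if it transmits the same beam quantity
as 0.5 mm of pure lead under a stated spectrum.  Because lead is dense and
toxic, composite shields replace it with high-Z fillers (W, Sn, Bi2O3,
BaSO4, Sb2O3, Gd2O3) in a flexible polymer matrix.  The ergonomic figure of
merit is the *areal mass* (kg/m^2) at a given protection level: density
times equivalent thickness.  This package computes, for a registry of 18
filler/polymer composites (78 wt% filler, 22 wt% PVC, with modelled bulk
densities), the thickness equivalent to 0.35 and 0.5 mm Pb at 80, 100 and
120 kVp, and ranks the composites by areal mass.

The multi-element design rationale is the K edge: each filler's
photoelectric cross section jumps at its K-shell binding energy (Sn
29.2 keV, Sb 30.5, Ba 37.4, Gd 50.2, W 69.5 keV), so mixtures can cover
each other's transmission windows across a polyenergetic spectrum.

## Physics tables

All attenuation physics flows from vendored per-element tables of mass
interaction coefficients (photoelectric, incoherent, coherent, total;
cm^2/g) on a 1-150 keV grid with duplicated rows at absorption edges.
Interpolation is log-log linear — the standard convention for photon
cross sections — with the above-edge value returned at an exact edge
energy, and the total evaluated as the sum of the interpolated components
so that additivity is exact off-grid.  No extrapolation outside 1-150 keV
is permitted.

The tables are an approximate reconstruction of the standard dosimetry
tabulations, generated once by `data-raw/make_physics_tables.R`:

* **incoherent**: exact integrated Klein-Nishina cross section per
  electron, times Z/A, suppressed at low energy by an empirical
  incoherent-scattering-function factor calibrated against tabulated
  high-Z values;
* **coherent**: Thomson scattering integrated numerically over a
  Thomas-Fermi-screened atomic form factor, with the screening scale
  calibrated at two benchmark points (Pb at 100 keV, C at 30 keV);
* **photoelectric**: anchored to trusted standard-grid attenuation values
  for O, Al, W and Pb (plus Sn at 100 keV), with per-shell power laws
  (exponent 2.72 above the K edge, 2.67 in the L region), K-edge jump-ratio
  systematics J(Z) = 4.63 + 0.034(74 − Z), and log-Z interpolation of the
  just-above-K cross section for Sn, Sb, Ba, Gd and Bi.  Low-Z elements are
  log-Z power-law interpolations between the O and Al anchors.

The anchored values reproduce the standard tabulation exactly at the anchor
energies; between anchors and for the interpolated elements the expected
accuracy is a few percent in the 20-150 keV band that controls the results.
M-edge fine structure (below ~4 keV for W/Pb/Bi, where any practical slab
is opaque) is smoothed over.  This accuracy envelope is the dominant
systematic of the whole pipeline and should be kept in mind wherever two
composites differ by only 1-2% in areal mass.

## Spectra

The beam model is a tungsten-anode bremsstrahlung continuum of Kramers form
(E0 − E)/E, attenuated by target self-filtration (mean exit path shrinking
linearly with photon energy, scaled by the anode angle) and by the added
aluminium filtration, plus the four W K characteristic lines (Kα1 59.3,
Kα2 58.0, Kβ1 67.2, Kβ2 69.1 keV) when the potential exceeds the W K edge,
with a line yield growing as (E0/EK − 1)^1.67.  Unstated tube parameters
are fixed at typical diagnostic values — anode angle 12°, total filtration
2.5 mm Al, 0.5 keV bins — and are configurable; no attempt is made to infer
any particular machine's exact tube model, and the reproduction tolerances
of the headline table absorb this freedom.

The pipeline's default inputs are the vendored reference spectra
(`spectrum_ref_080/100/120.csv`).  These are *synthetic references*
produced once by the same spectrum model with sub-bin integration
(`data-raw/make_reference_spectra.R`); an independent published spectrum
model was not available offline when they were frozen.  Consequently the
`spectrum_similarity()` check of generator vs reference (normalised RMSE,
peak offset, mean-energy difference) is a regression test of the generator
and rebinning plumbing, not a cross-model validation — a deliberate,
documented limitation.  All consumers are invariant to rescaling the
fluence; spectra never need normalising.

## Transmission engines

The default engine is deterministic narrow-beam: for thickness t,

T(t) = Σ w(E) q(E) exp(−μ(E) t) / Σ w(E) q(E),

with q = 1 for fluence weighting and q = E·(μen/ρ)air for air-kerma
weighting, and μ the mixture-rule linear attenuation coefficient
μ = ρ Σe we (μ/ρ)e.  Lead equivalence is a ratio quantity — composite
curve against lead reference under the *same* engine and weighting — so it
is insensitive to scatter build-up to first order; the deterministic engine
is therefore the default for the tabulation, and the weighting choice
defaults to fluence (transmitted-beam intensity).  Both weightings are
implemented and logged; the kerma-weighted results differ by well under the
reproduction tolerance.

The analog Monte Carlo broad-beam engine bounds the geometry sensitivity:
point source, 100 cm to the slab, directions sampled in the cone subtending
a 10 cm shield half-width, a 5 cm detector disc 10 cm behind the slab
(dimensions configurable; only the 100 cm distance is prescribed, the rest
are documented defaults).  Interactions are sampled analogically:
photoelectric absorption, Compton scattering with exact Klein-Nishina
sampling (Kahn's method), and optional coherent scattering with a
form-factor-free Thomson angular law (an approximation that overstates
large-angle coherent deflection; coherent scattering is a few percent of
the total here).  There is no electron transport — the energy tally is an
air-kerma weighting of photons reaching the detector, adequate below
150 keV.  The slab is laterally unbounded (side leakage is negligible for
millimetre slabs and a 10 cm half-width).  Runs are vectorised over
histories and bit-reproducible for a fixed seed; the default 10^6 histories
per point gives a relative standard error of roughly 1% at T ≈ 0.02 and
runs in about two seconds per point on one CPU — a desk-scale substitute
for production-scale history counts, and the history count is a knob.
Broad-beam equivalent thicknesses agree with the deterministic ones to
about 1% (checked in the test suite at 10^6 histories per point).

## Curve fitting and intersection

Each composite's transmission is computed on the 8-point grid 0.1, 0.2,
0.5, 1, 1.5, 2, 2.5, 3 mm.  The default continuous model is a monotone
cubic interpolant of log-transmission (Hyman-filtered spline): a
polyenergetic curve is *not* a single exponential (beam hardening makes
log T convex in t), and an interpolant is exact at the knots.  Classical
exponential-decay fitting is available as an audited option: `exp1` and
`exp2` fit one- and two-component exponentials by least squares on log T,
with residuals reported and a 3-sigma consistency flag against Monte Carlo
error bars.  Noisy curves whose inversions exceed 3 sigma per point are
rejected rather than fitted.

The equivalent thickness solves f(t) = T_Pb by bracketed root-finding
(tolerance 1e-12 mm) on the fitted range [0.1, 3] mm; the 3 mm maximum
comfortably exceeds every tabulated equivalent thickness (max ≈ 2.8 mm),
and extrapolation outside the curve is refused with an explicit error.
Intersecting the fitted interpolant or log-linear interpolation between the
raw points differ by under 0.02 mm (tested); the fitted route is the
default.  Reported thicknesses are rounded to 2 decimals in the exported
tables (full precision is kept internally); areal mass is density ×
thickness (1 g/cm^3 × 1 mm = 1 kg/m^2).

Engine consistency is a hard contract: a lead reference computed under a
different engine or weighting than the curve raises an error instead of a
silently mixed comparison.

## Synthetic oracles

Every stage is testable without external data:

* `make_monoenergetic()` beams make every transmission exactly exponential,
  so the end-to-end pipeline must match the closed form
  t_eq = μPb tPb / μmat to 1e-6 mm — asserted for all 18 registry
  composites at five energies (30-80 keV, 0.3 mm Pb target chosen so every
  intersection stays inside the curve bracket) and for 20 random toy
  materials;
* `toy_material()` wraps an arbitrary prescribed coefficient as a material;
* `make_noisy_curve()` draws multiplicative lognormal noise (median 1;
  lognormal keeps transmissions positive) around a known multi-exponential,
  with the default 1% noise mirroring a sub-1% simulation uncertainty
  target; the bi-exponential fit must recover the parameters within 5% and
  the intersection within 2% at 0.5% noise.

## Validation scope and limitations

What the passing tests show: the mixture rule, spectrum weighting, curve
fitting and root-finding are exact against closed forms; the Monte Carlo
engine agrees with Beer-Lambert in its primaries-only limit and with the
deterministic engine on equivalent thickness to ~1%; and the full
tabulation reproduces the reference values it targets within ±10% (or 0.20 mm),
with every checked cell inside that band and most within 5%.

What they do not show: absolute dosimetric accuracy.  The reconstructed
cross sections carry few-percent systematics (largest for the Z-interpolated
elements Sn, Sb, Ba, Gd), the tube model is generic, and the reference
spectra are synthetic.  One visible consequence: at 120 kVp and the 0.5 mm
target this pipeline ranks W-Gd2O3-PVC lighter than W-Sn-Gd2O3-PVC by about
2% in areal mass, while the reference tabulation orders them the other way by a
similarly thin margin — sub-2% ordinal gaps between near-tied composites
are below the resolution of an independent reimplementation.  Rankings
separated by more than ~5% in mass are stable.

Problem sizes used throughout (chosen as comfortable desk-scale settings):
the full tabulation is 18 × 3 × 2 = 108 deterministic cells (a few
seconds); Monte Carlo checks use 10^5-10^6 histories per point.

## Reproducing the study table

```{r, eval = FALSE}
library(leadequiv)
summary <- build_summary()        # 108 cells, deterministic engine
thickness_table(summary)          # equivalent thicknesses (mm)
mass_table(summary)               # areal masses (kg/m^2)
rank_by_mass(summary, 100, 0.5)   # lightest to heaviest at 100 kVp
glance(summary)                   # ranges and mass-increase statistics
autoplot(summary)                 # mass vs thickness scatter
```
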