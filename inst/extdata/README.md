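# Vendored data fixtures

## `xs/<symbol>.csv`

Elemental photon mass interaction coefficients (cm^2/g) on a 1-150 keV grid
(spacing at most 1 keV, absorption-edge energies duplicated: below-edge row
first, above-edge row second).  Columns: `energy_keV`, `photoelectric`,
`incoherent`, `coherent`, `total` (the total is the exact sum of the stored
components).

These tables are an approximate reconstruction of the standard photon
cross-section tabulations used in diagnostic dosimetry, generated once by
`data-raw/make_physics_tables.R` from trusted standard-grid anchor values
plus Klein-Nishina, form-factor and per-shell power-law models; see that
script and the package vignette for the method and its accuracy envelope.
They are physical-constant fixtures: tests never fetch data.

## `air_muen.csv`

Mass energy-absorption coefficient of dry air (cm^2/g) on the standard
dosimetry grid, with the Ar K edge duplicated; used for air-kerma weighting.

## `spectra/spectrum_ref_*.csv`

Synthetic reference tube spectra at 80, 100 and 120 kVp (tungsten anode,
12 degree anode angle, 2.5 mm Al total filtration, 0.5 keV bins), generated
once by `data-raw/make_reference_spectra.R` with the package's own
Kramers-form spectrum model (sub-bin integrated).  They are the default
beam input of the equivalence pipeline.  They are *not* an independent
spectrum measurement or third-party model output; the spectrum-similarity
metrics against them are a regression check of the generator and rebinning
plumbing, not a cross-model validation.
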