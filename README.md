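# vesiquant

Quantification of DNA-programmed phospholipid synthesis inside giant
unilamellar vesicles (GUVs), from two-channel fluorescence microscopy and
from targeted mass-spectrometry peak tables.

Synthetic cells that express the *E. coli* Kennedy-pathway enzymes inside
liposomes make new membrane lipids from soluble precursors. Verifying that
requires two measurements this package implements end to end:

* **Single-vesicle imaging.** Detect liposome lumina in the membrane-dye
  channel by threshold + border flood fill (enclosed dark regions are
  lumina), filter by area and a stringent circularity criterion
  (4πA/P² ≥ 0.85), then measure the reporter (e.g. LactC2-eGFP, a
  PS-specific probe) *at the membrane* as the mean over 63 radial rays of
  the per-ray maximum intensity. Vesicles are called lipid-enriched when
  their intensity exceeds the negative-control mean + 2 SD; per-liposome
  time courses are fitted with a 4-parameter logistic
  `I(t) = b + A/(1 + exp(-k(t - t0)))`, reporting the maximum rate `A k / 4`
  (a.u./min) and the plateau time `t0 + ln(19)/k` (time to 95% of the
  amplitude). Apparent radii are perimeter/2π under a perfect-circle
  assumption; radius changes are histogrammed in 0.25-µm bins.
* **Targeted MS.** Duplicate injections are averaged; integrated counts are
  converted to µM through a linear calibration pooled over the pre- and
  post-acquisition dilution series; heavy 13C-G3P labelling shifts de novo
  lipids by +3 Da (one G3P moiety: PA/PE/PS/CDP-DAG/LPA) or +6 Da (PG/PGP,
  two G3P moieties). Acyl-chain composition (DP/PO/DO) is compared with the
  random-incorporation null {p², 2p(1−p), (1−p)²}, and acyl-CoA conversion
  yield is `100 Σ cᵢ nᵢ / c(acyl-CoA)` with `nᵢ` the chains per product.

Because the raw experimental images and MS runs are not available at desk
scale, every stage is paired with a seeded synthetic generator
(ring-structured two-channel images, sigmoid kinetic cohorts, linear MS peak
tables — all with ground-truth tables), so the full analysis is testable and
reproducible offline.

## Worked example

```r
library(vesiquant)

# a synthetic field of 12 vesicles with ground truth
img <- generate_vesicle_image(image_spec(n_vesicles = 12L, height_px = 400L,
                                         width_px = 400L, seed = 42))
det <- detect_lumina(img$membrane, segmentation_params())
head(det[, c("id", "radius_px", "apparent_radius_um", "circularity")], 3)
#>   id radius_px apparent_radius_um circularity
#> 1  1  13.68087           2.788330   0.9629395
#> 2  2  22.01786           4.606284   0.9139209
#> 3  3  26.21509           5.483430   0.9142357

prof <- profile_detections(img$reporter, det)   # 63-ray membrane intensity

# enrichment against a 0%-enriched negative-control field
ctrl <- generate_vesicle_image(image_spec(n_vesicles = 12L, height_px = 400L,
                                          width_px = 400L,
                                          reporter_enriched_fraction = 0,
                                          seed = 43))
cprof <- profile_detections(ctrl$reporter, detect_lumina(ctrl$membrane))
thr <- enrichment_threshold(cprof$mean_membrane_intensity)  # mean + 2 SD
classify_enriched(prof$mean_membrane_intensity, thr)
#> <enrichment_result> 5 / 12 vesicles enriched (41.7%) at threshold 213.7 a.u.

# single-liposome kinetics
t <- seq(0, 960, 10)
set.seed(1)
fit <- fit_sigmoid(t, logistic4(t, 100, 400, 0.02, 180) + rnorm(length(t), 0, 10))
fit
#> <sigmoid_fit> baseline 97.82, amplitude 403.9 a.u., k 0.01933 /min, t0 178.9 min
#>   max rate 1.952 a.u./min, plateau 5.52 h, residual RMS 8.87, responder: TRUE

# MS stoichiometry
conversion_yield(c(DOPE = 12, DOPG = 8), precursor_acyl_coa_uM = 100)
#> [1] 40
chain_composition_fractions(c(POPE = 8, DOPE = 1, DPPE = 1))$null_percent
#> DP PO DO
#> 25 50 25
isotope_mass_shift("DOPG")   # PG carries two G3P moieties
#> [1] 6
```

Twelve of twelve generated vesicles are detected; the enrichment call (5/12
above threshold) reflects the configured 50% enriched fraction plus the
lognormal intensity spread straddling the control threshold. The logistic
fit recovers the simulated parameters (rate 1.95 vs true 2.0 a.u./min)
despite 2.5% noise.

The end-to-end driver runs every stage from one seeded config and is
byte-deterministic in its CSV outputs:

```r
run_pipeline(demo_config(seed = 1), "out/")
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/vesiquant.R`
(`Rscript vesiquant.R {synth|segment|profile|enrich|kinetics|msquant|run} ...`).

## Package layout

| Area | Functions |
|---|---|
| synthetic data | `image_spec`/`generate_vesicle_image`, `trace_spec`/`generate_kinetic_traces`, `ms_spec`/`generate_ms_tables` |
| segmentation | `detect_lumina`, `apparent_radius`, `circularity_filter`, `segmentation_params` |
| membrane profiling | `radial_membrane_intensity`, `profile_detections`, `extract_line_profile`, `two_peak_membrane_intensity` |
| enrichment statistics | `enrichment_threshold`, `classify_enriched`, `coefficient_of_variation`, `welch_test`, `box_stats`, `pearson_correlation`, `pearson_repeats` |
| kinetics | `fit_sigmoid` (+ `coef`/`predict`/`plot` methods), `fit_sigmoid_cohort`, `radius_change`, `link_timepoints` |
| MS quantification | `average_injections`, `fit_calibration`, `counts_to_concentration`, `quantify_ms_run`, `normalize_to_reference_peptide`, `isotope_mass_shift`, `chain_composition_fractions`, `conversion_yield`, `lipid_species` |
| IO / pipeline | `read_image`/`write_image`, `read_table`/`write_table`, `run_config`, `run_pipeline`, `demo_config` |

The methods vignette (`vignettes/vesiquant-methods.Rmd`) documents the
models, the numerical choices (interpolation, thresholds, tie-breaks), what
the synthetic generators do and do not emulate, and known limitations.
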