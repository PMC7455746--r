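---
title: "Quantifying in-liposome phospholipid synthesis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying in-liposome phospholipid synthesis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiquant)
```

# The measurement problem

Cell-free gene expression inside giant unilamellar vesicles (GUVs) can drive
synthesis of membrane phospholipids from soluble precursors
(glycerol-3-phosphate, acyl-CoA) via expressed enzymes of the *E. coli*
Kennedy pathway. Two complementary readouts quantify this:

* **Single-vesicle fluorescence.** An equatorial confocal section shows each
  GUV as a ring in a membrane-dye channel; a lipid-binding fluorescent
  reporter (e.g. a PS-specific lactadherin-C2 fusion) accumulates at the
  membrane of vesicles that synthesized the target lipid. The quantity of
  interest is the reporter intensity *at the membrane*, per vesicle, over
  thousands of vesicles, and over time.
* **Targeted mass spectrometry.** Integrated MRM peak counts for each lipid
  species, converted to absolute concentrations through a linear calibration
  from a dilution series of standards, with heavy-isotope labelling
  (13C-G3P) distinguishing de novo lipids from the pre-existing membrane.

Neither readout has public raw data at desk scale, so the package pairs every
analysis stage with a synthetic generator that produces ground-truth-annotated
inputs with the statistical structure the analysis assumes. All testing and
the worked examples run on those generators.

# Image model and segmentation

## Ring model

A vesicle's equatorial section is modelled as a radial Gaussian ring,
$I(d) = A\,e^{-(d-r)^2/2\sigma^2}$, with $d$ the distance from the center:
the profile of a thin bilayer convolved with the point-spread function. The
generator defaults are a 0.2 µm pixel, radii 2–6 µm (apparent diameters
4–12 µm, the range over which kinetic parameters were examined
experimentally), ring width $\sigma$ = 0.3 µm, and a membrane peak of 3000
a.u. on a 16-bit scale. Per-vesicle reporter ring amplitudes for "enriched"
vesicles are lognormal (meanlog log 800, sdlog 0.8): single-vesicle intensity
distributions of heterogeneous synthesizing populations are wide with a long
right tail. Non-enriched vesicles carry a ring at the reporter background
level, emulating residual non-specific probe signal. Optional Poisson shot
noise, Gaussian read noise and Gaussian PSF blur complete the camera model;
no further optics (vendor PSFs, depth effects, multilamellarity) are
simulated. Vesicle centers are snapped to pixel centers — sub-pixel placement
is irrelevant at the noise levels studied and keeps noise-free fixtures
exactly computable.

Because real fields in this preparation contain well-separated, fully visible
vesicles (and the analysis only handles those), the generator enforces
non-overlap (ring separation at least 6 σ) and a border margin of radius +
3 σ. Passing tests therefore demonstrate correctness for isolated rings, not
for touching or cut-off vesicles.

## Flood-fill lumen detection

Segmentation follows the lumen-detection approach: binarize the membrane
channel, flood-fill the below-threshold background inward from the image
border, and keep the remaining enclosed dark regions — the lumina of closed
rings. Choices the procedure leaves open, fixed here:

* **Threshold**: Otsu's method on a 256-bin histogram by default; a fixed
  threshold is available for reproducibility. When the histogram valley is
  empty the Otsu objective plateaus and any maximizer is equivalent; the
  implementation takes the first.
* **Connectivity**: 4-connectivity for the background fill, 8-connectivity
  for lumen labelling. An 8-connected ring of one-pixel width blocks
  4-connected background paths, so a thin ring cannot leak diagonally.
* **Geometry**: area is the pixel count; the perimeter is the chain-code
  length of the Moore-traced outer boundary (1 per axial step, √2 per
  diagonal); circularity is $4\pi A/P^2$. With this perimeter a rasterized
  disc scores ≈ 0.95, a 1×N line ≈ π/N.
* **Filters**: minimum lumen area 50 px; border margin 2 px; circularity
  cutoff 0.85. The stringent circularity criterion discards deformed or
  misdetected objects; 0.85 is a configuration default, not a measured
  constant. Nested lumina (multilamellar appearance) keep only the outermost
  region, since unilamellarity cannot be decided from one channel.
* **Radii**: for ray extents the equivalent-area radius $\sqrt{A/\pi}$ is
  used (less noise-sensitive); the *apparent radius* reported for size and
  growth statistics is perimeter/2π under a perfect-circle assumption, which
  for a square lumen of side $s$ gives $2s/\pi$ — the assumption's bias is
  documented and tested rather than hidden. The lumen boundary sits where
  the ring flank crosses the binarization threshold, about
  $\sigma\sqrt{2\ln(A/\tau)}$ inside the ring peak radius, so lumen-derived
  radii underestimate the ring-center radius by roughly 1.2 σ at τ ≈ A/2;
  1-px radius accuracy against ground truth holds for thin rings
  (σ ≤ ~0.7 px), the regime the recovery tests use.

# Membrane intensity by ray profiling

The automated statistic is the mean over 63 equally spaced rays (from the
centroid to 1.5 × radius) of the per-ray maximum intensity — the membrane
intersection. Sampling is at 0.5-px steps. Two numerical choices matter:

* **Interpolation.** Bilinear interpolation systematically truncates a
  smooth ring peak: the bilinear surface lies below a concave function
  between pixel centers, by up to $|f''|/8$ per dimension — measured at
  3–8% of the peak for realistic ring widths (σ 1–1.5 px). The default is
  therefore Catmull-Rom bicubic interpolation with a parabolic refinement
  of each per-ray maximum from its two neighbouring samples; the measured
  error on a σ = 1.5 px ring is under 0.6%. Bilinear sampling remains
  available (`interpolation = "bilinear"`) for comparison with legacy
  analyses.
* **Ray bookkeeping.** Rays with any sample outside the image are dropped
  and the used count reported; padding would bias maxima downward. All rays
  leaving the image is an error.

The per-ray maximum is exactly equivariant to intensity scaling and exactly
additive in a constant background (the parabolic refinement uses only
differences), properties the tests pin. It is also never below the annulus
mean — a max over each membrane window dominates the window mean.

The manual mode extracts a line profile across a vesicle and accepts it only
if it shows exactly two membrane peaks; fewer or more (flat profiles,
adjacent-vesicle crossings) produce a discard verdict carrying the peak
count. Peak calling uses topographic prominence with defaults of 3× a robust
noise SD and a minimum separation of half the vesicle radius, both explicit
configuration since the original procedure names none.

# Enrichment statistics

The classification threshold is the negative-control mean plus two sample
standard deviations (n − 1); a vesicle is enriched when its intensity is
*strictly greater*. Under a Gaussian null this passes
$P(X > \mu + 2\sigma) \approx 2.28\%$ false positives, which the tests
verify by Monte Carlo at $n = 10^5$. The threshold rule is affine-equivariant,
so classification is invariant to detector gain and offset. Sample SD with
n − 1 and type-7 (linear-interpolation) quartiles are used throughout; both
are conventions the source procedure leaves unstated. Welch's unequal-variance
t-test (via `stats::t.test`, cross-checked against a permutation oracle) and
box statistics with 1.5-IQR whiskers complete the reported population
summaries; correlations over independent repeats are computed per repeat and
summarised as mean ± SD.

# Single-liposome kinetics

Reporter recruitment traces are fitted with a four-parameter logistic
$I(t) = b + A/(1 + e^{-k(t-t_0)})$ — the exact functional form behind the
published sigmoid fits is not public, so this package's definitions are
explicit substitutes and the published plateau/rate values are not treated
as reference numbers. Derived quantities:

* **rate** = maximum slope of the fit, $Ak/4$, in a.u. per minute;
* **plateau time** = earliest time the fit reaches 95% of its amplitude,
  $t_0 + \ln(19)/k$, reported in hours;
* **responder** = converged and $A > 3 \times$ residual RMS.

Fitting uses Levenberg–Marquardt (minpack.lm) from 8 deterministic starts
(4 steepness values × 2 midpoints), keeping the lowest residual sum of
squares; non-convergence of all starts is a reported state, not an error.
Time-unit and intensity-affine equivariances are exact and tested.

The trace generator emulates a 16-h acquisition with 10-min sampling:
amplitudes lognormal around 400 a.u., steepness lognormal around 0.09 /min
and midpoints normal around 240 min, chosen so maximum slopes are of order
10 a.u./min and plateaus fall around 4–5 h — the experimentally observed
regime. The 10-min interval resolves the ~45-min rise of a typical trace
(≈ 5 samples across the rise), the minimal design under which steepness is
identifiable; parameter-recovery tests use a 50-trace cohort at 5% noise.
Radius-change distributions are reported in 0.25-µm bins centered on zero,
probability-normalised. Time-lapse identity linking is mutual-nearest-centroid
matching with a shift cap, appropriate for immobilized vesicles only.

# Targeted-MS quantification

Peak tables (sample, transition, injection, counts, block) are averaged over
replicate injections, calibrated by ordinary least squares of counts on
standard concentration — pooling the pre- and post-acquisition dilution
series into one fit, with the intercept retained — and inverted to
concentrations, clamping negative back-calculations to zero with a flag.
Pooling is the simplest defensible treatment of bracketing standards absent
evidence of drift; per-block interpolation is deliberately not implemented.
An optional blank subtraction (for the naturally occurring heavy-isotope
background) is exposed as data preparation, not applied by default.

Isotope bookkeeping counts 3 heavy carbons per uniformly 13C-labelled G3P
moiety: +3 Da nominal for single-G3P lipids (PA, PE, PS, CDP-DAG, LPA),
+6 Da for PG and PGP, whose headgroup glycerol is a second G3P-derived
moiety; exact mode uses 1.003355 Da per heavy carbon. Chain-composition
fractions classify diacyl end products as DP (16:0/16:0), DO (18:1/18:1) or
PO (mixed) and compare them with the random-incorporation null
$\{p^2,\,2p(1-p),\,(1-p)^2\}$ for a 16:0 precursor fraction $p$ — 50% mixed
at equimolar precursors. Conversion yield counts chains:
$100 \sum_i c_i n_i / c_{\text{acyl-CoA}}$, giving 40% for 20 µM diacyl
products from 100 µM acyl-CoA.

The MS generator produces counts linear in concentration with unit-mean
lognormal noise of configurable CV (5% default), duplicate injections, and
the calibration series emitted as bracketing pre/post blocks. It does not
simulate chromatographic drift, carry-over, matrix effects or detector
saturation — recovery tests certify the calibration arithmetic, not
instrument robustness.

# Determinism and problem sizes

Every generator is a pure function of its spec (seed included) and restores
the caller's RNG state; the pipeline driver derives all stage seeds from one
config seed, and identical configs reproduce all CSV artifacts byte for
byte. The test suite exercises, among others: 100 synthetic vesicles
(radii 10–30 px) for segmentation recovery; brute-force BFS flood-fill
equivalence on 64×64 images; a $10^5$-draw Gaussian null for the threshold
false-positive rate; a 50-trace kinetic cohort at 5% noise; and a
20-species × 5-sample MS run at 0% and 5% CV. These sizes were chosen to
make sampling error small relative to the tolerances being checked while
keeping the full suite fast to run routinely.

# Known limitations

* Segmentation assumes closed, isolated, roughly circular rings in focus;
  there is no deconvolution, 3-D handling, tracking, or multilamellarity
  classification.
* The per-ray-maximum statistic is upward-biased under noise (a maximum of
  noisy samples); with constant read noise the bias is additive and cancels
  in threshold-based classification, but absolute intensities carry it.
* Reporter photophysics (quenching of doubly labelled lipids,
  probe clustering) is not modelled.
* The logistic family is an assumption; traces with non-sigmoid shapes are
  summarised by their best logistic fit and flagged only through residual
  RMS.
* MS quantification starts from vendor-integrated peak counts; raw
  chromatogram processing is out of scope.
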