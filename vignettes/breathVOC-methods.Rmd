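---
title: "Breath-phase-resolved VOC profiling: models, parameters and design choices"
author: "breathVOC maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath-phase-resolved VOC profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Proton-transfer-reaction time-of-flight mass spectrometry (PTR-TOF-MS)
records a full mass spectrum of exhaled air every second while a subject
breathes into the instrument for about a minute. The exhaled volatile
organic compounds (VOCs) of clinical interest are concentrated in the
end-tidal (late-exhalation) fraction of each breath, so the raw recording
must be cut into inhalation–exhalation cycles and only the exhalation-phase
spectra kept before any quantification. `breathVOC` implements that
processing chain and the downstream statistics: per-recording quality
control, a cohort-level aligned feature matrix, chemical annotation of
features, and resampling-consensus feature selection feeding gradient
boosted classifiers for two endpoints — airway-disease diagnosis
(asthma / COPD / control) and bronchodilator responsiveness (BDR).

Because no public patient recordings accompany the method, the package
ships a first-class synthetic-data module whose outputs carry ground truth
for every stage; every quantitative claim in the test suite is made against
that ground truth or against independent oracles (exact-mass arithmetic,
brute-force enumeration, permutation nulls).

# Stage by stage

## Mass recalibration

Every recording is recalibrated against the three PerMaSCal reference ions
at m/z 21.0220, 203.94299 and 330.85. The correction is a quadratic in
$\sqrt{m/z}$ space — the natural space for TOF flight times —

$$\sqrt{m/z_{\mathrm{corr}}} = c_0 + c_1\sqrt{m/z} + c_2\, m/z,$$

fitted exactly through the three (detected centroid, reference) pairs.
Residuals are then measured on centroids re-detected on the corrected axis;
quality control requires the worst absolute residual below 100 ppm.
Centroids are located by the vertex of a parabola through the log
intensities at the apex and its two neighbours (exact for a Gaussian peak),
with an intensity-weighted mean over the above-half-maximum region as the
fallback. On simulated recordings with a 50 ppm linear drift the worst
post-fit residual is far below the 100 ppm gate (the acceptance script
recomputes it).

## Breath-phase segmentation

Extracted ion currents (EICs; intensity summed over a ±0.05 Da window,
configurable) are computed for the water adduct at m/z 37.038 and the three
tracer VOCs — isoprene (m/z 69.07), dimethyl sulfide (63.02) and
1,2-butadiene (55.03). A spectrum is retained as end-tidal iff

* the water-adduct EIC exceeds $2\times10^5$ cps, and
* at least two of the three tracer EICs show a local maximum within ±1
  spectrum.

The cycle count is the number of maximal runs of water-above-threshold
spectra; recordings with fewer than three complete cycles fail QC, as do
recordings whose capnostat (CO₂ sensor) maximum exceeds 3.5 units. The
capnostat is deliberately QC-only — its response lags the water adduct, so
it never participates in phase delineation. Local maxima are strict maxima
over a ±2-spectrum neighbourhood of the Savitzky–Golay-smoothed trace
(window 5, order 2); the first index of a plateau counts, and numerically
flat windows are never peaks. The ±2 neighbourhood is the widest that does
not merge adjacent cycles at a 1 s cadence and a ~4 s breath period.

The printed target masses (37.038 for the water adduct, 55.03 for
1,2-butadiene) are kept as instrument settings even where they differ from
the theoretical exact masses ((H₂O)H₃O⁺ ≈ 37.0284; C₄H₆·H⁺ ≈ 55.054): EIC
targets describe where the instrument integrates, not chemical
identifications, and they are configurable.

## Feature matrix

Selected spectra are averaged (the sum and the mean differ only by a factor
that normalization cancels; the mean is used) and smoothed along m/z with a
Savitzky–Golay filter (window 7 grid points, order 3 — a mild setting that
moves a noise-free Gaussian apex by less than one grid step, as the tests
verify). Peaks are local maxima expanded to their flanking minima, filtered
by an apex floor (100 cps) and relative prominence (0.5), with
intensity-weighted centroids and integrated areas.

Centroids are aligned across samples by single linkage on the pooled sorted
centroid list: a new feature starts wherever the gap between consecutive
centroids exceeds a mass-dependent tolerance interpolated linearly from
±0.015 Da at m/z 42 to ±0.4 Da at m/z 685 (approximately constant relative
resolution; the endpoints are the published working range). Features
detected in more than half of all samples are retained; the consensus m/z
is the median member centroid; missing entries are imputed as 0 (absence =
below detection on a cps scale). The procedure is deterministic and
invariant to sample order.

Each sample is then divided by its internal-standard value — the heavy-water
isotope adduct [D₂O+H₃O]⁺ at m/z 22.0274, present in every breath sample —
making the matrix invariant to global per-sample intensity scaling
(humidity, sensitivity drift). The integrated area is used for the standard
(the apex is available via a switch; the choice is not critical because the
same quantity is used for all features). Before modeling, calibrant-ion
features and all features below m/z 42 are excluded.

## Annotation

Annotations are hypotheses, never confirmations. Neutral masses are
computed as $m/z - 1.00728$ Da (all ions assumed singly protonated; the
electron mass is ignored, a < 8 ppm bias below m/z 80 that is documented
rather than corrected, matching the protonation arithmetic used
throughout). Three generators are provided:

* **Library matching** (±200 ppm) against a small curated table of
  breath-relevant compounds with exact masses computed from atomic masses;
  users can supply their own table.
* **Elemental-composition enumeration** (±5–10 ppm) by bounded depth-first
  search over C, H, N, O, P, S and optionally F, Cl, Na, Br, with a
  plausibility filter: ring-plus-double-bond equivalents non-negative and
  integer, $H + \mathrm{halogens} + \mathrm{Na} \le 2C + 2 + N$, and Na
  only as a substituent on a carbon skeleton. The suite proves equivalence
  with an independent brute-force enumeration on 50 random masses, and
  tolerance nesting (5 ppm results ⊆ 10 ppm results).
* **Isotopologue flagging**: feature B is a first ¹³C isotopologue of A iff
  the mass shift is 1.00336 ± 0.003 Da and the median intensity ratio B/A
  corresponds to a carbon count between 1 and $\lfloor M/12 \rfloor$ at a
  natural ¹³C fraction of 0.0107 per carbon.

## Cohort statistics and BDR labeling

Group comparisons follow a routed decision tree: Shapiro–Wilk per group at
α = 0.05 (the test is prescribed, the α is this package's choice) gates
Welch's t-test / one-way ANOVA versus Mann–Whitney / Kruskal–Wallis;
categorical variables use Pearson's χ² unless any expected cell count is
below 5, in which case Fisher's exact test. Raw p-values are reported (no
multiplicity correction — a deliberate match to how such cohort tables are
reported). The suite checks the routed procedure holds its nominal type-I
error on null simulations.

BDR positivity is ΔFEV₁ or ΔFVC **strictly greater than** 10 % of the
predicted value. The strict comparator follows the methods-level definition
of the rule; a `strict = FALSE` switch provides the ≥ variant that also
appears in the field.

## Selection and modeling

One stratified 70/30 split (endpoint × maneuver) is drawn once and reused
— the held-out samples never enter selection or tuning (a property the
suite enforces by corrupting held-out rows and asserting the selection is
unchanged). On the training samples, each maneuver runs 1000 resampling
iterations: draw two thirds of the samples without replacement (single-class
draws are redrawn), z-score within the subsample (bookkeeping only — trees
are scale-insensitive), fit an XGBoost classifier, record per-feature
importance ("gain" by default; "weight"/"cover" available). Features are
ranked by median importance across iterations (ties toward the lower m/z),
the per-maneuver rankings truncated at the top 30, and the intersection
retained as the consensus. A top-percentile rule (e.g. top 10 %) is
available as an alternative truncation; the fixed top-30 intersection is the
default consensus path, since the two published phrasings of the rule are
not reconciled anywhere.

Consensus features feed a 5-fold stratified CV grid search (depth 2/4,
learning rate 0.1/0.3, 50 rounds — a small grid, since none is published),
refit on the full training set, and evaluated on the untouched test set.
The BDR model uses only asthma and COPD subjects, concatenates consensus
VOCs with clinical covariates (FeNO, blood eosinophils, total IgE,
pre-bronchodilator FEV₁ %predicted), and is evaluated by leave-one-out
cross-validation, aggregating the out-of-sample probabilities before
computing the AUC. All confusion metrics are taken at probability ≥ 0.5 →
positive. Boosting uses the exact greedy split algorithm (midpoint cuts),
which is both deterministic and appropriate at these sample sizes.

# The synthetic-data module

The generator is the package's stand-in for patient recordings and defines
the conditions under which every downstream claim is tested.

**Recordings.** 60 s sessions, one spectrum per second, m/z 10–685 on a
dense grid (0.002 Da), TOF resolving power 2000, 14 breaths/min by default
(the physiological range emulated is 12–16). Exhalation follows a
raised-cosine envelope over half of each cycle — smooth, differentiable,
with a configurable duty cycle; nothing is published about the true
waveform, so it is a modeling choice, not a claim of fidelity. The water
adduct, tracer VOCs and internal standard co-modulate with the envelope;
calibrants are constant; the capnostat tracks the envelope with a 1 s lag.
Peaks are Gaussian on the m/z axis; noise is a Gaussian floor (30 cps SD)
plus an intensity-proportional term ($\mathrm{SD}=\sqrt{I}$) approximating
counting statistics without full Poisson machinery. A linear mass drift
(constant ppm error) can be imposed for calibration exercises. Channel
amplitudes are expressed as integrated EIC values; the defaults put the
water adduct an order of magnitude above the $2\times10^5$ cps threshold at
full exhalation and an order of magnitude below it at baseline.

**Cohorts.** Group sizes default to the study scale (160 asthma, 128 COPD,
254 controls) with BDR-positive rates of 70.1 % (asthma) and 45.5 % (COPD).
Feature intensities are log-normal with a shared per-subject effect (SD
0.6) and maneuver-specific noise (SD 0.8); planted group effects are
expressed in units of the pooled SD and shared between the tidal and forced
matrices. The default informative channels are the reported predictor
masses (49.005, 95.054, 79.054, 53.037, 71.055, 77.059, 83.086, 118.071,
44.991, 132.050) at shifts of 0.8–1 SD — moderate effects chosen to land
discrimination in the published mid-range rather than at saturation.
BDR-positive subjects carry elevated FeNO, eosinophils and IgE and shifted
BDR channels (79.054, 101.039), and their spirometry deltas are drawn to
satisfy the >10 % rule exactly, so the labeling function reproduces the
planted status.

**What passing tests do and do not show.** The simulator provides exact
ground truth, so the suite can prove recoverability (segmentation equals
the planted cycle count without noise; planted channels reach the
consensus; permuted labels yield chance-level AUC) and determinism. It does
not emulate instrument drift across days, overlapping isobars, peak-shape
asymmetry, missing-not-at-random clinical data, or between-site effects —
results on real recordings depend on those, and nothing here quantifies
them.

# Numerical choices and degenerate inputs

* Tie/plateau handling in local maxima: the first index of a plateau is the
  maximum; comparisons use a $10^{-8}$ relative tolerance so smoothing
  round-off cannot spawn peaks.
* Savitzky–Golay smoothing can undershoot; composite spectra are clipped at
  zero to preserve the non-negativity invariant.
* The alignment gap rule evaluates the tolerance at the midpoint of each
  consecutive centroid pair; sorting makes the clustering order-free.
* An internal standard missing or zero in any sample is an error (listing
  the samples), never silently imputed.
* Splits guarantee at least one sample per stratum on each side; singleton
  strata are errors. Probability ties at the threshold are called positive.
* Empty consensus intersections warn and return an empty set — the caller
  decides whether to proceed.
* Recording bundles store spectra as little-endian float64 with text
  vectors for the axes, so round trips are bit-exact; the layout mirrors
  the hierarchical container (spectra / mz_axis / aux/capnostat / meta)
  used by the instrument ecosystem.

# Problem sizes in the shipped checks

The test suite and acceptance script run on deliberately desk-scale
instances chosen by this package: segmentation checks use 20 simulated
one-minute recordings over an m/z 10–80 window (which contains every
channel the segmentation rule touches); calibration checks use a noise-free
m/z 10–340 window covering the PerMaSCal ions; selection checks use
cohorts of 40–50 subjects per group with 40–200 features and 40–200
resampling iterations; the consensus-plumbing check uses the full top-30
truncation on a ~200-feature matrix. The statistical acceptance bands
(permutation-null AUC within [0.45, 0.55]; planted-channel recovery in at
least 18 of 20 seeds) are properties of the method, evaluated at those
sizes.

# Known limitations

* Annotation stops at hypotheses; no MS/MS acquisition or fragmentation
  prediction.
* No isotope deconvolution of overlapping peaks and no cross-day drift
  correction.
* The diagnosis models are binary contrasts (one group versus control);
  the three-class problem is handled as separate contrasts.
* Propensity-score matching and adjusted regressions are out of scope.
* The published headline AUCs were obtained on patient data that is not
  distributed; nothing in this package claims to reproduce them, and the
  synthetic cohort is not calibrated to do so.
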