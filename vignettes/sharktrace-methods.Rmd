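---
title: "From ablation signals to gestation movements: the sharktrace methods"
author: "sharktrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ablation signals to gestation movements: the sharktrace methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharktrace)
```

## The scientific problem

Elasmobranch vertebrae grow by accretion and take up trace elements from the
blood, which in turn reflects the water the animal swims in. Two consequences
are exploited here. First, embryos are nourished through the maternal
bloodstream, so all vertebrae formed *in utero* — the region between the
vertebral **focus** (conception) and the **birthmark** — record the mother's
chemical environment: embryos of one litter should carry a common,
litter-specific multi-elemental "tag", and that tag should match the edge
(most recent) material of their mother. Second, the Sr:Ba signal ratio acts
as a salinity proxy (low nearshore, high offshore), so the *in utero* Sr:Ba
profile of a young-of-the-year (YOY) shark read from focus to birthmark is a
time series of its pregnant mother's movements across the nearshore–offshore
gradient, with Pb:Ca as a corroborating indicator of contaminated coastal
habitat use.

`sharktrace` implements the full chain that turns raw laser-ablation
ICP-MS (LA-ICP-MS) ion-count signals from vertebral sections into
(1) calibrated element:Ca spot signatures and the distance-based statistics
that test the maternal-tag hypotheses, and (2) smoothed Sr:Ba / Pb:Ca
transect profiles, a rule-based gestation migration-pattern classifier, and
a Fraser–Lee back-calculation of embryo length at the inferred habitat
shift. Because raw instrument data of this kind are rarely shareable, the
package includes a seeded synthetic generator that emulates a complete run
sequence with known ground truth; every stage is tested against that truth.

## Signal reduction

Each ablation record is a time-resolved matrix of counts per second (cps),
one column per monitored isotope mass. The reduction chain, in order:

1. **Signal window.** The published workflow screens signals visually; a
   deterministic stand-in is used here: the window is the longest contiguous
   region where the internal-standard (⁴³Ca) cps exceed the bracketing gas
   blanks' mean + 10 SD, trimmed by 2 s at each end. A record whose internal
   standard never leaves the blank level is flagged a failed ablation and
   excluded. An explicit window from the manifest overrides detection.
2. **Despiking.** The iterative two-sided Grubbs test (α = 0.05, critical
   value from the closed-form t-quantile expression) flags one point at a
   time until none exceeds the critical value; flagged spikes are replaced
   by the mean of the clean points. The procedure is deterministic and
   idempotent. On transects the underlying trend is smooth enough (relative
   to the critical value at several hundred points) that only genuine
   single-point spikes are removed.
3. **Background subtraction.** The mean of the bracketing gas blanks is
   subtracted per mass. Negative net values are kept, not clamped, so
   below-LOD bookkeeping stays unbiased.
4. **Drift correction and external calibration.** NIST-612 glass is ablated
   in replicate pairs before the first and after every fifth vertebral
   section. Sensitivity (cps/ppm) per mass comes from the first pair's mean
   response; the drift factor at any acquisition order is the linear
   interpolation, between the two nearest bracketing standard ablations, of
   each standard's net cps relative to that first-pair mean (constant
   extrapolation outside). Interpolating on acquisition order rather than
   clock time is deliberate: order is always present in a manifest. A
   synthetic linear drift is inverted exactly by this construction.
5. **Internal standardization.** Calibrated ppm are rescaled so that the
   internal standard equals the assumed Ca mass fraction of vertebral
   bioapatite (default 0.399, configurable — the true index of any given
   skeleton is unknown). Element:Ca molar ratios (µmol·mol⁻¹) are formed
   from the calibrated values and atomic masses; they cancel both ablation
   yield and the Ca-fraction assumption, and Ca:Ca ≡ 10⁶ by construction.
6. **Limits of detection.** LOD(ppm) = 3 × SD of the pooled gas-blank cps,
   converted through the drift-corrected sensitivity. An element with
   ≥ 10 % (boundary inclusive) of its measurements below LOD across the
   analysis set is dropped from every signature.
7. **Replicate screening.** Spots are ablated in triplicate; replicates are
   screened by a Stahel–Donoho projection-pursuit outlyingness pooled over
   all replicate scans of the analysis set (n = 3 per spot precludes
   per-spot covariance). Columns are first standardized by median/MAD —
   without this, projections are dominated by high-concentration elements
   and a gross displacement on a trace element goes unseen — and the
   coordinate axes are appended to the K = 1000 seeded random directions so
   single-element displacements have a deterministic detection floor.
   Replicates with outlyingness > 10 are excluded before averaging.

Transects are reduced the same way point-wise; time maps to distance from
the focus at the scan speed (10 µm·s⁻¹), and a manifest field records which
end the scan started from so profiles can be reversed onto a common
focus-at-zero coordinate. For cross-specimen comparison, profiles are
linearly interpolated onto the grid of the longest one. The feature matrix
for multivariate tests concatenates the resampled per-element sequences;
per-element transect means are also produced ("mean integrated" summaries
are ambiguous between the two readings; the full profile is the default
because it preserves the temporal structure the tests are about).

## Distance-based statistics

The maternal-tag hypotheses are tested on Euclidean distance matrices of
the signatures or profile features:

* **PERMANOVA** (one-way): pseudo-F from the partition of the total sum of
  squared interpoint distances, with significance by label permutation.
  The p-value convention is (b + 1)/(B + 1), counting the observed
  statistic, so p is never zero. On Euclidean distances of univariate data
  the pseudo-F equals the classical ANOVA F to machine precision — a
  property the test suite checks on random instances.
* **CAP** (canonical analysis of principal coordinates): principal
  coordinates of the distance matrix (Gower centring; negative eigenvalues
  discarded — Euclidean inputs make them zero anyway), the first *m*
  orthonormal axes retained, and a canonical discriminant analysis of the
  group factor on those axes. The trace statistic is the sum of squared
  canonical correlations, tr(Q′HQ), permutation-tested. Classification is
  assessed by leave-one-out cross-validation: the held-out sample is
  projected into the training ordination by Gower's add-a-point formula and
  assigned to the nearest group centroid in canonical space, ties to the
  lowest group index. `m = "auto"` maximizes LOO accuracy (ties to the
  smallest m), the classical recommendation; *m* can also be fixed by the
  user. G_prop reports the share of positive eigenvalue mass
  captured by the m axes.
* **PCC** (proportional chance criterion): chance accuracy Σ(nᵢ/N)², and an
  exact one-sided binomial tail for the observed correct count. The exact
  binomial was chosen over an unspecified permutation variant because it is
  reproducible and conservative at these sample sizes. For litters of
  4, 3, 3, 4 the chance rate is 50/196 = 25.5 %.

One calibration subtlety: when checking that CAP sits at chance on null
data, *m* must be fixed (the number of groups is used). Selecting *m* by
LOO-accuracy maximization and then reading LOO accuracy is selection on the
measured quantity and biases the null upward.

## Profile classification and back-calculation

Sr:Ba and Pb:Ca are formed as raw cps ratios point-wise along the distance
grid (ratios first, then smoothing — smoothing cps first and dividing after
would mix the two masses' kernels), with nonpositive denominators flagged
missing rather than infinite. An 11-point centred running average smooths
each series; at the edges the window shrinks symmetrically so the output
keeps the input length.

The migration pattern of the mother is called from the smoothed Sr:Ba
profile by thresholds taken from the observed class envelopes:

* **Pattern 2** (nearshore residency): maximum ≤ T_low = 200, the band
  observed for nearshore-resident profiles;
* **Pattern 1** (offshore excursion with nearshore return): maximum ≥
  T_peak = 600 (observed peaks span 600–1200) *and* terminal-segment mean ≤
  T_return = 400 (the nearshore re-entry range is 150–400);
* **undetermined** otherwise. Field practice tends to force a binary call,
  but no principled rule exists for profiles between the two envelopes; an
  explicit third class is more honest than an arbitrary tie-break.

Initial/terminal segments are the first/last 10 % of points ("shortly
prior to birth" is not quantified; 10 % of a gestation-long record is a few
weeks). Pb:Ca corroboration compares the terminal (Pattern 1) or initial
(Pattern 2) segment mean against the mid-gestation (25–75 %) mean. The
habitat-shift radius R_t is the distance of the first point after the
global smoothed maximum that falls below T_return; a Pattern-1 call whose
profile never crosses down is surfaced as an inconsistency. R_t only
involves the Sr/Ba ratio, so it is invariant to any common rescaling of the
two channels.

Embryo length at the shift uses the Fraser–Lee proportional model
L_t = (R_t/R_V)(L_C − a) + a with the published juvenile length–radius
relation L_C = 17.349·R_V + 14.516 supplying the intercept a and, inverted,
the generator's radii. The relation's radius unit is not stated with the
equation; mm is adopted (the convention of the growth literature it derives
from) and exposed as configuration, with transect µm converted at a single
point. The slope/intercept are configuration, not re-fit: the underlying
specimen data are not available.

## What the synthetic generator emulates

`make_study()` renders a complete run in acquisition order: gas blanks
before every ablation and after the last; NIST-612 replicate pairs before
the first and after every fifth vertebral section; MACS-3 bracketing each
slide; triplicate focus and edge spots per embryo; triplicate edge spots
per female; focus→edge transects per embryo and focus→birthmark transects
per YOY. Defaults reproduce the emulated study's design: 4 females with the
recorded lengths 291, 277, 253, 240 cm; litters of 4, 3, 3, 4 embryos
(41–49 cm); 15 YOY (49.2–59.6 cm) over three nursery sites; exactly 11 of
15 YOY mothers on Pattern 1.

The forward model is cps = blank baseline + sensitivity × drift × ppm, with
Gaussian counting noise (SD = √mean), 2 % multiplicative flicker, and
single-point spikes (probability 0.01 per point, factor Uniform(5, 20) —
sized to be Grubbs-detectable). Per-mass drift is linear over the run with
slopes in ±5–8 %. All randomness descends from one root seed through named
per-record substreams, so any record is individually reproducible and the
whole run is byte-stable under a fixed seed.

Study conditions that are modelling choices rather than published numbers:

* **Trajectories.** Pattern 1 is a logistic rise from a nearshore start to
  a peak drawn in 700–1100, then a rapid logistic decline (width ≈ 1 % of
  the gestation) starting at a shift fraction drawn in 0.80–0.88 — slightly
  before term, and early enough that the terminal tenth of the record lies
  after the return, matching the classifier's terminal segment — down to a
  terminal value in 120–340. Pattern 2 is a constant level in 80–160 with
  AR(1) jitter clamped to the 0–200 band. Pb indices mirror the observed
  behaviour: terminal rise for Pattern 1, elevated focus values for
  Pattern 2.
* **Maternal tags.** Litter signatures are lognormal draws around
  bioapatite-plausible element:Ca bases with a between-litter log-SD of
  0.15 (differences of tens of percent). A mother's edge-period environment
  vector *is* her litter's, so tag consistency is exact at truth level.
* **Replicate heterogeneity.** Replicate spots sample slightly different
  material; a 5 % lognormal per-element perturbation per replicate
  reproduces typical replicate RSDs. This matters beyond realism: with
  perfectly identical replicates the pooled outlyingness statistic
  degenerates, and replicate screening would be pointless.
* **Acquisition rate** 5 points/s (not published; exposed as
  configuration), scan speed 10 µm·s⁻¹, 60 s spots, 83 µm spots.
* **Sr:Ba rendering.** The environmental index r is split as
  ppm_Sr ∝ √r and ppm_Ba ∝ 1/√r with scales tied to the sensitivities so
  the raw cps ratio reproduces r; this also yields the observed inverse
  relation between Sr:Ca and Ba:Ca along Pattern-1 transects.

What the generator does *not* emulate: isobaric interferences, matrix
effects beyond a scalar sensitivity, crater geometry, dwell-time/dead-time
effects, or vitellogenesis-period chemistry near the focus. Passing tests
on synthetic data therefore demonstrate that the *processing chain* is
correct and calibrated — exact parameter recovery without noise, < 5 %
relative RMSE with default noise, nominal type-I error, chance-level CAP
under the null, ≥ 90 % pattern recovery — not that real vertebrae satisfy
the model's assumptions.

## Numerical choices and degenerate inputs

* Grubbs on a constant (zero-variance) window: no spikes, series returned
  unchanged; series shorter than 3 points: warning, unchanged.
* Standards with nonpositive net cps on a mass render that mass
  uncalibratable; it is excluded from quantification (NA, flagged).
* Outlyingness: zero-MAD columns and zero-MAD projections are skipped;
  if everything degenerates the statistic is undefined and nothing is
  excluded (with a warning).
* PCoA eigenvalues below 10⁻¹⁰ of the largest are treated as null space.
* LOO ties between equidistant centroids resolve to the lowest group
  index; Grubbs ties to the first index — determinism everywhere.
* Permutation p-values are (b + 1)/(B + 1) and seed-reproducible.
* A transect shorter than 50 points refuses classification (too little
  temporal context for a gestation-scale call).

## Problem sizes used in the packaged checks

The packaged tests and the acceptance script run the default study (33
vertebral sections, ≈ 300 records), 500 null data sets of n = 12 for the
PERMANOVA size check, 200 null data sets for the CAP chance calibration,
200 default-noise transects (plus 30 noiseless ones) for pattern recovery,
and 30+ spot signatures for the noisy recovery bound. These sizes give the
binomial confidence the checks assert while keeping a full run in the
order of a minute on one core.

## Known limitations

* The pooled outlyingness screen assumes the analysis set is broadly
  homogeneous; with very strong between-group structure it can flag whole
  legitimate groups. The cutoff (10) is generous for that reason.
* The pattern classifier is a threshold rule, not a changepoint model; a
  profile with a genuine but shallow excursion (peak between 200 and 600)
  is reported as undetermined rather than forced into a class.
* Back-calculation assumes proportional growth near term; it is not
  intended for early-gestation radii.
* Absolute ppm depend on the assumed Ca mass fraction; element:Ca ratios,
  and everything downstream of them, do not.

## A worked example

```{r example, eval = FALSE}
library(sharktrace)

res <- run_pipeline(pipeline_config(design = study_design(seed = 1),
                                    out_dir = "sharktrace_out"))
res$stats_report              # PERMANOVA / CAP / PCC per hypothesis
res$calls                     # migration-pattern calls per transect
subset(res$backcalc, !is.na(l_t_cm))  # lengths at the habitat shift
```
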