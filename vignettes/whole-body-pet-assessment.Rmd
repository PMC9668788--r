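---
title: "Assessing whole-body PSMA PET lesion segmentations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing whole-body PSMA PET lesion segmentations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmapet)
```

# The problem

In biochemically recurrent prostate cancer, whole-body
[^68^Ga]Ga-PSMA-11 PET/CT is the standard diagnostic tool for localising
metastatic lesions. Automated lesion segmentation promises reproducible
whole-body tumour-burden biomarkers, but any segmenter — deep-learning or
threshold-based — needs a rigorous downstream assessment: does it call the
scan correctly, does it find the individual lesions, how well does it trace
their boundaries, and are the biomarkers it produces prognostic?

`psmapet` implements that downstream assessment, independent of the
segmenter. It takes co-registered PET (SUV or activity concentration) and CT
volumes plus binary or labelled lesion masks, and produces:

1. **patient-level scan classification** — is the scan PSMA-positive?
2. **lesion-level detection** — which ground-truth lesions were found,
   and how many predicted clusters are spurious?
3. **voxel-level segmentation metrics** — Dice similarity coefficient
   (DSC), sensitivity, positive predictive value (PPV), specificity;
4. **whole-body biomarkers** — total lesional volume (TLV, cm^3) and total
   lesional uptake (TLU, unitless SUV sum);
5. **survival stratification** — Kaplan–Meier curves and log-rank tests on
   biomarker splits.

Because clinical whole-body PET datasets cannot be redistributed, the
package ships a synthetic phantom generator that emulates the relevant
structure of such a cohort with exactly known ground truth, so that every
stage of the pipeline is testable end to end.

# Data model and conventions

`VolumeGrid` holds a 3D scalar field (PET SUV~bw~, CT Hounsfield units, or
activity in Bq/mL) with voxel spacing in mm and a world origin; voxel
`(i, j, k)` (0-based) is centred at `origin + (i, j, k) * spacing`.
Orientation is fixed axis-aligned: phantoms never need oblique geometry, and
oblique NIfTI inputs are rejected rather than silently reoriented.
`BinaryMask` and `LabelledMask` share the geometry; labelled masks carry one
integer per lesion plus an anatomical site category (local prostate,
regional nodal, distant nodal, osseous, visceral).

The default grid, 96 × 96 × 256 voxels at 4.07 × 4.07 × 2 mm, matches the
full-resolution reconstruction of a clinical whole-body PSMA protocol; the
voxel volume is `prod(spacing)/1000 = 0.0331298` cm^3.

## SUV conversion

PET consoles usually export SUV directly; when raw activity concentration is
supplied instead, `toSUVbw()` applies the standard body-weight SUV:

$$\mathrm{SUV_{bw}}(v) = \frac{C(v)\; [\mathrm{Bq/mL}] \cdot m\;[\mathrm{g}]}
{A_\mathrm{inj} \cdot 2^{-\Delta t / T_{1/2}}\;[\mathrm{Bq}]}$$

with the injected activity decay-corrected to scan start. The half-life
defaults to 67.71 min (^68^Ga) and is a parameter, as is the delay
$\Delta t$ (protocol target: ~60 min uptake). The decay-correction
convention of a given vendor console is not observable from the images, so
both knobs are explicit rather than hard-coded.

## Resampling

CT volumes are reconstructed on finer, different grids than PET and must be
brought into the PET coordinate space. `resampleToGrid()` uses an
interpolating cubic (Catmull–Rom) spline kernel for intensity volumes — the
concrete reading of "cubic spline interpolation" chosen here because the
spline order is conventionally unstated in clinical pipelines and cubic is
the ubiquitous default. The kernel is exact on linear fields, including at
the volume boundary (out-of-range taps are linearly extrapolated rather
than clamped). Masks are always resampled nearest-neighbour so labels are
never interpolated. Target voxels outside the source extent are filled with
the source minimum (≈ air for CT) to avoid fabricating tissue.

## Connected components

Lesion clusters are maximal connected voxel sets. Lattice connectivity (6 =
faces, 18 = +edges, 26 = +corners) is a genuine degree of freedom:
"contiguous voxels" has no unique reading. The default is 26, the most
inclusive choice, and every cluster-consuming function exposes the
parameter. Labels are assigned in raster-scan order of each cluster's
minimum linear index, making labelling deterministic and testable against a
brute-force union-find oracle.

# The evaluation criteria

## Lesion detection and the 10% rule

A ground-truth lesion counts as **detected** when the predicted mask covers
at least a fraction τ of the lesion's voxels, with τ = 0.10 by default and
the comparison inclusive (`overlap ≥ τ`): a 1000-voxel lesion with exactly
100 predicted voxels inside it is detected at τ = 0.10 and missed at
τ = 0.101. The overlap denominator is always the ground-truth lesion
volume, not the union or the prediction, and the overlap is computed
against the whole predicted mask, so one predicted cluster may detect
several adjacent lesions while each lesion is counted once.

A **false-positive cluster** is a connected component of the prediction
whose intersection with the ground-truth foreground is empty. Predicted
clusters that touch a lesion without triggering its detection are neither
true nor false positives. This accounting makes lesion-level PPV equal
`detected / (detected + FP clusters)` and reproduces the arithmetic of
detection studies that report, e.g., 224 detections among 254 predicted
clusters; it is the one reading of the criterion consistent with such
counts, though rarely spelled out, and is therefore stated here
explicitly.

## Scan classification

A PSMA-positive scan (≥ 1 ground-truth lesion) is a true positive when at
least one lesion is detected at τ. A PSMA-negative scan is a true negative
only when the prediction contains **not a single positive voxel** — the
strictest possible criterion, appropriate because any spurious cluster on a
negative scan would trigger clinical review.

## Voxel metrics and display

DSC `= 2|A∩B|/(|A|+|B|)`, sensitivity `= |A∩B|/|A|`, PPV `= |A∩B|/|B|`, and
specificity over all grid voxels are computed per scan on ground-truth
positive scans only — DSC is undefined on an empty ground truth, and
negative scans are excluded from voxel-level summaries rather than imputed.
Cohort summaries report mean ± SD and the median (the latter used for
paired inter-observer comparisons). Display rounding is half-up to one
decimal (`roundHalfUp()`), with full precision retained in all
machine-readable output; p-values below 0.005 are displayed as "< 0.005"
with the exact value kept alongside.

# Biomarkers

TLV is the positive-voxel count times the voxel volume, in cm^3. TLU is the
**unweighted** sum of SUV~bw~ over positive voxels — the verbatim
"sum of the SUVs" definition. Because reporting conventions differ on
whether such sums are volume-weighted, the volume-weighted alternative
(Σ SUV × voxel volume, i.e. a total-lesion-activity-style quantity) is
available as the explicitly named `totalLesionActivity()`, never the
default. `compareBiomarkers()` pairs automated against manual records by
scan and reports medians, Wilcoxon signed-rank p, Spearman ρ, and
identity-line scatter data with an optional `log1p` transform for the
heavily right-skewed burden distributions.

# Survival analysis

Overall survival is analysed on baseline scans only; follow-up timepoints
are filtered out. `stratifySurvival()` splits patients on a biomarker:

* **median split** — values ≤ median go to the low group. The tie rule has
  to be fixed somewhere; ≤ keeps the low group weakly larger and is stated
  rather than inferred.
* **Q1 vs Q4** — lowest versus highest quartile, with quartile boundaries
  from linear-interpolation quantiles (`stats::quantile` type 7, the R
  default). Membership is `≤ Q1` / `≥ Q3`.

Groups are compared with the unweighted (Mantel–Haenszel) log-rank test,
1 df, via `survival::survdiff`; Kaplan–Meier curves with at-risk counts at
requested ticks come from `survival::survfit`. The supporting statistics
(Wilcoxon signed-rank with exact null for n ≤ 25 and no ties, normal
approximation with continuity correction otherwise; Spearman ρ as Pearson
correlation of mid-ranks with a t-approximation p; classical one-way
ANOVA) wrap the corresponding `stats` routines; the test suite checks them
against independent sign-flip enumeration, permutation, and hand-computed
sums-of-squares oracles.

# The synthetic phantom

## What it emulates

* whole-body grid: 96 × 96 × 256 voxels at 4.07 × 4.07 × 2 mm;
* lognormal soft-tissue background (median SUV 0.5, σ = 0.3) inside an
  elliptic body cylinder, zero outside, additive Gaussian SUV noise
  (σ = 0.1, floored at 0);
* physiologic hot organs (bladder, kidneys, liver) as ellipsoids with SUV
  in [5, 30], returned as an explicit physiologic mask — the automated
  stand-in for the manual discarding of physiologic uptake;
* lesions: spheres of radius 4–20 mm, peak SUV 3.5–25, count per positive
  scan ~ Poisson(4.2) truncated ≥ 1 (4.2 ≈ 880 lesions / 209 scans, the
  burden of a realistic training cohort); site categories drawn with
  probabilities (0.1602, 0.2170, 0.4045, 0.1898, 0.0284) for local
  prostate / regional nodal / distant nodal / osseous / visceral — printed
  percentages that sum to 0.9999 and are renormalised exactly at
  construction; sites are realised as z-axis anatomical bands
  (pelvic/abdominal/thoracic) with osseous lesions placed inside the
  high-HU spine column of the CT;
* 41.4% of cohort scans are PSMA-negative: physiologic organs but no
  lesions;
* survival: event times exponential with rate
  `base_rate · exp(β · log1p(TLV))`, independent exponential censoring,
  administrative horizon 80 months (matching a follow-up range of roughly
  21–80 months). Defaults `base_rate = 0.002`/month, `β = 0.5`,
  `censor_rate = 0.005`/month give a realistically censored cohort;
  calibration tests use `β = 0` (null) and `β = 1.5` (strong effect).

## The lesion intensity profile

Lesion SUV falls off from its peak to the background **smoothly at the
boundary**: a flat core at the peak for normalised radius ρ ≤ 0.7 and a
cosine taper to background on 0.7 < ρ ≤ 1. The flat core is deliberate: a
taper from the centre outward would leave less than 10% of a peak-3.5
lesion above the SUV 3 segmentation threshold, so even a perfect global
threshold could not detect it under the 10% rule. With the flat core,
≥ ~30% of any lesion's volume sits at its peak, and threshold segmentation
of uncorrupted phantoms achieves lesion sensitivity 1.0 with zero false
positives — a property the test suite asserts.

## Controlled corruption

`corruptPrediction()` turns the ground truth into an imperfect "prediction"
with independently controllable error modes: per-lesion drop probability
(whole misses), signed morphological radius (boundary over/under-
segmentation with the face-connected structuring element), an exact partial
overlap mode (each retained lesion keeps `⌈f · volume⌉` voxels nearest its
centroid — a contiguous interior core for spherical lesions, giving exact
boundary cases for the 10% rule), and Poisson-rate false-positive clusters
placed with a one-voxel guard band so they can never merge with true
lesions or each other under 26-connectivity. Recovery tests confirm that
measured lesion sensitivity equals 1 − drop probability and the FP rate
matches its Poisson mean, each within 3 binomial standard errors.

## What the phantom does *not* emulate

No scanner point-spread function, scatter, partial-volume effect,
reconstruction noise texture, or anatomical atlas realism; lesions are
spheres, organs are ellipsoids, and CT has only three Hounsfield bands.
Passing tests on phantoms therefore validate the *assessment machinery* —
metric arithmetic, matching rules, biomarker bookkeeping, statistical
calibration — not the clinical performance of any segmenter on real
images.

# Reproducibility and problem sizes

All randomness flows through per-call seeds; a master seed fans out
deterministically to per-scan sub-seeds (kept below 2^31), and identical
configuration plus seed yields byte-identical volumes, masks and result
tables. The test suite exercises cohort-level properties on a reduced
48 × 48 × 128 phantom grid — drop-probability and FP-rate recovery are
per-lesion/per-scan properties independent of grid resolution — while the
acceptance script runs the full 96 × 96 × 256 grid with the 128-scan
test-set composition (41.4% negative, drop 0.27, 30/128 FP clusters).
Oracle-equivalence tests compare against O(n²) brute-force voxel-set
oracles on 100 random grids of 5–8 voxels per side across all three
connectivities.

# Known limitations

* Only axis-aligned volumes; oblique acquisitions must be resampled
  upstream.
* The physiologic mask is an input: the package does not model the manual
  judgement of discarding physiologic uptake, nor the manual contouring of
  lesions missed by thresholding.
* Two-group log-rank only (no trend tests, no Cox regression, no competing
  risks).
* TLU units follow the unweighted-sum convention; cross-study comparisons
  should check which convention the other study used (both are computed
  here).

# A worked example

```{r example, eval = FALSE}
cfg <- runConfig(
    phantom = phantomConfig(),
    corruption = corruptionConfig(drop_prob = 0.27, fp_rate = 30 / 128),
    n_scans = 32, seed = 1)
res <- runPipeline(cfg, out_dir = "run1")
reportTables("run1")$performance
```
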