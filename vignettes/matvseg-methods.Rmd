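---
title: "Segmentation methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matvseg)
```

## The problem

Metabolically active tumour volume (MATV) summarizes a patient's whole-body
tumour burden from an FDG-PET scan as the total millilitres of PET-avid
tumour. In cancers that seed many small lesions throughout the body —
metastatic melanoma being the motivating case — manual delineation of every
lesion is impractically slow and observer-dependent, so semi-automatic
threshold-based delineation with a small amount of operator correction is
the realistic workflow. `matvseg` implements that workflow end to end:
voxel-threshold segmentation, consensus voting, a minimum lesion volume,
replayable operator edits, biomarker quantification (MATV, TLG, SUVmax,
SUVpeak), agreement metrics between segmentations, and survival
stratification of the resulting burden estimates.

All inputs are assumed SUV-calibrated (g/mL). The package performs no dose
or decay calibration and no resampling: masks must live on their image's
grid.

## The delineation methods

Six methods operate on an `SUVImage`:

| Method | Rule |
|--------|------|
| SUV25 | voxels with SUV ≥ 2.5 g/mL |
| SUV40 | voxels with SUV ≥ 4.0 g/mL |
| 41MAX | adaptive: SUV ≥ 0.41 × lesion SUVmax |
| A50P | adaptive: SUV ≥ B + 0.5 × (SUVpeak − B), B = local background |
| MV2 | voxels included by ≥ 2 of the four methods above |
| MV3 | voxels included by ≥ 3 of the four methods above |

All SUV comparisons are inclusive (≥), chosen once for bit-exact
reproducibility. After the voxel rule, the mask is split into connected
components (26-neighbourhood by default) and lesions smaller than 3 mL are
discarded — on the default 3.2 × 3.2 × 2 mm grid that boundary falls at
146.48 voxels, so a 146-voxel component is removed and a 147-voxel one
kept. The volume comparison is inclusive: a lesion of exactly 3 mL
survives.

The adaptive methods need a region to adapt to. Candidates are the
connected components above the *detection threshold* (default 2.5 g/mL,
the most inclusive of the four base thresholds — the vote can only include
a voxel at least one base method sees, and SUV25 is the widest). Within
each candidate, 41MAX thresholds at 41% of the candidate's SUVmax and
keeps the component containing the hottest voxel, restricted to the
candidate's bounding box padded by the outer shell margin so an adaptive
threshold below background cannot flood the volume. Ties in the argmax go
to the smallest linear voxel index.

### SUVpeak

SUVpeak is the maximum over sphere positions of the mean SUV in a 1 mL
sphere (diameter ≈ 12.4 mm) defined in world millimetres. Sphere centers
are restricted to voxel centers inside the region, and sphere membership
is by voxel-center distance ≤ radius — a deterministic rule, preferred
over partial-voxel weighting. For lesions smaller than the sphere the mean
deliberately includes out-of-lesion voxels, the standard EANM-style
behaviour; a single-voxel region on a coarse grid degenerates to that
voxel's value.

### A50P iteration

A50P alternates four steps until the voxel set is stable: (1) SUVpeak P of
the current region; (2) local background B = mean SUV over a shell
obtained by dilating the region by 5 voxel steps and removing its
2-step dilation (Chebyshev dilations), excluding every candidate voxel so
neighbouring lesions cannot inflate the background; (3) threshold
T = B + 0.5 × (P − B); (4) new region = connected component of
{SUV ≥ T} at the peak position inside the candidate's padded bounding
box. With B = 0 this reduces to plain 50%-of-peak. Convergence is
declared on identical voxel sets; after 10 iterations the last iterate is
kept with a warning (oscillation is possible in principle; it has not
arisen on any tested phantom). A region that vanishes mid-iteration
yields an empty mask — recorded, contributing 0 mL — rather than an
error, since a method failing to segment a faint lesion is a legitimate
outcome.

The exact background-correction formula and shell geometry inside the
clinical tools this workflow mirrors are not published; the linear
contrast correction above is the standard member of the
adaptive-threshold family, and both the fractions and the shell margins
are exposed in `methodConfig()` rather than hard-coded.

### Majority voting

MV2/MV3 vote voxel-wise over the four *raw* base masks — whole-image
masks, with the adaptive ones unioned over candidates — before any
minimum-volume filtering; the 3 mL rule is applied once to the voted
result. This matches a reading in which the volume rule governs the final
method output, not each ingredient. The implied nesting
(intersection ⊆ MV3 ⊆ MV2 ⊆ union) is asserted by property tests.

## Operator workflow

Clinical use of threshold segmentation needs two corrections: removing
physiological uptake (brain, bladder, kidneys, myocardium all exceed
every threshold) and adding lesions the automatic pass missed. Both are
modelled as world-coordinate seed points in a replayable script
(`readSeedScript()`, `applyScript()`), making an interactive session
headless and testable. Removal deletes the lesion under the seed;
addition snaps the seed to the local SUV maximum within 10 mm, then
delineates by the result's own method rule — the same thresholding the
automatic pass would have used — and flags the lesion `source = "added"`.
Added lesions bypass the 3 mL filter, because the lesions an operator
adds are precisely the ones the automatic pass dropped, typically for
being under 3 mL. Every action is appended to an audit log whose volume
deltas sum exactly to the net MATV change; the uncorrected result is the
total VOI, the script-corrected one the "plus" variant, and addition can
only grow the total.

## Statistics

Per-patient MATV series are compared with Pearson correlation and a
paired t test on log-transformed values; since methods that segment
nothing produce MATV = 0, the transform uses log(x + offset) with a 1 mL
offset by default, reported back in the output. Mask agreement uses the
Jaccard coefficient |A∩B|/|A∪B| and the overlap fraction
|A∩B|/min(|A|,|B|) — the min-denominator convention is the one under
which a mask nested in another scores 1. Two empty masks score 0 (with a
warning), not NaN: a segmentation that captured nothing has zero
agreement with anything.

Survival association mirrors the standard biomarker analysis: patients
are split at the median predictor (ties at the median go low, a
deterministic rule), overall survival is estimated per group by
Kaplan–Meier, groups are compared with the unweighted log-rank test
(hypergeometric variance, no continuity correction), and discrimination
of vital status at end of follow-up is summarized by the ROC AUC with
midrank tie handling, which makes the AUC a normalized Mann–Whitney
statistic and invariant under monotone transforms. Time-dependent ROC is
out of scope.

## The synthetic generators

`generatePhantom()` emulates an EARL-like whole-body acquisition: spheres
painted by voxel-center membership on a uniform background (default
1 g/mL), convolved with an isotropic Gaussian point-spread function
(default FWHM 6.5 mm) on a 256 × 256 in-plane grid of 3.2 × 3.2 × 2 mm
voxels, plus additive Gaussian noise (default SD 0.1 g/mL, about 10% of
soft-tissue background — a plausible post-reconstruction noise level;
values are clipped at 0 to keep the SUV invariant). Ground truth is the
unblurred sphere set; physiological regions are painted and tagged
separately so removal clicks can be exercised. What the phantom does
*not* emulate: reconstruction physics (sinograms, attenuation, scatter),
spatially varying noise correlation, non-spherical lesions, and
heterogeneous uptake. Exactness results on unblurred phantoms therefore
validate the segmentation *logic*, not clinical accuracy; blurred
phantoms additionally exhibit the qualitative partial-volume behaviour
(41MAX volume error grows as the diameter approaches the FWHM), which is
tested as a monotone trend, not a clinical error rate.

`generateCohort()` draws per-patient lesion sets (1 + Poisson(3) lesions,
log-normal diameters with median 20 mm truncated to 8–60 mm) giving an
analytic true MATV, and links survival through an exponential model with
hazard log(2)/18 per month at the reference burden of 25 mL — the
generator's own median cohort MATV — scaled by exp(β · log(MATV/25)),
with uniform administrative censoring at 18–42 months. The defaults
(n = 64, β = 0.5) produce roughly one third of patients alive at
censoring, the regime the workflow is intended for. β = 0 gives null
cohorts used to check that the median-split log-rank test keeps its
nominal 5% size.

## Numerical and testing choices

* Coordinates: 1-based voxel indices, world = origin + (index − 1) ·
  spacing, voxel-center convention, axis order (x, y, z) everywhere.
* Label order is deterministic: descending volume, ties by smallest
  linear voxel index; all tie-breaks in the package follow the
  smallest-linear-index rule, and no segmentation code path uses random
  numbers.
* Connectivity defaults to 26 (permissive, avoids fragmenting thin
  lesions); 6 is available in `methodConfig()`.
* Non-finite or negative SUV voxels are rejected at construction/load
  time, never clamped.
* Test problem sizes: phantoms of 24³–72³ voxels and cohorts of 32–64
  patients with up to 500 replicates for calibration checks — small
  enough for a routine test run, large enough that every stage (blur,
  candidate detection, adaptive iteration, voting, survival statistics)
  is exercised at realistic voxel counts.

## Limitations

Gradient-based (edge-seeking) manual delineation, DICOM/SUV calibration,
inter-grid registration, partial-volume correction, PERCIST-style
liver-reference thresholds, Cox regression and time-dependent ROC are all
out of scope. The A50P shell geometry, while configurable, is one
reasonable choice among several used by clinical tools; results for
faint, small lesions near hot neighbours are the most sensitive to it.
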