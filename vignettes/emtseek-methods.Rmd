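---
title: "Quantifying disseminating EMT cancer stem cells: models and methods"
author: "emtseek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying disseminating EMT cancer stem cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

A field of view is a four-channel 16-bit grey-level image: DAPI (nuclei),
FITC (CD24), CY3 (EpCAM, or pan-keratin in benchmark mode) and CY5
(Vimentin). The quantity of interest is, per field and per tissue region,
the fraction of nucleated cells that are *triple positive*
(EpCAM⁺Vim⁺CD24⁺ — a disseminating EMT cancer-stem-cell phenotype) or
*double positive* (EpCAM⁺Vim⁺CD24⁻, a non-predictive control population).

The chain is:

1. **Nucleus detection.** The DAPI channel is min–max normalized, smoothed
   (Gaussian, `smoothing_sigma = 2` px), thresholded with Otsu's two-class
   cutoff, hole-filled, and split by watershed on the distance map;
   objects under `min_area_px = 12` px² are discarded. Normalization makes
   detection invariant to uniform intensity rescaling. A flat DAPI channel
   yields zero cells with a warning rather than an error.
2. **Tumour/stroma segmentation (the dense cloud).** The reference marker
   channel (CY3 by default; CY5 supported for specimens segmented on the
   mesenchymal side) is Gaussian-smoothed (`smoothing_sigma_px = 10`),
   thresholded (automatic Otsu cutoff on the smoothed channel, overridable
   with a numeric grey level for degenerate fields such as all-tumour
   tiles), morphologically closed (`closing_radius_px = 16` — bridges the
   gaps between neighbouring stained tumour cells so the body becomes one
   region), dilated (`dilation_radius_px = 4`), and filtered by component
   size. Two size filters apply: an absolute floor
   (`min_component_area_px = 3000` px²) and a relative floor (components
   smaller than `min_component_fraction = 0.25` of the largest component).
   The relative floor is the scale-free statement of the same idea — the
   tumour body is the dominant cohesive region — and keeps satellite blobs
   of scattered stromal marker-positive cells out of the mask even when
   the automatic cutoff sits close to the background (e.g. noiseless
   images). This component filtering is what lets a single disseminating
   EpCAM⁺ cell in the stroma be counted as stromal rather than absorbed
   into the tumour mask.
3. **Region assignment.** A cell is tumour iff the pixel containing its
   centroid is inside the mask (pixel-centred, 0-based coordinates;
   a centroid exactly on the border counts as inside if its containing
   pixel is set). Every cell gets exactly one region.
4. **Intensity extraction.** A cell's grey level per channel is the mean
   pixel value over its measurement mask: the nucleus mask dilated by 2 px
   (discrete disc brush), capturing peri-nuclear membranous stain.
5. **Background thresholds.** Per channel, the threshold is
   `multiplier × median` (default multiplier 1.5) of the *per-cell* grey
   levels of a negative-control slide, pooled over control fields. The
   control median could equally be taken per pixel; per cell is the
   default because the threshold is applied to per-cell values, so the
   null distribution should be per-cell. Both are exposed
   (`measure = "cell"`/`"pixel"`).
6. **Positivity calls.** Strict inequality: a cell is positive iff its
   grey level exceeds the channel threshold; ties are negative. Triple
   positive = positive in FITC, CY3 and CY5; double positive = positive in
   CY3 and CY5 but not FITC. The two calls are mutually exclusive by
   construction. Calls are invariant to multiplying all intensities
   (fields and controls) by a constant.
7. **Field QC.** Fields with fewer nucleated cells than
   `min_fraction = 0.2` of the median count (median per slide when slide
   ids are present) are excluded; fields over folded specimen edges are
   excluded via a caller-supplied blacklist, not an algorithm. If QC
   removes every field of a slide, that is an error naming the slide.

## Cohort statistics

The slide, not the field, is the biological replicate: fields within one
tumour are pseudo-replicates, so fields are pooled within slide first
(total positives / total region cells) and inference runs on slide-level
proportions. Group means carry 95 % t-intervals; groups are compared with
a two-tailed two-sample t test — Welch's unequal-variance form by default,
the classic pooled form via `var.equal = TRUE`. Degenerate input (both
groups constant and equal) returns p = 1 by convention; constant but
different groups return p = 0. Stars follow the usual convention
(*** for p < 0.001). A "normal region" group can be carried through the
manifest as a third label.

## Metastasis prediction

The supervised task is to classify each imaging field as coming from a
metastatic or non-metastatic tumour; `"metastatic"` is the positive class
everywhere.

**Features.** Variable numbers of cells per field must become a fixed
vector. In `cell_intensity` mode the background threshold is subtracted
from each cell's FITC/CY3/CY5 grey level and each channel is reduced to a
16-bin histogram of `log1p` of the positive part (proportions of cells,
fixed breaks over the 16-bit range) plus the mean and maximum of the
subtracted values; the field's cell count is appended (3 × 18 + 1 = 55
features). The reduction is order-invariant and hand-checkable. `pixel`
mode mean-pools each marker channel to 64 × 64, subtracts the channel
threshold and flattens. `stroma_counts`/`tumour_counts` use the region's
triple-positive count as a single feature, and `gaussian_dummy` draws
seeded i.i.d. standard-normal features as a chance-level baseline.

**Models.** Logistic regression, SVM (RBF), naive Bayes, k-NN, decision
tree — all through the packages a practitioner would use — plus a
hand-implemented feed-forward neural network: two ReLU hidden layers
(64, 32), logistic output, cross-entropy loss, seeded He initialisation,
mini-batch gradient descent (batch 16, learning rate 0.05, momentum 0.9),
14 epochs by default, inputs standardized, with per-epoch accuracy and
loss recorded on the training set and a validation set. A non-finite loss
aborts with diagnostics; hidden layers with zero units are rejected.
Within-class standard deviations in naive Bayes are floored at 1e-6 so a
feature constant inside one class cannot produce degenerate densities.

**Evaluation.** Splits are stratified by class and, by default, grouped by
slide so no tumour's fields straddle the train/validation boundary
(`by_slide = FALSE` reproduces a literal field-level random split, which
leaks slide identity and is documented as such). Cross-validation uses
stratified folds at field level; the score is F1 with metastatic positive
(defined as 0 when there are neither true nor predicted positives). Grid
search is exhaustive over the supplied hyperparameter grid with a
deterministic first-in-grid-order tie-break. ROC curves sweep all score
thresholds; AUC is the trapezoid rule (equal to the pairwise concordance
fraction, which the tests verify); sensitivity and specificity are
reported at the 0.5 operating point. Slide-level calls take the majority
vote over a pool of 10 fields; an even split is resolved by the mean
predicted probability (metastatic iff ≥ 0.5) — pools of 10 make ties
possible and the tie rule must be explicit.

## scRNA-seq co-expression

Marker positivity in a normalized expression matrix uses a cutoff computed
over **all** cells (median, upper quartile, or a fixed value), with strict
inequality; per-group cutoffs are available as an option. The triple-positive
fraction is reported per cell group (tumour / non-tumour) with numerator and
denominator. Tightening the rule from median to upper quartile can only
remove positives. Tumour/non-tumour labels are taken as given; inferring
them (e.g. by CNV) is out of scope.

## What the synthetic generator emulates — and what it does not

`generate_field` renders: a cohesive tumour body on one side of an
invasive front (a half-plane perturbed by three random low-frequency
sinusoids, amplitude 25 px, emulating irregular invasive presentations);
nuclei as discs (radius 5 px) with marker stain on a disc dilated 2 px
(membranous-stain geometry); i.i.d. Gaussian background noise (mean 200,
sd 60 grey levels), clipped at zero and quantised, on a 16-bit scale;
per-cell lognormal staining variability (CV 0.1) around channel gains
(6000–8000). Tumour cells carry CY3, stromal cells CY5, planted
disseminating cells the planted combination. Cells sit on a jittered grid
whose pitch guarantees that stain discs never overlap, so a pixel-level
oracle for every downstream quantity is exact. Planted disseminating cells
are placed at least 80 px beyond the front and at least 50 px apart: the
phenomenon being modelled is *single scattered* disseminating cells, and
the separation also keeps them from merging into pseudo-clusters that no
small-component filter could reject. Negative controls render nuclei with
background-only marker channels, which makes the 1.5×-median threshold
meaningful by construction.

Cohorts add two tabular fidelity layers sharing the same hierarchical
seeding (slide-level lognormal density multiplier, CV 0.25, then per-field
binomial planting): `"cells"` emits the per-cell grey-level tables the
imaging pipeline would extract (positive channels at the gain with
lognormal variability; background channels at the background mean with the
standard error of a disc-mean), and `"counts"` emits only planted counts.
The pixel path is exercised end to end at small scale; the tabular layers
make cohort-scale classifier experiments and a 1000-cohort type-I-error
calibration tractable on one CPU. The default cohort — 12 metastatic and
12 non-metastatic slides, 10 fields of 150 tumour + 180 stromal cells,
stromal triple-positive densities 20 vs 1 per 1000 stromal cells, double
positives 10 per 1000 in both groups — yields slide-level stromal
triple-positive fractions near 2 % vs 0.1 %, a strong-enrichment regime;
double positives are deliberately non-discriminative.

Not modelled: optical point-spread functions, autofluorescence, uneven
illumination, tissue folds (fold exclusion is a mask input), touching or
overlapping cells beyond what the watershed handles, chromatic
misregistration, and realistic per-cell intensity distributions of stained
tissue — the gains are free parameters. Passing tests therefore
demonstrate that the *pipeline arithmetic and logic* are correct and that
the method recovers planted structure under its own assumptions; they do
not certify segmentation or classification performance on clinical slides.

The expression-matrix generator plants co-expressing cells (all three
markers at offset 8 + Exp(1), above any data-driven cutoff) against
background cells that express at most two of the three markers (one
marker, chosen uniformly, is exactly zero; the rest are Exp(1)). Under any
positive cutoff the planted rate is recovered exactly in expectation. This
is a stylized co-expression structure, not a transcriptome model.

## Numerical choices and degenerate inputs

- Coordinates are pixel-centred and 0-based (x right, y down); matrices
  are stored row = y.
- Positivity, threshold rules and QC all use the conventions above
  (strict `>`, per-cell control median, per-slide QC median).
- Otsu cutoffs are computed on min–max-normalized data, so segmentation
  and detection are scale-free; flat channels warn and return empty
  results instead of erroring.
- The ANN is deterministic given (data seed, split seed, model seed);
  everything stochastic in the package flows through explicit integer
  seeds, and generators restore the caller's RNG state.
- Validation sets with a single class make the ROC an error (not NaN);
  empty groups, zero-cell fields and empty splits are errors naming the
  offending unit.
- The chance-level behaviour of the Gaussian-dummy baseline is assessed as
  the mean AUC over 20 seeded draws: a single ~70-field validation AUC has
  a standard error near 0.07, so per-draw bounds would be dominated by
  sampling noise.

## Problem sizes

The test suite runs the pixel path on 352²–512² px fields (20 fields for
the zero-noise exactness and segmentation checks), the tabular cohort
layer at the full 24-slide × 10-field design for classifier checks, and
1000 counts-layer cohorts for null calibration; these sizes were chosen so
the whole suite and the acceptance script each complete in minutes on a
single CPU while keeping every statistical check adequately powered.

## Known limitations

- The dense cloud assumes one dominant tumour body per field; fields with
  several comparable tumour islands or no tumour at all need an explicit
  cutoff and a relaxed component-fraction filter.
- The per-cell measurement disc uses a discrete brush, so measured means
  on synthetic discs are diluted by a one-pixel rim; positivity calls are
  unaffected at realistic gain/background separations.
- Cohort-2-style segmentation variants beyond switching the reference
  channel to Vimentin are not modelled.
- Field-level cross-validation folds may split a slide's fields across
  folds (as in a literal random split); slide-grouped splitting is the
  default for the single train/validation partition but not for CV folds.
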