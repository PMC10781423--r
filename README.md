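# emtseek

Quantification of disseminating EMT cancer stem cells in multiplexed
immunofluorescence images of tumour–stroma boundaries, and image-based
prediction of metastatic status.

## The problem

Carcinoma cells that undergo epithelial–mesenchymal transition (EMT) detach
from the tumour body and disseminate into the surrounding stroma, where they
become morphologically indistinguishable from resident mesenchymal cells.
A small subpopulation of these cells retains the epithelial surface marker
EpCAM and the plasticity marker CD24 alongside the mesenchymal marker
Vimentin; cells staining positive for all three
(EpCAM⁺Vim⁺CD24⁺, "triple positive") mark disseminating EMT cancer stem
cells, and their abundance in the stroma of oral squamous cell carcinoma
specimens is associated with metastasis.

`emtseek` implements the full analysis chain for four-colour
(DAPI + CD24/FITC + EpCAM/CY3 + Vimentin/CY5) fields of view:

1. **Synthetic data** (`generate_field`, `generate_negative_control`,
   `generate_cohort`, `generate_expression_matrix`) — seeded fields with an
   irregular invasive front, stromal background cells, rare planted
   disseminating cells, negative controls, labelled two-group cohorts and
   single-cell expression matrices, all with complete ground truth.
2. **Image quantification** (`detect_nuclei`, `build_dense_cloud`,
   `assign_regions`, `extract_intensities`, `compute_thresholds`,
   `classify_cells`, `qc_filter_fields`, `summarize_field`) — nucleus
   detection on DAPI; a marker "dense cloud" mask separating the tumour
   body from the stroma; per-cell grey levels; per-channel background
   thresholds (1.5 × the per-cell median of a negative control); strict
   positivity calls. A cell above threshold in all three marker channels is
   triple positive; above CY3 and CY5 but not FITC is double positive
   (EpCAM⁺Vim⁺CD24⁻). Fields with fewer than 20 % of the median nucleated
   cell count are excluded.
3. **Cohort statistics** (`slide_proportions`, `aggregate_proportions`,
   `compare_groups`) — slide-level pooling (the slide is the biological
   replicate), group means with 95 % t-intervals, and a two-tailed
   two-sample t test (Welch by default) comparing e.g. the metastatic vs
   non-metastatic stromal triple-positive percentage.
4. **Metastasis prediction** (`build_feature_matrix`,
   `split_train_validation`, `cross_validate`, `grid_search`, `train_ann`,
   `compute_roc`, `predict_slide`) — field-level features (per-cell
   intensity descriptors, pooled pixels, region counts, or a Gaussian dummy
   baseline); logistic regression, SVM, naive Bayes, k-NN, decision tree
   and a feed-forward neural network (two ReLU hidden layers, logistic
   output, per-epoch accuracy/loss traces); stratified 70:30 splits and
   10-fold cross-validated F1 with metastatic as the positive class;
   ROC/AUC by the trapezoid rule; majority-vote slide calls over pools of
   10 fields.
5. **scRNA-seq co-expression** (`threshold_positive`,
   `coexpression_fraction`, `coexpression_analysis`) — marker positivity by
   median/upper-quartile/fixed expression cutoffs and per-group
   triple-positive fractions.

`run_pipeline()` orchestrates simulate → quantify → stats → train from a
single seeded configuration; `inst/cli/emtseek.R` is a thin command-line
wrapper.

## Worked example

```r
library(emtseek)

# a boundary field with planted disseminating cells, and a negative control
spec <- field_spec(planted_triple_positive_density = 30, seed = 7)
field <- generate_field(spec)
control <- generate_negative_control(field_spec(seed = 8))

thresholds <- compute_thresholds(control)   # 1.5 x per-cell median
thresholds
#> <threshold_set> multiplier 1.5 x cell median of 330 cells (negative_control)
#>   FITC    CY3    CY5
#> 299.43 298.80 299.70

q <- quantify_field(field, thresholds)
q$summary[, c("n_cells", "n_tumour", "n_stroma",
              "stroma_triple", "prop_stroma_triple")]
#>   n_cells n_tumour n_stroma stroma_triple prop_stroma_triple
#> 1     330      143      187             5         0.02673797
```

Five of 187 stromal cells (2.7 %) are EpCAM⁺Vim⁺CD24⁺ — exactly the five
planted disseminating cells (`field$truth$cells`), none absorbed into the
tumour mask. On a full synthetic cohort (12 metastatic + 12 non-metastatic
slides × 10 fields):

```r
co <- generate_cohort(cohort_spec(seed = 11), output = "cells")
thr <- compute_thresholds(co$control_cells)
cells <- classify_cells(co$cells, thr)
ft <- build_feature_matrix(cells, "cell_intensity",
                           manifest = co$manifest, thresholds = thr)
cross_validate(ft, "ann", k = 10, seed = 3)
#> <cv_report> ann: 10-fold mean F1 = 0.905 (folds 0.86 0.92 0.96 ...)
```

The neural network recovers the planted group difference from per-field
intensity descriptors; the mean cross-validated F1 of 0.905 means fields of
metastatic slides are identified with ~90 % balanced precision/recall,
limited by fields that happen to contain no disseminating cell.

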