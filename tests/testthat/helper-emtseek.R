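# small field spec for fast image tests
tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(width_px = 352, height_px = 352, n_tumour_cells = 70,
                   n_stroma_cells = 55, front_position = 0.45,
                   front_amplitude_px = 15, stroma_margin_px = 80,
                   planted_min_sep_px = 50, seed = 1)
  do.call(field_spec, utils::modifyList(defaults, args))
}

# brute-force F1 from the contingency definition
bf_f1 <- function(truth, pred, positive = "metastatic") {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(truth)) {
    if (pred[i] == positive && truth[i] == positive) tp <- tp + 1
    if (pred[i] == positive && truth[i] != positive) fp <- fp + 1
    if (pred[i] != positive && truth[i] == positive) fn <- fn + 1
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# AUC as the pairwise concordance count / (n_pos * n_neg), ties count 1/2
bf_auc <- function(scores, labels, positive = "metastatic") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + (p > q) + 0.5 * (p == q)
  conc / (length(pos) * length(neg))
}

# textbook two-sample t statistic (Welch)
bf_welch_t <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

# per-cell grey levels recomputed with an explicit pixel loop over the
# measurement discs (generator geometry: nucleus radius + 2)
bf_cell_means <- function(field, centroids, radius) {
  h <- nrow(field$channels$DAPI); w <- ncol(field$channels$DAPI)
  t(apply(centroids, 1, function(ce) {
    vals <- sapply(c("FITC", "CY3", "CY5"), function(ch) {
      m <- field$channels[[ch]]
      tot <- 0; cnt <- 0
      for (col in max(1, floor(ce[1] - radius)):min(w, ceiling(ce[1] + radius) + 1)) {
        for (row in max(1, floor(ce[2] - radius)):min(h, ceiling(ce[2] + radius) + 1)) {
          if ((col - 1 - ce[1])^2 + (row - 1 - ce[2])^2 <= radius^2) {
            tot <- tot + m[row, col]; cnt <- cnt + 1
          }
        }
      }
      tot / cnt
    })
    vals
  }))
}

# random classified cell table for oracle checks
random_cells <- function(n, seed) {
  set.seed(seed)
  data.frame(field_id = sample(sprintf("f%02d", 1:5), n, replace = TRUE),
             region = sample(c("tumour", "stroma"), n, replace = TRUE),
             grey_FITC = runif(n, 0, 400),
             grey_CY3 = runif(n, 0, 400),
             grey_CY5 = runif(n, 0, 400))
}

# small separable feature table: one informative feature
toy_table <- function(n_per_class = 30, sep = 4, seed = 1, n_noise = 3) {
  set.seed(seed)
  n <- 2 * n_per_class
  label <- rep(c("metastatic", "non_metastatic"), each = n_per_class)
  x <- cbind(signal = rnorm(n) + ifelse(label == "metastatic", sep, 0),
             matrix(rnorm(n * n_noise), nrow = n,
                    dimnames = list(NULL, paste0("n", 1:n_noise))))
  slide <- paste0("s", rep(1:10, length.out = n))
  slide <- paste0(slide, "_", label)  # slides are label-pure
  emtseek:::new_feature_table(x, label, sprintf("f%03d", 1:n), slide,
                              "cell_intensity")
}
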