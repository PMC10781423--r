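make_cells_cohort <- function(seed = 11, ...) {
  co <- generate_cohort(cohort_spec(seed = seed, ...), output = "cells")
  thr <- compute_thresholds(co$control_cells)
  cells <- classify_cells(co$cells, thr)
  list(cohort = co, thresholds = thr, cells = cells)
}

test_that("feature construction matches hand computation", {
  thr <- c(FITC = 100, CY3 = 100, CY5 = 100)
  man <- data.frame(field_id = "f1", slide_id = "s1", label = "metastatic")
  cells <- data.frame(field_id = "f1",
                      grey_FITC = c(150, 90, 100, 300, 101),
                      grey_CY3 = c(200, 200, 200, 200, 200),
                      grey_CY5 = c(100, 100, 100, 100, 100))
  ft <- build_feature_matrix(cells, "cell_intensity", manifest = man,
                             thresholds = thr)
  expect_equal(ncol(ft$x), 55)
  expect_equal(unname(ft$x[1, "n_cells"]), 5)
  expect_equal(unname(ft$x[1, "FITC_mean"]), mean(c(50, -10, 0, 200, 1)))
  expect_equal(unname(ft$x[1, "FITC_max"]), 200)
  expect_equal(unname(ft$x[1, "CY5_max"]), 0)
  # histogram: subtracted FITC positives log1p(c(50,0,0,200,1)); bin width
  # log1p(65535)/16 = 0.6937; bins: 50 -> bin 6, 200 -> bin 8, 1 -> bin 1,
  # zeros -> bin 1
  b <- log1p(65535) / 16
  expect_equal(unname(ft$x[1, sprintf("FITC_h%02d",
                                      ceiling(log1p(50) / b))]), 1 / 5)
  expect_equal(sum(ft$x[1, sprintf("FITC_h%02d", 1:16)]), 1)

  # count modes take the region triple-positive count
  sums <- data.frame(field_id = "f1", stroma_triple = 3, tumour_triple = 1)
  expect_equal(unname(build_feature_matrix(sums, "stroma_counts",
                                           manifest = man)$x[1, 1]), 3)
  expect_equal(unname(build_feature_matrix(sums, "tumour_counts",
                                           manifest = man)$x[1, 1]), 1)

  # dummy features are seeded and label-independent
  d1 <- build_feature_matrix(sums, "gaussian_dummy", manifest = man,
                             dummy_seed = 3)
  d2 <- build_feature_matrix(sums, "gaussian_dummy", manifest = man,
                             dummy_seed = 3)
  expect_identical(d1$x, d2$x)

  # a field with zero cells cannot be featurized
  expect_error(build_feature_matrix(cells[0, ], "cell_intensity",
                                    manifest = man, thresholds = thr),
               "field_id|zero cells")
})

test_that("pixel-mode features background-subtract pooled channels", {
  f <- generate_field(tiny_spec(seed = 2))
  man <- data.frame(field_id = "f1", slide_id = "s1", label = "metastatic")
  thr <- c(FITC = 300, CY3 = 300, CY5 = 300)
  ft <- build_feature_matrix(list(f1 = f), "pixel", manifest = man,
                             thresholds = thr, pool_to = 16)
  expect_equal(ncol(ft$x), 3 * 16 * 16)
  # first pooled block of FITC equals the hand-pooled mean
  # (352 rows pooled to 16 -> 22 px blocks)
  block <- f$channels$FITC[1:22, 1:22]
  expect_equal(unname(ft$x[1, 1]), mean(block) - 300)
})

test_that("train/validation split is stratified, seeded and leak-free", {
  co <- make_cells_cohort(seed = 5)
  ft <- build_feature_matrix(co$cells, "cell_intensity",
                             manifest = co$cohort$manifest,
                             thresholds = co$thresholds)
  parts <- split_train_validation(ft, 0.7, seed = 1)
  expect_equal(nrow(parts$train$x) + nrow(parts$validation$x), 240)
  # 70:30 at slide level: 8 + 8 training slides (24 x 10 fields)
  expect_equal(length(unique(parts$train$slide_id)), 16)
  # no slide straddles the split
  expect_length(intersect(parts$train$slide_id,
                          parts$validation$slide_id), 0)
  # both classes in both partitions
  expect_setequal(unique(parts$train$label),
                  c("metastatic", "non_metastatic"))
  expect_setequal(unique(parts$validation$label),
                  c("metastatic", "non_metastatic"))
  # same seed -> identical partition
  parts2 <- split_train_validation(ft, 0.7, seed = 1)
  expect_identical(parts$train$field_id, parts2$train$field_id)
  # field-level split obeys the 70:30 ratio on fields
  pf <- split_train_validation(ft, 0.7, seed = 2, by_slide = FALSE)
  expect_equal(nrow(pf$train$x), 168)
  expect_error(split_train_validation(ft, 1.0), "between 0 and 1")
})

test_that("cross-validated F1 behaves at the extremes and matches hand folds", {
  # perfectly separable features
  tab <- toy_table(n_per_class = 30, sep = 6)
  cv <- cross_validate(tab, "logistic", k = 10, seed = 1)
  expect_equal(cv$mean_f1, 1.0)

  # permuted labels fall to the prevalence baseline
  perm <- toy_table(n_per_class = 25, sep = 6, seed = 3)
  set.seed(42)
  f1s <- vapply(1:30, function(i) {
    p <- perm
    p$label <- sample(p$label)
    cross_validate(p, "logistic", k = 5, seed = i)$mean_f1
  }, numeric(1))
  # null F1 for a balanced problem concentrates near 0.5
  expect_lt(abs(mean(f1s) - 0.5), 0.1)

  # k = 2 on a 4-row table with a deterministic family: fold scores match
  # a hand computation via the brute-force F1
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1,
              dimnames = list(NULL, "v"))
  tab4 <- emtseek:::new_feature_table(
    x, c("non_metastatic", "non_metastatic", "metastatic", "metastatic"),
    paste0("f", 1:4), paste0("s", 1:4), "stroma_counts")
  cv2 <- cross_validate(tab4, "knn", k = 2, seed = 7, params = list(k = 1))
  fold <- emtseek:::stratified_folds(tab4$label, 2, seed = 7)
  hand <- vapply(1:2, function(f) {
    fit <- fit_classifier(tab4[fold != f], "knn", params = list(k = 1))
    bf_f1(tab4$label[fold == f], predict(fit, tab4[fold == f], "class"))
  }, numeric(1))
  expect_equal(cv2$fold_f1, hand)

  expect_error(cross_validate(tab4, "knn", k = 3), "fewer than k")
})

test_that("every classifier family learns a separable problem", {
  tab <- toy_table(n_per_class = 20, sep = 6, seed = 2)
  for (fam in CLASSIFIER_FAMILIES) {
    fit <- fit_classifier(tab, fam, params = list())
    pred <- predict(fit, tab, type = "class")
    expect_gt(bf_f1(tab$label, pred), 0.9)
    p <- predict(fit, tab, type = "prob")
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("grid search is exhaustive with a deterministic tie-break", {
  tab <- toy_table(n_per_class = 15, sep = 6, seed = 4)
  # singleton grid returns that setting
  gs1 <- grid_search(tab, "knn", list(k = 3), k = 3, seed = 1)
  expect_equal(gs1$best_params$k, 3)
  # 2x2 grid: all four evaluated; best equals max of recorded scores
  gs <- grid_search(tab, "svm", list(cost = c(0.01, 1),
                                     gamma = c(0.01, 0.5)),
                    k = 3, seed = 1)
  expect_equal(nrow(gs$results), 4)
  expect_equal(gs$best_f1, max(gs$results$mean_f1))
  first_max <- which.max(gs$results$mean_f1)
  expect_equal(as.numeric(gs$best_params),
               as.numeric(gs$results[first_max, c("cost", "gamma")]))
  expect_error(grid_search(tab, "knn", list(cost = 1)), "not supported")
})

test_that("the neural network trains, traces epochs, and rejects bad configs", {
  expect_error(train_ann(toy_table(), hidden = c(0, 4)), "at least one unit")

  tab <- toy_table(n_per_class = 40, sep = 6, seed = 5)
  m <- train_ann(tab, seed = 2)
  expect_equal(nrow(m$history), 14)
  expect_true(all(c("train_loss", "train_acc", "val_loss", "val_acc")
                  %in% names(m$history)))
  # linearly separable data: training accuracy saturates within 14 epochs
  expect_equal(m$history$train_acc[14], 1.0)
  # losses decrease overall
  expect_lt(m$history$train_loss[14], m$history$train_loss[1])
  # determinism
  m2 <- train_ann(tab, seed = 2)
  expect_identical(m$history, m2$history)
  expect_equal(predict(m, tab), predict(m2, tab))
})

test_that("ROC, AUC and the operating point match the concordance oracle", {
  # perfect scores
  roc <- compute_roc(c(0.9, 0.8, 0.2, 0.1),
                     c("metastatic", "metastatic", "non_metastatic",
                       "non_metastatic"))
  expect_equal(roc$auc, 1.0)
  expect_equal(roc$sensitivity, 1.0)
  expect_equal(roc$specificity, 1.0)

  # six hand-listed pairs: AUC equals pairwise concordance / (n+ x n-)
  scores <- c(0.9, 0.4, 0.65, 0.2, 0.55, 0.7)
  labels <- c("metastatic", "metastatic", "metastatic",
              "non_metastatic", "non_metastatic", "non_metastatic")
  roc <- compute_roc(scores, labels)
  expect_equal(roc$auc, bf_auc(scores, labels))

  # random scores across repeats hover at chance
  set.seed(8)
  aucs <- replicate(200, {
    compute_roc(runif(40), sample(rep(labels[c(1, 4)], 20)))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)

  # agreement with an independent implementation on random instances
  for (i in 1:5) {
    set.seed(i)
    s <- runif(30)
    l <- sample(rep(c("metastatic", "non_metastatic"), 15))
    expect_equal(compute_roc(s, l)$auc,
                 as.numeric(pROC::auc(pROC::roc(
                   response = l, predictor = s, levels =
                     c("non_metastatic", "metastatic"),
                   direction = "<", quiet = TRUE))))
    expect_equal(compute_roc(s, l)$auc, bf_auc(s, l))
  }

  expect_error(compute_roc(c(0.1, 0.9), c("metastatic", "metastatic")),
               "single class")
})

test_that("F1 matches the brute-force definition on small tables", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    truth <- sample(c("metastatic", "non_metastatic"), n, replace = TRUE)
    pred <- sample(c("metastatic", "non_metastatic"), n, replace = TRUE)
    expect_equal(f1_score(truth, pred), bf_f1(truth, pred))
  }
})

test_that("slide prediction takes the majority vote with a mean-probability tie-break", {
  # scorer whose predicted probabilities are the first feature column
  fake_model <- function(fields) as.numeric(fields$x[, 1])
  as_ft <- function(p) emtseek:::new_feature_table(
    matrix(p, ncol = 1), rep("metastatic", length(p)),
    sprintf("f%d", seq_along(p)), "s1", "cell_intensity")

  v <- predict_slide(fake_model, as_ft(c(rep(0.9, 6), rep(0.1, 4))))
  expect_equal(v$label, "metastatic")
  expect_equal(unname(v$votes["metastatic"]), 6)
  v <- predict_slide(fake_model, as_ft(rep(0.1, 10)))
  expect_equal(v$label, "non_metastatic")
  # 5/5 tie resolved by mean probability: mean(0.9 x5, 0.1 x5) = 0.5 -> met
  v <- predict_slide(fake_model, as_ft(c(rep(0.9, 5), rep(0.1, 5))))
  expect_equal(v$label, "metastatic")
  expect_equal(v$mean_prob, 0.5)
  # tie with low probabilities -> non-metastatic
  v <- predict_slide(fake_model, as_ft(c(rep(0.6, 5), rep(0.1, 5))))
  expect_equal(v$label, "non_metastatic")
  expect_error(predict_slide(fake_model, as_ft(numeric(0))), "no fields")
})

test_that("count features carry signal when the groups differ only in stromal counts", {
  co <- generate_cohort(cohort_spec(seed = 19), output = "counts")
  sums <- truth_field_summaries(co)
  ft <- build_feature_matrix(sums, "stroma_counts",
                             manifest = co$manifest)
  parts <- split_train_validation(ft, 0.7, seed = 3)
  m <- fit_classifier(parts$train, "logistic")
  roc <- compute_roc(m, parts$validation)
  expect_gt(roc$auc, 0.5)
})

test_that("the full prediction pipeline is deterministic given its seeds", {
  co1 <- make_cells_cohort(seed = 23, fields_per_slide = 5)
  co2 <- make_cells_cohort(seed = 23, fields_per_slide = 5)
  ft1 <- build_feature_matrix(co1$cells, "cell_intensity",
                              manifest = co1$cohort$manifest,
                              thresholds = co1$thresholds)
  ft2 <- build_feature_matrix(co2$cells, "cell_intensity",
                              manifest = co2$cohort$manifest,
                              thresholds = co2$thresholds)
  expect_identical(ft1$x, ft2$x)
  m1 <- train_ann(ft1, seed = 4, val_fraction = 0)
  m2 <- train_ann(ft2, seed = 4, val_fraction = 0)
  expect_identical(m1$history, m2$history)
})
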