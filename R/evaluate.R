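#' F1 score with the metastatic class positive
#'
#' Harmonic mean of precision and recall. When there are neither predicted
#' nor true positives the score is defined as 0.
#'
#' @param truth,pred character vectors of labels.
#' @param positive the positive class.
#' @return a single number in [0, 1].
#' @export
f1_score <- function(truth, pred, positive = "metastatic") {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(label, k, seed) {
  fold <- integer(length(label))
  local_seed(seed, {
    for (lv in unique(label)) {
      idx <- which(label == lv)
      if (length(idx) < k)
        stopf("class '%s' has %d fields, fewer than k = %d folds",
              lv, length(idx), k)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' k-fold cross-validated F1
#'
#' Stratified k-fold cross-validation of one classifier family; the score
#' is the F1 with metastatic as the positive class, averaged over folds.
#'
#' @param table a \code{feature_table}.
#' @param family one of \code{\link{CLASSIFIER_FAMILIES}}.
#' @param k number of folds (10 by default).
#' @param seed seed for the fold assignment (and the ANN).
#' @param params family hyperparameters.
#' @return an object of class \code{cv_report}: \code{fold_f1} (k scores),
#'   \code{mean_f1}, \code{family}, \code{k}.
#' @export
cross_validate <- function(table, family = CLASSIFIER_FAMILIES, k = 10,
                           seed = 1, params = list()) {
  family <- match.arg(family)
  fold <- stratified_folds(table$label, k, seed)
  scores <- vapply(seq_len(k), function(f) {
    fit <- fit_classifier(table[fold != f], family, params)
    pred <- predict(fit, table[fold == f], type = "class")
    f1_score(table$label[fold == f], pred)
  }, numeric(1))
  structure(list(fold_f1 = scores, mean_f1 = mean(scores),
                 family = family, k = k),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: %d-fold mean F1 = %.3f (folds %s)\n",
              x$family, x$k, x$mean_f1,
              paste(sprintf("%.2f", x$fold_f1), collapse = " ")))
  invisible(x)
}

#' Exhaustive grid search over hyperparameters
#'
#' Evaluates every combination in the grid by cross-validated mean F1 and
#' refits the best setting on the full table. Ties are broken
#' deterministically by the first combination in grid order
#' (\code{expand.grid} over the supplied values, first key varying
#' fastest).
#'
#' @param table a \code{feature_table}.
#' @param family classifier family.
#' @param grid named list of hyperparameter value vectors (keys must be
#'   supported by the family).
#' @param k,seed cross-validation settings.
#' @return list with \code{best_params}, \code{best_f1}, \code{results}
#'   (one row per combination) and \code{model} (refit on all data).
#' @export
grid_search <- function(table, family, grid, k = 10, seed = 1) {
  if (length(grid) == 0 || any(lengths(grid) == 0))
    stopf("grid must contain at least one value per key")
  bad <- setdiff(names(grid), FAMILY_PARAMS[[family]])
  if (length(bad))
    stopf("grid key(s) %s not supported by family '%s'",
          paste(bad, collapse = ", "), family)
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  f1 <- vapply(seq_len(nrow(combos)), function(i) {
    cross_validate(table, family, k = k, seed = seed,
                   params = as.list(combos[i, , drop = FALSE]))$mean_f1
  }, numeric(1))
  best <- which.max(f1)  # first maximum: deterministic tie-break
  best_params <- as.list(combos[best, , drop = FALSE])
  list(best_params = best_params, best_f1 = f1[best],
       results = cbind(combos, mean_f1 = f1),
       model = fit_classifier(table, family, best_params))
}

#' ROC curve, AUC and operating point
#'
#' The ROC is traced over all score thresholds; the AUC is computed by the
#' trapezoid rule, and sensitivity/specificity are reported at the default
#' 0.5 operating point (a score >= 0.5 predicts metastatic).
#'
#' @param scores numeric scores (probability of metastatic), or a fitted
#'   model, in which case \code{labels} must be the validation
#'   \code{feature_table}.
#' @param labels character labels, or the validation table.
#' @param positive positive class.
#' @return an object of class \code{roc_report}: \code{points} (data frame
#'   fpr, tpr, threshold), \code{auc}, \code{sensitivity},
#'   \code{specificity}.
#' @export
compute_roc <- function(scores, labels, positive = "metastatic") {
  if (inherits(scores, "emtseek_model") || inherits(scores, "ann_model")) {
    stopifnot(inherits(labels, "feature_table"))
    table <- labels
    scores <- predict(scores, table, type = "prob")
    labels <- table$label
  }
  y <- labels == positive
  if (all(y) || !any(y))
    stopf("ROC undefined: validation set contains a single class")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !y) / sum(!y), tpr = sum(pred & y) / sum(y))
  }, numeric(2)))
  points <- data.frame(fpr = pts[, "fpr"], tpr = pts[, "tpr"],
                       threshold = thr)
  auc <- sum(diff(points$fpr) *
               (head(points$tpr, -1) + points$tpr[-1]) / 2)
  pred05 <- scores >= 0.5
  structure(list(points = points, auc = auc,
                 sensitivity = sum(pred05 & y) / sum(y),
                 specificity = sum(!pred05 & !y) / sum(!y)),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("<roc_report> AUC = %.3f; at 0.5: sensitivity %.3f, specificity %.3f\n",
              x$auc, x$sensitivity, x$specificity))
  invisible(x)
}

#' Plot a ROC curve
#' @param x a \code{roc_report}.
#' @param path optional PNG path.
#' @param ... ignored.
#' @export
plot.roc_report <- function(x, path = NULL, ...) {
  if (!is.null(path)) {
    png(path, width = 500, height = 500)
    on.exit(dev.off(), add = TRUE)
  }
  plot(x$points$fpr, x$points$tpr, type = "l", xlab = "1 - specificity",
       ylab = "sensitivity", main = sprintf("AUC = %.3f", x$auc))
  abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Majority-vote slide-level prediction
#'
#' Predicts each of a slide's imaging fields independently and returns the
#' majority label over the pool (10 fields by convention). An even split
#' is resolved by the mean predicted probability: metastatic iff it is at
#' least 0.5.
#'
#' @param model a fitted classifier, or a function mapping the field table
#'   to a numeric vector of metastatic probabilities.
#' @param fields \code{feature_table} (or feature matrix) of the slide's
#'   fields.
#' @param n expected number of fields; a differing pool size is accepted
#'   with a warning.
#' @return an object of class \code{slide_prediction}: \code{label},
#'   \code{votes} (named tally), \code{mean_prob}, \code{field_probs}.
#' @export
predict_slide <- function(model, fields, n = 10) {
  probs <- if (is.function(model)) model(fields)
           else predict(model, fields, type = "prob")
  if (length(probs) == 0) stopf("no fields supplied for slide prediction")
  if (length(probs) != n)
    warnf("slide pooled %d fields (expected %d)", length(probs), n)
  pred <- probs >= 0.5
  votes <- c(metastatic = sum(pred), non_metastatic = sum(!pred))
  label <- if (votes["metastatic"] > votes["non_metastatic"]) "metastatic"
           else if (votes["metastatic"] < votes["non_metastatic"]) "non_metastatic"
           else if (mean(probs) >= 0.5) "metastatic" else "non_metastatic"
  structure(list(label = label, votes = votes, mean_prob = mean(probs),
                 field_probs = probs),
            class = "slide_prediction")
}

#' @export
print.slide_prediction <- function(x, ...) {
  cat(sprintf("<slide_prediction> %s (votes %d/%d, mean prob %.3f)\n",
              x$label, x$votes["metastatic"], sum(x$votes), x$mean_prob))
  invisible(x)
}
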