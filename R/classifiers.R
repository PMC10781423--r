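#' Classifier families for field-level metastasis prediction
#'
#' One common fit/predict surface over the classical supervised families:
#' logistic regression, support-vector machine, naive Bayes, k-nearest
#' neighbours, decision tree, and the feed-forward neural network of
#' \code{\link{train_ann}}. Every model predicts the probability that a
#' field comes from a metastatic tumour; the positive class is
#' \code{"metastatic"} throughout.
#'
#' @format character vector of family names.
#' @export
CLASSIFIER_FAMILIES <- c("logistic", "svm", "naive_bayes", "knn", "tree",
                         "ann")

# hyperparameters each family accepts in fit_classifier()/grid_search()
FAMILY_PARAMS <- list(
  logistic = character(0),
  svm = c("cost", "gamma", "kernel"),
  naive_bayes = c("laplace"),
  knn = c("k"),
  tree = c("cp", "maxdepth"),
  ann = c("hidden", "epochs", "lr", "batch_size", "seed")
)

#' Fit one classifier family
#'
#' @param table a \code{feature_table} (or list with \code{x} and
#'   \code{label}).
#' @param family one of \code{\link{CLASSIFIER_FAMILIES}}.
#' @param params named list of family hyperparameters (see
#'   \code{grid_search} docs for the supported keys per family).
#' @return an object of class \code{emtseek_model}.
#' @export
fit_classifier <- function(table, family = CLASSIFIER_FAMILIES,
                           params = list()) {
  family <- match.arg(family)
  bad <- setdiff(names(params), FAMILY_PARAMS[[family]])
  if (length(bad))
    stopf("hyperparameter(s) %s not supported by family '%s'",
          paste(bad, collapse = ", "), family)
  x <- table$x
  y <- factor(table$label, levels = c("non_metastatic", "metastatic"))
  if (nlevels(droplevels(y)) < 2) stopf("training data has a single class")
  keep <- which(apply(x, 2, sd) > 0)
  if (length(keep) == 0) stopf("all features are constant")
  xk <- x[, keep, drop = FALSE]

  if (family == "ann") {
    fit <- train_ann(structure(list(x = xk, label = as.character(y),
                                    slide_id = table$slide_id,
                                    field_id = table$field_id,
                                    mode = table$mode %||% "unknown"),
                               class = "feature_table"),
                     epochs = params$epochs %||% 14,
                     hidden = params$hidden %||% c(64, 32),
                     lr = params$lr %||% 0.05,
                     batch_size = params$batch_size %||% 16,
                     seed = params$seed %||% 1,
                     val_fraction = 0)
    return(structure(list(family = family, fit = fit, keep = keep),
                     class = "emtseek_model"))
  }

  center <- colMeans(xk)
  scale <- pmax(apply(xk, 2, sd), 1e-8)
  xs <- mlp_scale(xk, center, scale)
  colnames(xs) <- paste0("f", seq_len(ncol(xs)))
  fit <- switch(family,
    logistic = {
      d <- data.frame(.y = as.integer(y == "metastatic"), xs)
      suppressWarnings(glm(.y ~ ., data = d, family = binomial()))
    },
    svm = e1071::svm(xs, y, kernel = params$kernel %||% "radial",
                     cost = params$cost %||% 1,
                     gamma = params$gamma %||% (1 / ncol(xs)),
                     probability = TRUE),
    naive_bayes = {
      nb <- e1071::naiveBayes(xs, y, laplace = params$laplace %||% 0)
      # floor within-class sds so a feature constant inside one class
      # cannot produce degenerate densities
      nb$tables <- lapply(nb$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], 1e-6); tb
      })
      nb
    },
    knn = list(train = xs, y = y, k = params$k %||% 5),
    tree = {
      d <- data.frame(.y = y, xs)
      rpart::rpart(.y ~ ., data = d, method = "class",
                   cp = params$cp %||% 0.01,
                   maxdepth = params$maxdepth %||% 30)
    })
  structure(list(family = family, fit = fit, keep = keep,
                 center = center, scale = scale),
            class = "emtseek_model")
}

#' Predict the probability that fields are metastatic
#'
#' @param object an \code{emtseek_model}.
#' @param newdata a \code{feature_table} or feature matrix.
#' @param type \code{"prob"} (probability of the metastatic class) or
#'   \code{"class"}.
#' @param ... ignored.
#' @export
predict.emtseek_model <- function(object, newdata,
                                  type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "feature_table")) newdata$x else newdata
  xk <- x[, object$keep, drop = FALSE]
  p <- if (object$family == "ann") {
    predict(object$fit, xk, type = "prob")
  } else {
    xs <- mlp_scale(xk, object$center, object$scale)
    colnames(xs) <- paste0("f", seq_len(ncol(xs)))
    switch(object$family,
      logistic = as.numeric(predict(object$fit,
                                    data.frame(xs), type = "response")),
      svm = {
        pr <- predict(object$fit, xs, probability = TRUE)
        attr(pr, "probabilities")[, "metastatic"]
      },
      naive_bayes = predict(object$fit, xs, type = "raw")[, "metastatic"],
      knn = {
        pr <- class::knn(object$fit$train, xs, object$fit$y,
                         k = object$fit$k, prob = TRUE)
        win <- attr(pr, "prob")
        ifelse(pr == "metastatic", win, 1 - win)
      },
      tree = predict(object$fit, data.frame(xs),
                     type = "prob")[, "metastatic"])
  }
  p <- as.numeric(p)
  if (type == "prob") p
  else ifelse(p >= 0.5, "metastatic", "non_metastatic")
}

#' @export
print.emtseek_model <- function(x, ...) {
  cat(sprintf("<emtseek_model> family = %s, %d features\n", x$family,
              length(x$keep)))
  invisible(x)
}
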