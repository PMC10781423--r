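# Feed-forward neural network for field-level metastasis prediction:
# fully-connected layers with rectifier activations, a logistic output
# unit, cross-entropy loss, and seeded mini-batch gradient descent with
# momentum. Small enough to train on a laptop; records per-epoch traces.

mlp_init <- function(n_in, hidden) {
  sizes <- c(n_in, hidden, 1L)
  lapply(seq_len(length(sizes) - 1), function(l) {
    list(W = matrix(rnorm(sizes[l] * sizes[l + 1]) * sqrt(2 / sizes[l]),
                    nrow = sizes[l]),
         b = rep(0, sizes[l + 1]))
  })
}

mlp_forward <- function(layers, x) {
  acts <- list(x)
  n_l <- length(layers)
  for (l in seq_len(n_l)) {
    z <- acts[[l]] %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(x), length(layers[[l]]$b), byrow = TRUE)
    acts[[l + 1]] <- if (l < n_l) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  acts
}

mlp_loss_acc <- function(prob, y) {
  eps <- 1e-10
  p <- pmin(pmax(prob, eps), 1 - eps)
  c(loss = -mean(y * log(p) + (1 - y) * log(1 - p)),
    acc = mean((prob >= 0.5) == (y == 1)))
}

mlp_scale <- function(x, center, scale) {
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

#' Train the feed-forward neural network with per-epoch traces
#'
#' Architecture: two rectifier hidden layers (64 and 32 units by default),
#' a logistic output, cross-entropy loss, seeded He initialisation, and
#' mini-batch gradient descent with momentum. Inputs are standardized
#' (centre/scale stored in the model). After every epoch the accuracy and
#' loss on the full training set and on the validation set are recorded,
#' mirroring per-epoch learning curves.
#'
#' @param table a \code{feature_table}, or a list \code{list(x, label)}.
#' @param epochs training epochs (14 by default).
#' @param hidden integer vector of hidden-layer sizes (every entry >= 1).
#' @param lr learning rate.
#' @param batch_size mini-batch size.
#' @param momentum momentum coefficient.
#' @param seed seed for initialisation and batch shuffling.
#' @param validation optional \code{feature_table} used for the validation
#'   trace; if absent and \code{val_fraction > 0}, a stratified slide-level
#'   split of \code{table} is used.
#' @param val_fraction fraction held out for the validation trace when no
#'   \code{validation} table is given.
#' @return an object of class \code{ann_model}: layers, scaling, and
#'   \code{history} (data frame epoch, train_loss, train_acc, val_loss,
#'   val_acc).
#' @export
train_ann <- function(table, epochs = 14, hidden = c(64, 32), lr = 0.05,
                      batch_size = 16, momentum = 0.9, seed = 1,
                      validation = NULL, val_fraction = 0.3) {
  if (any(hidden < 1) || length(hidden) < 1)
    stopf("every hidden layer needs at least one unit")
  if (epochs < 1) stopf("epochs must be >= 1")
  if (is.null(validation) && val_fraction > 0 &&
      inherits(table, "feature_table")) {
    parts <- split_train_validation(table, 1 - val_fraction, seed = seed)
    table <- parts$train; validation <- parts$validation
  }
  x <- table$x
  y <- as.integer(table$label == "metastatic")
  center <- colMeans(x)
  scale <- pmax(apply(x, 2, sd), 1e-8)
  xs <- mlp_scale(x, center, scale)
  has_val <- !is.null(validation)
  if (has_val) {
    xv <- mlp_scale(validation$x, center, scale)
    yv <- as.integer(validation$label == "metastatic")
  }

  local_seed(seed, {
    layers <- mlp_init(ncol(xs), hidden)
    vel <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
    n <- nrow(xs)
    history <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        acts <- mlp_forward(layers, xs[idx, , drop = FALSE])
        nb <- length(idx)
        # output delta for sigmoid + cross-entropy
        delta <- (acts[[length(acts)]] - y[idx]) / nb
        for (l in rev(seq_along(layers))) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
          }
          vel[[l]]$W <- momentum * vel[[l]]$W - lr * gW
          vel[[l]]$b <- momentum * vel[[l]]$b - lr * gb
          layers[[l]]$W <- layers[[l]]$W + vel[[l]]$W
          layers[[l]]$b <- layers[[l]]$b + vel[[l]]$b
        }
      }
      tr <- mlp_loss_acc(mlp_forward(layers, xs)[[length(layers) + 1]], y)
      if (!is.finite(tr["loss"]))
        stopf("non-finite training loss at epoch %d (lr = %g); reduce the learning rate",
              ep, lr)
      row <- data.frame(epoch = ep, train_loss = tr["loss"],
                        train_acc = tr["acc"],
                        val_loss = NA_real_, val_acc = NA_real_)
      if (has_val) {
        va <- mlp_loss_acc(mlp_forward(layers, xv)[[length(layers) + 1]], yv)
        row$val_loss <- va["loss"]; row$val_acc <- va["acc"]
      }
      history[[ep]] <- row
    }
    history <- do.call(rbind, history)
    rownames(history) <- NULL
    structure(list(layers = layers, center = center, scale = scale,
                   hidden = hidden, epochs = epochs, lr = lr,
                   batch_size = batch_size, seed = seed,
                   history = history,
                   feature_names = colnames(x)),
              class = c("ann_model", "emtseek_model"))
  })
}

#' @export
predict.ann_model <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "feature_table")) newdata$x else newdata
  xs <- mlp_scale(x, object$center, object$scale)
  p <- as.numeric(mlp_forward(object$layers, xs)[[length(object$layers) + 1]])
  if (type == "prob") p
  else ifelse(p >= 0.5, "metastatic", "non_metastatic")
}

#' @export
print.ann_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<ann_model> %d inputs -> %s -> 1, %d epochs\n",
              length(x$center), paste(x$hidden, collapse = "-"), x$epochs))
  cat(sprintf("  final train acc %.3f / loss %.3f", last$train_acc,
              last$train_loss))
  if (!is.na(last$val_acc))
    cat(sprintf(", validation acc %.3f / loss %.3f", last$val_acc,
                last$val_loss))
  cat("\n")
  invisible(x)
}

#' Plot per-epoch accuracy and loss traces
#'
#' @param x an \code{ann_model}.
#' @param path optional PNG path.
#' @param ... ignored.
#' @export
plot.ann_model <- function(x, path = NULL, ...) {
  if (!is.null(path)) {
    png(path, width = 900, height = 450)
    on.exit(dev.off(), add = TRUE)
  }
  h <- x$history
  op <- par(mfrow = c(1, 2))
  on.exit(par(op), add = TRUE, after = FALSE)  # restore before dev.off
  plot(h$epoch, h$train_acc, type = "l", ylim = c(0, 1), xlab = "epoch",
       ylab = "accuracy", col = "darkgreen")
  if (!all(is.na(h$val_acc))) lines(h$epoch, h$val_acc, col = "red")
  legend("bottomright", c("train", "validation"),
         col = c("darkgreen", "red"), lty = 1, bty = "n")
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       col = "blue",
       ylim = range(c(h$train_loss, h$val_loss), na.rm = TRUE))
  if (!all(is.na(h$val_loss))) lines(h$epoch, h$val_loss, col = "orange")
  legend("topright", c("train", "validation"),
         col = c("blue", "orange"), lty = 1, bty = "n")
  invisible(x)
}
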