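FEATURE_MODES <- c("cell_intensity", "pixel", "stroma_counts",
                   "tumour_counts", "gaussian_dummy")

# fixed-length descriptor of one field's background-subtracted per-cell
# grey levels: per channel a 16-bin histogram (proportions of cells, bins
# equal-width in log1p of the positive part), the mean and the max of the
# subtracted values; plus the field's cell count
intensity_descriptor <- function(d, thr, n_bins = 16) {
  breaks <- seq(0, log1p(GREY_MAX), length.out = n_bins + 1)
  out <- c()
  for (ch in MARKER_CHANNELS) {
    v <- d[[paste0("grey_", ch)]] - thr[[ch]]
    h <- hist(log1p(pmax(v, 0)), breaks = breaks, plot = FALSE)$counts
    out <- c(out,
             setNames(h / length(v), sprintf("%s_h%02d", ch, 1:n_bins)),
             setNames(c(mean(v), max(v)), paste0(ch, c("_mean", "_max"))))
  }
  c(out, n_cells = nrow(d))
}

# mean-pool a matrix to approximately pool_to x pool_to
mean_pool <- function(m, pool_to = 64) {
  fr <- ceiling(nrow(m) / pool_to); fc <- ceiling(ncol(m) / pool_to)
  ri <- (seq_len(nrow(m)) - 1L) %/% fr
  ci <- (seq_len(ncol(m)) - 1L) %/% fc
  pooled <- rowsum(m, ri)
  pooled <- t(rowsum(t(pooled), ci))
  counts <- tcrossprod(tabulate(ri + 1L), tabulate(ci + 1L))
  pooled / counts
}

new_feature_table <- function(x, label, field_id, slide_id, mode) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  rownames(x) <- field_id
  structure(list(x = x, label = label, field_id = field_id,
                 slide_id = slide_id, mode = mode),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d fields x %d features, mode = %s (%d metastatic)\n",
              nrow(x$x), ncol(x$x), x$mode, sum(x$label == "metastatic")))
  invisible(x)
}

#' @export
`[.feature_table` <- function(x, i) {
  new_feature_table(x$x[i, , drop = FALSE], x$label[i], x$field_id[i],
                    x$slide_id[i], x$mode)
}

#' Build the field-level feature matrix for metastasis prediction
#'
#' Converts quantified imaging data into one fixed-length feature vector
#' per field:
#' \describe{
#'   \item{\code{cell_intensity}}{from per-cell records: the background
#'     threshold is subtracted from each cell's FITC/CY3/CY5 grey level and
#'     the variable-length per-cell triplets are reduced, per channel, to a
#'     16-bin histogram (equal-width in log1p of the positive part,
#'     proportions of cells) plus mean and max, and the field cell count
#'     (3 x 18 + 1 = 55 features).}
#'   \item{\code{pixel}}{from rendered fields: each marker channel is
#'     mean-pooled to \code{pool_to x pool_to}, background-subtracted and
#'     flattened.}
#'   \item{\code{stroma_counts} / \code{tumour_counts}}{a single feature,
#'     the triple-positive cell count in that region, from field
#'     summaries.}
#'   \item{\code{gaussian_dummy}}{seeded i.i.d. standard-normal features, a
#'     chance-level baseline.}
#' }
#'
#' @param data per-cell records (cell_intensity), field summaries (count
#'   modes and gaussian_dummy), or a named list of \code{field_image}
#'   (pixel mode) whose names are field ids.
#' @param mode one of \code{"cell_intensity"}, \code{"pixel"},
#'   \code{"stroma_counts"}, \code{"tumour_counts"},
#'   \code{"gaussian_dummy"}.
#' @param manifest data frame with field_id, slide_id, label.
#' @param thresholds \code{\link{compute_thresholds}} result (intensity and
#'   pixel modes).
#' @param n_dummy_features,dummy_seed gaussian_dummy settings.
#' @param pool_to pixel-mode pooled resolution.
#' @return an object of class \code{feature_table}: feature matrix
#'   \code{x}, \code{label}, \code{field_id}, \code{slide_id}, \code{mode}.
#' @export
build_feature_matrix <- function(data, mode = FEATURE_MODES,
                                 manifest = NULL, thresholds = NULL,
                                 n_dummy_features = 10, dummy_seed = 1,
                                 pool_to = 64) {
  mode <- match.arg(mode)
  get_meta <- function(field_ids) {
    if (is.null(manifest)) stopf("a manifest (field_id, slide_id, label) is required")
    i <- match(field_ids, manifest$field_id)
    if (anyNA(i)) stopf("field(s) missing from manifest: %s",
                        paste(head(field_ids[is.na(i)]), collapse = ", "))
    manifest[i, , drop = FALSE]
  }
  thr <- if (inherits(thresholds, "threshold_set")) thresholds$thresholds
         else thresholds

  if (mode == "cell_intensity") {
    if (is.null(thr)) stopf("cell_intensity mode needs background thresholds")
    if (is.null(data$field_id)) stopf("cell records need a field_id column")
    if (nrow(data) == 0)
      stopf("fields with zero cells cannot be featurized (they cannot occur post-QC)")
    sp <- split(data, data$field_id)
    feats <- t(vapply(sp, intensity_descriptor, thr = thr,
                      numeric(3 * 18 + 1)))
    meta <- get_meta(names(sp))
    return(new_feature_table(feats, meta$label, names(sp), meta$slide_id,
                             mode))
  }
  if (mode == "pixel") {
    if (is.null(thr)) stopf("pixel mode needs background thresholds")
    if (!is.list(data) || is.data.frame(data))
      stopf("pixel mode needs a named list of field_image objects")
    feats <- t(vapply(data, function(f) {
      unlist(lapply(MARKER_CHANNELS, function(ch)
        as.numeric(mean_pool(f$channels[[ch]], pool_to) - thr[[ch]])))
    }, numeric(3 * pool_to^2)))
    meta <- get_meta(names(data))
    return(new_feature_table(feats, meta$label, names(data), meta$slide_id,
                             mode))
  }
  if (mode %in% c("stroma_counts", "tumour_counts")) {
    col <- if (mode == "stroma_counts") "stroma_triple" else "tumour_triple"
    if (is.null(data[[col]]))
      stopf("count mode needs field summaries with a %s column", col)
    meta <- get_meta(data$field_id)
    x <- matrix(data[[col]], ncol = 1,
                dimnames = list(NULL, "triple_positive_count"))
    return(new_feature_table(x, meta$label, data$field_id, meta$slide_id,
                             mode))
  }
  # gaussian_dummy: field ids / labels from summaries or manifest rows
  ids <- data$field_id %||% manifest$field_id
  meta <- get_meta(ids)
  x <- local_seed(dummy_seed,
                  matrix(rnorm(length(ids) * n_dummy_features),
                         nrow = length(ids)))
  colnames(x) <- sprintf("noise%02d", seq_len(n_dummy_features))
  new_feature_table(x, meta$label, ids, meta$slide_id, mode)
}

#' Stratified train/validation split
#'
#' Splits a feature table into training and validation partitions in a
#' given ratio, stratified by class. By default whole slides are assigned
#' to one partition (fields from one tumour never straddle the split,
#' preventing leakage); \code{by_slide = FALSE} reproduces a literal
#' field-level random split, which leaks slide identity across partitions.
#'
#' @param table a \code{feature_table}.
#' @param train_fraction fraction of units assigned to training.
#' @param seed split seed.
#' @param by_slide split whole slides (default) or individual fields.
#' @return list with \code{train} and \code{validation} feature tables.
#' @export
split_train_validation <- function(table, train_fraction = 0.7, seed = 1,
                                   by_slide = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must lie strictly between 0 and 1 (validation must be non-empty)")
  units <- if (by_slide) table$slide_id else table$field_id
  u <- unique(units)
  u_label <- table$label[match(u, units)]
  train_units <- local_seed(seed, {
    unlist(lapply(split(u, u_label), function(g) {
      n_tr <- round(train_fraction * length(g))
      sample(g, min(max(n_tr, 1), length(g)))
    }))
  })
  in_train <- units %in% train_units
  if (!any(in_train) || all(in_train))
    stopf("split produced an empty partition")
  tr <- table[in_train]; va <- table[!in_train]
  for (lv in unique(table$label)) {
    if (!lv %in% tr$label || !lv %in% va$label)
      stopf("class '%s' absent from one partition; use more slides or a different seed",
            lv)
  }
  list(train = tr, validation = va)
}
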