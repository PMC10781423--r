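#' Call cells positive for a gene by an expression threshold
#'
#' The cutoff is computed over all cells (not per group) and positivity is
#' strict: a cell is positive iff its normalized expression strictly
#' exceeds the cutoff. Rules: \code{"median"}, \code{"upper_quartile"}
#' (75th percentile), or a fixed value given as \code{"fixed:v"} or a
#' number.
#'
#' @param mat cells x genes numeric matrix (or an
#'   \code{\link{generate_expression_matrix}} result), gene names as
#'   column names.
#' @param gene gene to threshold.
#' @param rule threshold rule.
#' @param per_group optional factor; when supplied the cutoff is computed
#'   within each group instead of over all cells.
#' @return logical vector of per-cell calls, with the cutoff as attribute
#'   \code{"cutoff"}.
#' @export
threshold_positive <- function(mat, gene, rule = "median",
                               per_group = NULL) {
  if (inherits(mat, "expression_matrix")) mat <- mat$matrix
  if (!gene %in% colnames(mat)) stopf("gene '%s' absent from the matrix", gene)
  v <- mat[, gene]
  cutoff_of <- function(x) {
    if (is.numeric(rule)) return(rule)
    if (rule == "median") return(median(x))
    if (rule == "upper_quartile") return(unname(quantile(x, 0.75)))
    if (grepl("^fixed:", rule)) return(as.numeric(sub("^fixed:", "", rule)))
    stopf("unknown threshold rule '%s'", rule)
  }
  if (is.null(per_group)) {
    cutoff <- cutoff_of(v)
    calls <- v > cutoff
  } else {
    cutoff <- tapply(v, per_group, cutoff_of)
    calls <- v > cutoff[as.character(per_group)]
  }
  attr(calls, "cutoff") <- cutoff
  calls
}

#' Per-group triple-positive (co-expression) fractions
#'
#' Combines per-gene positivity calls by logical AND and reports, per
#' group, the number and fraction of cells positive for all genes.
#'
#' @param calls list of logical call vectors (one per gene, equal length),
#'   e.g. from \code{\link{threshold_positive}}.
#' @param groups per-cell group labels (e.g. tumour / non_tumour).
#' @return data frame: group, n_positive, n_cells, fraction.
#' @export
coexpression_fraction <- function(calls, groups) {
  if (!is.list(calls) || length(calls) < 1)
    stopf("calls must be a non-empty list of logical vectors")
  n <- unique(lengths(calls))
  if (length(n) != 1) stopf("call vectors differ in length")
  if (length(groups) != n) stopf("groups must have one label per cell")
  joint <- Reduce(`&`, calls)
  sp <- split(joint, groups)
  if (any(lengths(sp) == 0)) stopf("empty group")
  out <- do.call(rbind, lapply(names(sp), function(g) {
    data.frame(group = g, n_positive = sum(sp[[g]]),
               n_cells = length(sp[[g]]),
               fraction = mean(sp[[g]]))
  }))
  rownames(out) <- NULL
  out
}

#' Marker co-expression analysis of an expression matrix
#'
#' Convenience wrapper: thresholds each marker gene with the same rule and
#' returns per-group triple-positive fractions.
#'
#' @param mat expression matrix (or \code{expression_matrix} object).
#' @param groups per-cell labels; defaults to the object's labels.
#' @param genes the three marker genes.
#' @param rule threshold rule (see \code{\link{threshold_positive}}).
#' @return the \code{\link{coexpression_fraction}} table.
#' @export
coexpression_analysis <- function(mat, groups = NULL,
                                  genes = c("EPCAM", "VIM", "CD24"),
                                  rule = "median") {
  if (inherits(mat, "expression_matrix")) {
    groups <- groups %||% mat$labels
    mat <- mat$matrix
  }
  if (is.null(groups)) stopf("per-cell group labels are required")
  calls <- lapply(genes, function(g) threshold_positive(mat, g, rule))
  coexpression_fraction(calls, groups)
}
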