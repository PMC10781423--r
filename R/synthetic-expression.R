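#' Generate a synthetic single-cell expression matrix with planted marker
#' co-expression
#'
#' Emulates a normalized scRNA-seq matrix carrying the three protein-marker
#' genes (EPCAM, VIM, CD24) with a planted per-group rate of cells that
#' co-express all three. Each cell is either a planted co-expressing cell -
#' all three marker genes drawn well above any data-driven cutoff
#' (offset + Exp(1)) - or a background cell, which expresses at most two of
#' the three markers: one marker, chosen at random, is exactly zero and the
#' others are Exp(1). Under any threshold rule whose cutoff is positive
#' (median, upper quartile, or fixed > 0 on these data) a background cell
#' can never be called jointly positive, so the expected triple-positive
#' fraction per group equals the planted rate.
#'
#' This is a stylized co-expression structure, not a model of full
#' transcriptomes: marginal distributions, dropout and depth effects of
#' real scRNA-seq are out of scope.
#'
#' @param n_tumour,n_nontumour cells per group.
#' @param coexpression_rates numeric length 2 (tumour, non_tumour)
#'   probabilities that a cell is a planted co-expressing cell.
#' @param genes marker gene names (first three columns of the matrix).
#' @param n_extra_genes additional uninformative Exp(1) genes.
#' @param high_offset expression offset of planted cells.
#' @param seed integer seed.
#' @return an object of class \code{expression_matrix}: list with
#'   \code{matrix} (cells x genes, non-negative), \code{labels}
#'   (\code{"tumour"}/\code{"non_tumour"} per cell) and \code{planted}
#'   (logical, the ground-truth co-expressing cells).
#' @export
generate_expression_matrix <- function(n_tumour, n_nontumour,
                                       coexpression_rates =
                                         c(tumour = 0.12, non_tumour = 0.008),
                                       genes = c("EPCAM", "VIM", "CD24"),
                                       n_extra_genes = 20,
                                       high_offset = 8,
                                       seed = 1L) {
  if (n_tumour < 0 || n_nontumour < 0) stopf("cell counts must be >= 0")
  if (any(coexpression_rates < 0 | coexpression_rates > 1))
    stopf("coexpression rates must lie in [0, 1]")
  if (length(genes) != 3) stopf("exactly three marker genes are required")
  n <- n_tumour + n_nontumour
  labels <- c(rep("tumour", n_tumour), rep("non_tumour", n_nontumour))
  local_seed(seed, {
    rate <- ifelse(labels == "tumour", coexpression_rates[[1]],
                   coexpression_rates[[2]])
    planted <- rbinom(n, 1, rate) == 1
    m <- matrix(rexp(n * 3), nrow = n, dimnames = list(NULL, genes))
    zero_gene <- sample(3, n, replace = TRUE)
    m[cbind(seq_len(n), zero_gene)] <- 0
    if (any(planted))
      m[planted, ] <- high_offset + matrix(rexp(sum(planted) * 3),
                                           ncol = 3)
    if (n_extra_genes > 0) {
      extra <- matrix(rexp(n * n_extra_genes), nrow = n)
      colnames(extra) <- sprintf("GENE%03d", seq_len(n_extra_genes))
      m <- cbind(m, extra)
    }
    rownames(m) <- sprintf("cell_%05d", seq_len(n))
    structure(list(matrix = m, labels = labels, planted = planted,
                   genes = genes, seed = as.integer(seed)),
              class = "expression_matrix")
  })
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes (%d tumour, %d non-tumour), %d planted co-expressing\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$labels == "tumour"),
              sum(x$labels == "non_tumour"), sum(x$planted)))
  invisible(x)
}
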