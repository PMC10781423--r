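# complete a field-summary data frame: per-region proportions from counts.
# A region with zero cells has undefined proportions, reported as NA (never
# coerced to 0), and a default qc_pass of TRUE (QC is applied later).
finish_summary <- function(fc) {
  prop <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  fc$prop_tumour_triple <- prop(fc$tumour_triple, fc$n_tumour)
  fc$prop_tumour_double <- prop(fc$tumour_double, fc$n_tumour)
  fc$prop_stroma_triple <- prop(fc$stroma_triple, fc$n_stroma)
  fc$prop_stroma_double <- prop(fc$stroma_double, fc$n_stroma)
  if (is.null(fc$qc_pass)) fc$qc_pass <- TRUE
  rownames(fc) <- NULL
  fc
}

#' Summarize classified cells of one field
#'
#' Counts cells and triple/double positives per region and derives
#' per-region proportions. A region with no cells yields \code{NA}
#' proportions (missing, not zero).
#'
#' @param cells classified, region-assigned cell records
#'   (\code{\link{classify_cells}} output with a \code{region} column).
#' @param field_id identifier recorded in the summary.
#' @param slide_id optional slide identifier.
#' @return a one-row data frame: counts (\code{n_cells}, \code{n_tumour},
#'   \code{n_stroma}, \code{tumour_triple}, ...) and proportions
#'   (\code{prop_stroma_triple}, ...).
#' @export
summarize_field <- function(cells, field_id = "field", slide_id = NA) {
  if (is.null(cells$region) || is.null(cells$triple_positive))
    stopf("cells must be region-assigned and classified before summarizing")
  tum <- cells$region == "tumour"
  fc <- data.frame(slide_id = slide_id, field_id = field_id,
                   n_cells = nrow(cells),
                   n_tumour = sum(tum), n_stroma = sum(!tum),
                   tumour_triple = sum(cells$triple_positive[tum]),
                   tumour_double = sum(cells$double_positive[tum]),
                   stroma_triple = sum(cells$triple_positive[!tum]),
                   stroma_double = sum(cells$double_positive[!tum]))
  finish_summary(fc)
}

#' Field-level quality control
#'
#' Drops fields with fewer nucleated cells than \code{min_fraction} times
#' the median cell count (the median is computed per slide when a
#' \code{slide_id} column is present, otherwise over all fields), and any
#' field named in \code{exclude} (e.g. fields intersecting folded specimen
#' edges, supplied as a blacklist).
#'
#' @param summaries field-summary data frame with \code{n_cells} and
#'   \code{field_id}.
#' @param min_fraction fraction of the median cell count below which a
#'   field is excluded (0.2 by default).
#' @param exclude optional character vector of field_ids to drop.
#' @param return_all if \code{TRUE}, return every field with its
#'   \code{qc_pass} flag instead of only the retained ones.
#' @return the retained field summaries (or all, flagged).
#' @export
qc_filter_fields <- function(summaries, min_fraction = 0.2, exclude = NULL,
                             return_all = FALSE) {
  if (nrow(summaries) == 0) stopf("no fields to QC")
  if (min_fraction < 0) stopf("min_fraction must be >= 0")
  grp <- if (!is.null(summaries$slide_id) &&
             !all(is.na(summaries$slide_id))) summaries$slide_id
         else rep("all", nrow(summaries))
  med <- stats::ave(summaries$n_cells, grp, FUN = median)
  keep <- summaries$n_cells >= min_fraction * med
  if (!is.null(exclude)) keep <- keep & !(summaries$field_id %in% exclude)
  summaries$qc_pass <- keep
  dropped_all <- tapply(keep, grp, function(k) !any(k))
  if (any(dropped_all))
    stopf("all fields excluded by QC for slide(s): %s",
          paste(names(dropped_all)[dropped_all], collapse = ", "))
  if (return_all) summaries else summaries[keep, , drop = FALSE]
}

#' Quantify one field end to end
#'
#' Runs the full single-field chain: nucleus detection, dense-cloud
#' segmentation, region assignment, intensity extraction and positivity
#' calls, returning per-cell records and the field summary.
#'
#' @param field a \code{field_image}.
#' @param thresholds a \code{\link{compute_thresholds}} result.
#' @param cloud_params a \code{\link{dense_cloud_params}}.
#' @param field_id,slide_id identifiers for the outputs.
#' @param dilate_px measurement-mask dilation.
#' @return list with \code{cells} (classified cell records including
#'   field_id and region), \code{summary} (one-row data frame) and
#'   \code{mask} (the dense-cloud tumour mask).
#' @export
quantify_field <- function(field, thresholds,
                           cloud_params = dense_cloud_params(),
                           field_id = "field", slide_id = NA,
                           dilate_px = 2) {
  nuc <- detect_nuclei(field)
  mask <- build_dense_cloud(field, cloud_params)
  cells <- extract_intensities(field, nuc, dilate_px = dilate_px)
  cells <- assign_regions(cells, mask)
  cells <- classify_cells(cells, thresholds)
  cells <- cbind(field_id = field_id, slide_id = slide_id, cells)
  list(cells = cells,
       summary = summarize_field(cells, field_id, slide_id),
       mask = mask)
}

#' Quantify a rendered cohort
#'
#' Computes thresholds from the cohort's negative control, quantifies every
#' field, and applies field QC.
#'
#' @param cohort a \code{\link{generate_cohort}} result with
#'   \code{output = "images"}.
#' @param multiplier background-threshold multiplier.
#' @param min_fraction QC fraction of the median cell count.
#' @param cloud_params a \code{\link{dense_cloud_params}}.
#' @return list with \code{cells}, \code{summaries} (QC-flagged, all
#'   fields), \code{retained} (QC-passing summaries) and \code{thresholds}.
#' @export
quantify_cohort <- function(cohort, multiplier = 1.5, min_fraction = 0.2,
                            cloud_params = dense_cloud_params()) {
  stopifnot(inherits(cohort, "cohort"))
  if (cohort$output != "images")
    stopf("quantify_cohort needs a cohort generated with output = 'images'")
  thresholds <- compute_thresholds(cohort$control, multiplier = multiplier)
  out <- lapply(seq_len(nrow(cohort$manifest)), function(i) {
    fid <- cohort$manifest$field_id[i]
    quantify_field(cohort$fields[[fid]], thresholds,
                   cloud_params = cloud_params, field_id = fid,
                   slide_id = cohort$manifest$slide_id[i])
  })
  summaries <- do.call(rbind, lapply(out, `[[`, "summary"))
  summaries <- qc_filter_fields(summaries, min_fraction = min_fraction,
                                return_all = TRUE)
  list(cells = do.call(rbind, lapply(out, `[[`, "cells")),
       summaries = summaries,
       retained = summaries[summaries$qc_pass, , drop = FALSE],
       thresholds = thresholds)
}
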