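#' Extract per-cell marker grey levels
#'
#' For every detected nucleus, the grey level in each marker channel
#' (FITC/CD24, CY3/EpCAM, CY5/Vimentin) is the mean pixel value over the
#' cell's measurement mask: the nucleus mask dilated by \code{dilate_px}
#' pixels, capturing peri-nuclear membranous stain.
#'
#' @param field a \code{field_image}.
#' @param nuclei a \code{\link{detect_nuclei}} result, or a list with
#'   \code{masks} (linear pixel index vectors) and \code{centroids}.
#' @param dilate_px dilation of the nucleus mask used for measurement.
#' @return a data frame with one row per cell: \code{x}, \code{y},
#'   \code{grey_FITC}, \code{grey_CY3}, \code{grey_CY5}.
#' @export
extract_intensities <- function(field, nuclei, dilate_px = 2) {
  dims <- dim(field$channels$DAPI %||% field$channels[[1]])
  n <- length(nuclei$masks)
  out <- data.frame(x = nuclei$centroids$x %||% rep(NA_real_, n),
                    y = nuclei$centroids$y %||% rep(NA_real_, n))
  if (n == 0) {
    for (ch in MARKER_CHANNELS) out[[paste0("grey_", ch)]] <- numeric(0)
    return(out)
  }
  npix <- prod(dims)
  bad <- vapply(nuclei$masks,
                function(idx) any(idx < 1 | idx > npix), logical(1))
  masks <- nuclei$masks
  if (any(bad)) {
    warnf("%d cell mask(s) extend outside the image; clipped", sum(bad))
    masks[bad] <- lapply(masks[bad], function(idx) idx[idx >= 1 & idx <= npix])
  }
  if (dilate_px > 0) {
    lab <- matrix(0L, dims[1], dims[2])
    for (i in seq_len(n)) lab[masks[[i]]] <- i
    lab <- EBImage::imageData(EBImage::dilate(EBImage::Image(lab),
                                              disc_brush(dilate_px)))
    masks <- split(which(lab > 0), lab[lab > 0])[as.character(seq_len(n))]
  }
  for (ch in MARKER_CHANNELS) {
    m <- field$channels[[ch]]
    if (is.null(m)) stopf("channel %s missing from field", ch)
    out[[paste0("grey_", ch)]] <-
      vapply(masks, function(idx) mean(m[idx]), numeric(1))
  }
  out
}

#' Compute per-channel background thresholds from negative controls
#'
#' The threshold for each marker channel is
#' \code{multiplier x median} of the per-cell grey levels of the negative
#' control, pooled over all supplied control fields. The median is taken
#' over per-cell values (the null of the quantity the threshold is applied
#' to); set \code{measure = "pixel"} to use the per-pixel median of the raw
#' channel instead.
#'
#' @param controls a \code{field_image}, a list of them, or a data frame of
#'   control cells with \code{grey_FITC}, \code{grey_CY3}, \code{grey_CY5}
#'   columns.
#' @param multiplier background multiplier (1.5 by default).
#' @param measure \code{"cell"} (default) or \code{"pixel"}.
#' @param dilate_px measurement-mask dilation, as in
#'   \code{\link{extract_intensities}}.
#' @param source identifier recorded for provenance.
#' @return an object of class \code{threshold_set}: list with
#'   \code{thresholds} (named numeric: FITC, CY3, CY5), \code{multiplier},
#'   \code{medians}, \code{n_cells}, \code{source}.
#' @export
compute_thresholds <- function(controls, multiplier = 1.5,
                               measure = c("cell", "pixel"),
                               dilate_px = 2, source = "negative_control") {
  measure <- match.arg(measure)
  if (multiplier <= 0) stopf("multiplier must be positive")
  if (is.data.frame(controls)) {
    vals <- controls
    if (!all(paste0("grey_", MARKER_CHANNELS) %in% names(vals)))
      stopf("control data frame must have grey_FITC/grey_CY3/grey_CY5 columns")
    n_cells <- nrow(vals)
  } else {
    if (inherits(controls, "field_image")) controls <- list(controls)
    if (measure == "pixel") {
      meds <- vapply(MARKER_CHANNELS, function(ch) {
        median(unlist(lapply(controls, function(f) f$channels[[ch]])))
      }, numeric(1))
      ts <- structure(list(thresholds = multiplier * meds,
                           medians = meds, multiplier = multiplier,
                           measure = measure, n_cells = NA_integer_,
                           source = source), class = "threshold_set")
      return(ts)
    }
    vals <- do.call(rbind, lapply(controls, function(f) {
      extract_intensities(f, detect_nuclei(f), dilate_px = dilate_px)
    }))
    n_cells <- nrow(vals)
    if (n_cells == 0)
      stopf("no nucleated cells detected in the negative control")
  }
  if (n_cells == 0) stopf("negative control contains no cells")
  meds <- vapply(MARKER_CHANNELS,
                 function(ch) median(vals[[paste0("grey_", ch)]]),
                 numeric(1))
  structure(list(thresholds = multiplier * meds, medians = meds,
                 multiplier = multiplier, measure = measure,
                 n_cells = n_cells, source = source),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> multiplier %g x %s median of %s cells (%s)\n",
              x$multiplier, x$measure,
              ifelse(is.na(x$n_cells), "?", x$n_cells), x$source))
  print(round(x$thresholds, 2))
  invisible(x)
}

#' Call marker positivity and triple/double-positive status
#'
#' A cell is positive for a marker iff its grey level strictly exceeds the
#' channel threshold (ties at the threshold are negative). A triple
#' positive (EpCAM+Vim+CD24+, encoded 1) exceeds all three thresholds; a
#' double positive (EpCAM+Vim+CD24-) exceeds CY3 and CY5 but not FITC. The
#' two calls are mutually exclusive by construction.
#'
#' @param cells data frame with \code{grey_FITC}, \code{grey_CY3},
#'   \code{grey_CY5} columns.
#' @param thresholds a \code{\link{compute_thresholds}} result (or a named
#'   numeric vector of per-channel thresholds).
#' @return \code{cells} with logical \code{pos_FITC}, \code{pos_CY3},
#'   \code{pos_CY5} and integer \code{triple_positive},
#'   \code{double_positive} columns.
#' @export
classify_cells <- function(cells, thresholds) {
  thr <- if (inherits(thresholds, "threshold_set")) thresholds$thresholds
         else thresholds
  for (ch in MARKER_CHANNELS) {
    col <- paste0("grey_", ch)
    if (is.null(cells[[col]])) stopf("column %s missing from cell records", col)
    if (is.na(thr[[ch]] %||% NA)) stopf("no threshold for channel %s", ch)
    cells[[paste0("pos_", ch)]] <- cells[[col]] > thr[[ch]]
  }
  cells$triple_positive <- as.integer(cells$pos_FITC & cells$pos_CY3 &
                                        cells$pos_CY5)
  cells$double_positive <- as.integer(!cells$pos_FITC & cells$pos_CY3 &
                                        cells$pos_CY5)
  cells
}
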