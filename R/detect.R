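#' Detect nucleated cells in the DAPI channel
#'
#' Standard deterministic nucleus segmentation: Gaussian smoothing, Otsu
#' two-class intensity threshold, hole filling, watershed split of touching
#' nuclei on the distance map, and a minimum-area filter. Detection is
#' invariant to uniform rescaling of the DAPI channel because the channel
#' is min-max normalized before thresholding.
#'
#' @param field a \code{field_image} (the DAPI channel must be present).
#' @param smoothing_sigma Gaussian sigma in pixels.
#' @param min_area_px nuclei smaller than this many pixels are discarded.
#' @param tolerance watershed tolerance (grey-level depth between objects).
#' @return an object of class \code{nuclei}: list with \code{masks} (list of
#'   integer vectors of linear pixel indices, one disjoint mask per
#'   nucleus), \code{centroids} (data frame x, y in 0-based pixel-centred
#'   coordinates), \code{n} and \code{dim}.
#' @export
detect_nuclei <- function(field, smoothing_sigma = 2, min_area_px = 12,
                          tolerance = 1) {
  dapi <- field$channels$DAPI
  if (is.null(dapi)) stopf("field has no DAPI channel")
  rng <- range(dapi)
  empty <- function() {
    structure(list(masks = list(),
                   centroids = data.frame(x = numeric(0), y = numeric(0)),
                   n = 0L, dim = dim(dapi)), class = "nuclei")
  }
  if (diff(rng) == 0) {
    warnf("DAPI channel is flat; no nuclei detected")
    return(empty())
  }
  norm <- (dapi - rng[1]) / diff(rng)
  sm <- EBImage::gblur(EBImage::Image(norm), sigma = smoothing_sigma)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  bw <- EBImage::fillHull(sm > thr)
  lab <- EBImage::watershed(EBImage::distmap(bw), tolerance = tolerance)
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0) {
    warnf("no nuclei found above the automatic DAPI threshold")
    return(empty())
  }
  pix <- which(lab > 0)
  by_lab <- split(pix, lab[pix])
  by_lab <- by_lab[lengths(by_lab) >= min_area_px]
  if (length(by_lab) == 0) {
    warnf("all detected nuclei below min_area_px")
    return(empty())
  }
  h <- nrow(dapi)
  cents <- t(vapply(by_lab, function(idx) {
    rows <- (idx - 1L) %% h + 1L
    cols <- (idx - 1L) %/% h + 1L
    c(x = mean(cols) - 1, y = mean(rows) - 1)
  }, numeric(2)))
  structure(list(masks = unname(by_lab),
                 centroids = data.frame(x = cents[, "x"], y = cents[, "y"]),
                 n = length(by_lab), dim = dim(dapi)),
            class = "nuclei")
}

#' @export
print.nuclei <- function(x, ...) {
  cat(sprintf("<nuclei> %d detected in a %d x %d px field\n",
              x$n, x$dim[2], x$dim[1]))
  invisible(x)
}
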