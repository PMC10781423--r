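#' Parameters for dense-cloud tumour-body segmentation
#'
#' The tumour body is delimited by a "dense cloud" of a reference marker:
#' the cohesive region where smoothed EpCAM (CY3) - or, for specimens
#' segmented on the mesenchymal side, Vimentin (CY5) - intensity is high.
#' The mask is built by Gaussian smoothing, intensity cutoff, morphological
#' closing, dilation, and removal of small components. The small-component
#' filter is what keeps a single disseminating marker-positive cell in the
#' stroma from being absorbed into the tumour mask, so it can be counted as
#' stromal.
#'
#' @param reference_channel \code{"CY3"} (EpCAM dense cloud) or
#'   \code{"CY5"} (Vimentin dense cloud).
#' @param smoothing_sigma_px Gaussian sigma converting discrete stained
#'   cells into a smooth density.
#' @param intensity_cutoff \code{"auto"} (Otsu two-class cutoff on the
#'   smoothed channel) or a numeric grey level.
#' @param closing_radius_px closing radius; bridges gaps between
#'   neighbouring tumour cells so the body becomes one solid region.
#' @param dilation_radius_px final dilation of the mask.
#' @param min_component_area_px connected components smaller than this are
#'   dropped (isolated stromal cells).
#' @param min_component_fraction components smaller than this fraction of
#'   the largest component are also dropped: the tumour body is the
#'   dominant cohesive region, so satellite blobs of scattered stromal
#'   marker-positive cells are excluded at any field scale.
#' @return an object of class \code{dense_cloud_params}.
#' @export
dense_cloud_params <- function(reference_channel = c("CY3", "CY5"),
                               smoothing_sigma_px = 10,
                               intensity_cutoff = "auto",
                               closing_radius_px = 16,
                               dilation_radius_px = 4,
                               min_component_area_px = 3000,
                               min_component_fraction = 0.25) {
  reference_channel <- match.arg(reference_channel)
  if (smoothing_sigma_px < 0) stopf("smoothing sigma must be >= 0")
  if (closing_radius_px < 0 || dilation_radius_px < 0)
    stopf("morphological radii must be >= 0")
  structure(list(reference_channel = reference_channel,
                 smoothing_sigma_px = smoothing_sigma_px,
                 intensity_cutoff = intensity_cutoff,
                 closing_radius_px = closing_radius_px,
                 dilation_radius_px = dilation_radius_px,
                 min_component_area_px = min_component_area_px,
                 min_component_fraction = min_component_fraction),
            class = "dense_cloud_params")
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
}

#' Build the dense-cloud tumour-body mask
#'
#' @param field a \code{field_image}.
#' @param params a \code{\link{dense_cloud_params}}.
#' @return a logical height x width matrix; \code{TRUE} marks the tumour
#'   body.
#' @export
build_dense_cloud <- function(field, params = dense_cloud_params()) {
  ch <- field$channels[[params$reference_channel]]
  if (is.null(ch)) stopf("reference channel %s missing",
                         params$reference_channel)
  sm <- ch
  if (params$smoothing_sigma_px > 0)
    sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(ch),
                                            sigma = params$smoothing_sigma_px))
  if (identical(params$intensity_cutoff, "auto")) {
    rng <- range(sm)
    if (diff(rng) == 0) {
      warnf("reference channel is flat; dense cloud is empty")
      return(matrix(FALSE, nrow(ch), ncol(ch)))
    }
    cutoff <- EBImage::otsu(EBImage::Image((sm - rng[1]) / diff(rng)),
                            range = c(0, 1)) * diff(rng) + rng[1]
  } else {
    cutoff <- params$intensity_cutoff
    if (cutoff > max(sm)) {
      warnf("intensity cutoff above channel maximum; dense cloud is empty")
      return(matrix(FALSE, nrow(ch), ncol(ch)))
    }
  }
  bw <- EBImage::Image(sm > cutoff)
  if (params$closing_radius_px > 0)
    bw <- EBImage::closing(bw, disc_brush(params$closing_radius_px))
  if (params$dilation_radius_px > 0)
    bw <- EBImage::dilate(bw, disc_brush(params$dilation_radius_px))
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    floor_area <- max(params$min_component_area_px,
                      (params$min_component_fraction %||% 0) * max(areas))
    drop <- which(areas < floor_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  mask <- lab > 0
  dim(mask) <- dim(ch)
  mask
}

#' Assign detected cells to the tumour or stromal region
#'
#' A cell is tumour iff the pixel containing its centroid is set in the
#' dense-cloud mask (a centroid exactly on the mask border counts as inside
#' if its containing pixel is set); every cell receives exactly one label.
#'
#' @param cells a data frame with 0-based centroid columns \code{x},
#'   \code{y} (e.g. from \code{\link{extract_intensities}}).
#' @param mask logical tumour-body matrix from
#'   \code{\link{build_dense_cloud}}.
#' @return \code{cells} with a \code{region} column
#'   (\code{"tumour"}/\code{"stroma"}).
#' @export
assign_regions <- function(cells, mask) {
  if (nrow(cells) == 0) {
    cells$region <- character(0)
    return(cells)
  }
  px <- centroid_pixel(cells$x, cells$y)
  px[, "row"] <- pmin(pmax(px[, "row"], 1L), nrow(mask))
  px[, "col"] <- pmin(pmax(px[, "col"], 1L), ncol(mask))
  inside <- mask[px]
  cells$region <- ifelse(inside, "tumour", "stroma")
  cells
}
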