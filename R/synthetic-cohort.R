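#' Specification for a synthetic slide cohort
#'
#' Emulates the study design of a stratified primary-tumour cohort: two
#' groups of slides (metastatic / non-metastatic), a fixed number of
#' tumour-stroma boundary fields per slide, and a group-specific density of
#' disseminating triple-positive (EpCAM+Vim+CD24+) cells in the stroma.
#' Slide-to-slide biological variability is modelled by a lognormal
#' multiplier on the group density. Double-positive (EpCAM+Vim+CD24-) cells
#' are planted at the same density in both groups: in the source biology
#' they do not discriminate metastatic status.
#'
#' @param n_metastatic_slides,n_nonmetastatic_slides slides per group.
#' @param fields_per_slide imaging fields per slide.
#' @param met_stromal_triple_density,nonmet_stromal_triple_density planted
#'   triple-positive cells per 1000 stromal cells in each group.
#' @param double_positive_density planted double-positive cells per 1000
#'   stromal cells (both groups).
#' @param slide_density_cv lognormal sd (on the log scale) of the per-slide
#'   density multiplier.
#' @param field a \code{\link{field_spec}} template used for every field;
#'   its planted densities are overridden per slide.
#' @param n_control_cells nucleated cells measured on the cohort's
#'   negative-control slide.
#' @param seed integer seed.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_metastatic_slides = 12,
                        n_nonmetastatic_slides = 12,
                        fields_per_slide = 10,
                        met_stromal_triple_density = 20,
                        nonmet_stromal_triple_density = 1,
                        double_positive_density = 10,
                        slide_density_cv = 0.25,
                        field = field_spec(),
                        n_control_cells = 300,
                        seed = 1L) {
  if (n_metastatic_slides < 1 || n_nonmetastatic_slides < 1)
    stopf("each group needs at least one slide")
  if (fields_per_slide < 1) stopf("fields_per_slide must be >= 1")
  if (met_stromal_triple_density < 0 || nonmet_stromal_triple_density < 0 ||
      double_positive_density < 0)
    stopf("densities must be non-negative")
  structure(list(n_metastatic_slides = as.integer(n_metastatic_slides),
                 n_nonmetastatic_slides = as.integer(n_nonmetastatic_slides),
                 fields_per_slide = as.integer(fields_per_slide),
                 met_stromal_triple_density = met_stromal_triple_density,
                 nonmet_stromal_triple_density = nonmet_stromal_triple_density,
                 double_positive_density = double_positive_density,
                 slide_density_cv = slide_density_cv,
                 field = field,
                 n_control_cells = as.integer(n_control_cells),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# per-cell measurement noise of a background (non-stained) channel: the
# extracted value is a mean over ~pi*(r+2)^2 pixels of the background
measurement_se <- function(fs) {
  fs$background_sd / sqrt(pi * (fs$nucleus_radius_px + 2)^2)
}

# draw the observed per-cell grey level table for one field, mirroring what
# extract_intensities() produces on a rendered field
draw_field_cells <- function(fs, n_triple, n_double) {
  n_vim <- fs$n_stroma_cells - n_triple - n_double
  cls <- c(rep("epithelial", fs$n_tumour_cells),
           rep("triple_pos", n_triple), rep("double_pos", n_double),
           rep("vim_only", n_vim))
  n <- length(cls)
  se <- measurement_se(fs)
  grey <- sapply(MARKER_CHANNELS, function(ch) {
    pos <- vapply(cls, function(k) ch %in% CLASS_MARKERS[[k]], logical(1))
    v <- fs$background_mean + rnorm(n, 0, se)
    v[pos] <- fs$channel_gains[[ch]] * exp(rnorm(sum(pos), 0, fs$gain_cv))
    pmax(v, 0)
  })
  data.frame(region = ifelse(cls == "epithelial", "tumour", "stroma"),
             class = cls,
             grey_FITC = grey[, "FITC"], grey_CY3 = grey[, "CY3"],
             grey_CY5 = grey[, "CY5"])
}

#' Generate a labelled synthetic cohort
#'
#' Produces a two-group cohort of slides with per-field ground truth at one
#' of three fidelity levels:
#' \describe{
#'   \item{\code{"counts"}}{only the planted per-field cell and
#'     triple/double-positive counts are drawn - the statistical layer used
#'     for large simulation studies (e.g. type-I-error calibration).}
#'   \item{\code{"cells"}}{per-cell grey-level tables as the imaging
#'     pipeline would extract them, plus a negative-control cell table -
#'     the layer used for classifier experiments at cohort scale.}
#'   \item{\code{"images"}}{fully rendered \code{field_image} objects (and a
#'     rendered negative control); the pixel-level path, intended for small
#'     numbers of fields.}
#' }
#' All levels share the same hierarchical structure: a per-slide density
#' drawn lognormally around the group density, then per-field binomial
#' planting.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param output fidelity level, see above.
#' @return an object of class \code{cohort}: list with \code{manifest}
#'   (slide_id, field_id, label), \code{slides} (per-slide label and drawn
#'   density), and depending on \code{output}: \code{field_counts} (data
#'   frame), or \code{cells} (per-cell data frame with field_id, slide_id)
#'   plus \code{control_cells}, or \code{fields} (named list of
#'   \code{field_image}) plus \code{control}.
#' @export
generate_cohort <- function(spec,
                            output = c("cells", "counts", "images")) {
  output <- match.arg(output)
  stopifnot(inherits(spec, "cohort_spec"))
  n_slides <- spec$n_metastatic_slides + spec$n_nonmetastatic_slides
  labels <- c(rep("metastatic", spec$n_metastatic_slides),
              rep("non_metastatic", spec$n_nonmetastatic_slides))
  slide_ids <- sprintf("slide_%02d", seq_len(n_slides))
  fs <- spec$field

  slides <- local_seed(spec$seed, {
    base <- ifelse(labels == "metastatic",
                   spec$met_stromal_triple_density,
                   spec$nonmet_stromal_triple_density)
    data.frame(slide_id = slide_ids, label = labels,
               stromal_triple_density =
                 base * exp(rnorm(n_slides, 0, spec$slide_density_cv)))
  })

  manifest <- do.call(rbind, lapply(seq_len(n_slides), function(i) {
    data.frame(slide_id = slide_ids[i],
               field_id = sprintf("%s_f%03d", slide_ids[i],
                                  seq_len(spec$fields_per_slide)),
               label = labels[i])
  }))

  res <- list(manifest = manifest, slides = slides, spec = spec,
              output = output)

  field_seed <- function(i, j) derive_seed(spec$seed, i * 1000 + j)

  if (output == "counts") {
    rows <- lapply(seq_len(n_slides), function(i) {
      dens <- min(slides$stromal_triple_density[i], 1000)
      do.call(rbind, lapply(seq_len(spec$fields_per_slide), function(j) {
        local_seed(field_seed(i, j), {
          n_tp <- rbinom(1, fs$n_stroma_cells, dens / 1000)
          n_dp <- rbinom(1, fs$n_stroma_cells,
                         spec$double_positive_density / 1000)
          data.frame(slide_id = slide_ids[i],
                     field_id = sprintf("%s_f%03d", slide_ids[i], j),
                     label = slides$label[i],
                     n_cells = fs$n_tumour_cells + fs$n_stroma_cells,
                     n_tumour = fs$n_tumour_cells,
                     n_stroma = fs$n_stroma_cells,
                     tumour_triple = 0L, tumour_double = 0L,
                     stroma_triple = n_tp,
                     stroma_double = min(n_dp, fs$n_stroma_cells - n_tp))
        })
      }))
    })
    res$field_counts <- do.call(rbind, rows)
    rownames(res$field_counts) <- NULL
    return(structure(res, class = "cohort"))
  }

  if (output == "cells") {
    rows <- lapply(seq_len(n_slides), function(i) {
      dens <- min(slides$stromal_triple_density[i], 1000)
      do.call(rbind, lapply(seq_len(spec$fields_per_slide), function(j) {
        local_seed(field_seed(i, j), {
          n_tp <- rbinom(1, fs$n_stroma_cells, dens / 1000)
          n_dp <- rbinom(1, fs$n_stroma_cells,
                         spec$double_positive_density / 1000)
          n_dp <- min(n_dp, fs$n_stroma_cells - n_tp)
          cells <- draw_field_cells(fs, n_tp, n_dp)
          cbind(field_id = sprintf("%s_f%03d", slide_ids[i], j),
                slide_id = slide_ids[i], cells)
        })
      }))
    })
    res$cells <- do.call(rbind, rows)
    rownames(res$cells) <- NULL
    res$control_cells <- local_seed(derive_seed(spec$seed, 999983), {
      se <- measurement_se(fs)
      n <- spec$n_control_cells
      data.frame(field_id = "control_f001", slide_id = "control",
                 region = "stroma", class = "negative",
                 grey_FITC = pmax(fs$background_mean + rnorm(n, 0, se), 0),
                 grey_CY3 = pmax(fs$background_mean + rnorm(n, 0, se), 0),
                 grey_CY5 = pmax(fs$background_mean + rnorm(n, 0, se), 0))
    })
    return(structure(res, class = "cohort"))
  }

  # output == "images"
  fields <- list()
  for (i in seq_len(n_slides)) {
    dens <- min(slides$stromal_triple_density[i], 1000)
    for (j in seq_len(spec$fields_per_slide)) {
      f <- fs
      f$planted_triple_positive_density <- dens
      f$planted_double_positive_density <- spec$double_positive_density
      f$seed <- field_seed(i, j)
      fields[[sprintf("%s_f%03d", slide_ids[i], j)]] <-
        generate_field(structure(f, class = "field_spec"))
    }
  }
  res$fields <- fields
  ctrl <- fs
  ctrl$seed <- derive_seed(spec$seed, 999983)
  res$control <- generate_negative_control(structure(ctrl,
                                                     class = "field_spec"))
  structure(res, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d slides (%d metastatic), %d fields, output = %s\n",
              nrow(x$slides), sum(x$slides$label == "metastatic"),
              nrow(x$manifest), x$output))
  invisible(x)
}

#' Ground-truth field summaries of a cohort
#'
#' Converts a cohort's planted truth into the per-field summary format of
#' \code{\link{summarize_field}}, bypassing the imaging pipeline. Available
#' for \code{"counts"} and \code{"cells"} cohorts.
#'
#' @param cohort a \code{cohort}.
#' @return a field-summary data frame (one row per field).
#' @export
truth_field_summaries <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (cohort$output == "counts") {
    fc <- cohort$field_counts
  } else if (cohort$output == "cells") {
    sp <- split(cohort$cells, cohort$cells$field_id)
    fc <- do.call(rbind, lapply(sp, function(d) {
      data.frame(slide_id = d$slide_id[1], field_id = d$field_id[1],
                 n_cells = nrow(d),
                 n_tumour = sum(d$region == "tumour"),
                 n_stroma = sum(d$region == "stroma"),
                 tumour_triple = sum(d$region == "tumour" &
                                       d$class == "triple_pos"),
                 tumour_double = sum(d$region == "tumour" &
                                       d$class == "double_pos"),
                 stroma_triple = sum(d$region == "stroma" &
                                       d$class == "triple_pos"),
                 stroma_double = sum(d$region == "stroma" &
                                       d$class == "double_pos"))
    }))
    fc <- fc[match(unique(cohort$cells$field_id), fc$field_id), ]
  } else {
    stopf("truth summaries need a 'counts' or 'cells' cohort")
  }
  finish_summary(fc)
}
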