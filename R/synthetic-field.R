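#' Specification for one synthetic imaging field
#'
#' Describes a four-colour field of view at a tumour-stroma boundary: a
#' cohesive tumour body of EpCAM-high epithelial cells on one side of an
#' irregular invasive front, Vimentin-high stromal cells on the other, and
#' rare planted disseminating cells in the stroma. Densities are given per
#' 1000 stromal cells; the number of planted cells in a field is drawn as
#' Binomial(n_stroma_cells, density / 1000).
#'
#' Grey levels use a 16-bit scale. Channel gains are the mean grey level of
#' a positive cell in its channel and must exceed \code{background_mean};
#' for positivity calls to be meaningful they should also exceed
#' 1.5 x \code{background_mean}, the default background threshold.
#'
#' @param width_px,height_px field dimensions in pixels.
#' @param n_tumour_cells,n_stroma_cells cells placed in each compartment.
#' @param planted_triple_positive_density planted EpCAM+Vim+CD24+
#'   (FITC+CY3+CY5) disseminating cells per 1000 stromal cells.
#' @param planted_double_positive_density planted EpCAM+Vim+CD24-
#'   (CY3+CY5, FITC-) cells per 1000 stromal cells.
#' @param channel_gains named vector (DAPI, FITC, CY3, CY5): mean grey level
#'   rendered on a positive cell's stain disc.
#' @param background_mean,background_sd mean and sd of the i.i.d. Gaussian
#'   background noise (clipped at 0, quantised to integer grey levels).
#' @param nucleus_radius_px nucleus disc radius; marker stain is rendered on
#'   a disc dilated 2 px beyond the nucleus (membranous-stain geometry).
#' @param gain_cv lognormal coefficient of variation of per-cell, per-channel
#'   staining intensity around the channel gain.
#' @param front_position horizontal position of the invasive front as a
#'   fraction of field width (tumour occupies the left side).
#' @param front_amplitude_px amplitude of the low-frequency perturbation of
#'   the front, creating an irregular invasive presentation.
#' @param stroma_margin_px minimum distance from the front at which
#'   disseminating (triple/double-positive) cells are planted; they model
#'   cells that have detached and moved into the stroma.
#' @param planted_min_sep_px minimum pairwise distance between planted
#'   disseminating cells: they occur as single scattered cells, not
#'   clusters.
#' @param seed integer seed; identical spec + seed gives bitwise-identical
#'   fields.
#' @return an object of class \code{field_spec} (a validated list).
#' @export
field_spec <- function(width_px = 512, height_px = 512,
                       n_tumour_cells = 150, n_stroma_cells = 180,
                       planted_triple_positive_density = 0,
                       planted_double_positive_density = 0,
                       channel_gains = c(DAPI = 8000, FITC = 6000,
                                         CY3 = 6000, CY5 = 6000),
                       background_mean = 200, background_sd = 60,
                       nucleus_radius_px = 5, gain_cv = 0.1,
                       front_position = 0.5, front_amplitude_px = 25,
                       stroma_margin_px = 80, planted_min_sep_px = 50,
                       seed = 1L) {
  spec <- list(width_px = as.integer(width_px),
               height_px = as.integer(height_px),
               n_tumour_cells = as.integer(n_tumour_cells),
               n_stroma_cells = as.integer(n_stroma_cells),
               planted_triple_positive_density =
                 planted_triple_positive_density,
               planted_double_positive_density =
                 planted_double_positive_density,
               channel_gains = channel_gains,
               background_mean = background_mean,
               background_sd = background_sd,
               nucleus_radius_px = nucleus_radius_px,
               gain_cv = gain_cv,
               front_position = front_position,
               front_amplitude_px = front_amplitude_px,
               stroma_margin_px = stroma_margin_px,
               planted_min_sep_px = planted_min_sep_px,
               seed = as.integer(seed))
  validate_field_spec(spec)
  structure(spec, class = "field_spec")
}

validate_field_spec <- function(spec) {
  if (spec$width_px <= 0 || spec$height_px <= 0)
    stopf("field dimensions must be positive (got %d x %d)",
          spec$width_px, spec$height_px)
  if (spec$n_tumour_cells < 0 || spec$n_stroma_cells < 0)
    stopf("cell counts must be non-negative")
  if (spec$planted_triple_positive_density < 0 ||
      spec$planted_double_positive_density < 0)
    stopf("planted densities must be non-negative")
  dens <- spec$planted_triple_positive_density +
    spec$planted_double_positive_density
  if (dens > 1000)
    stopf("planted densities (%g per 1000) imply more planted cells than stromal cells",
          dens)
  if (spec$background_sd < 0) stopf("background_sd must be >= 0")
  if (!all(ALL_CHANNELS %in% names(spec$channel_gains)))
    stopf("channel_gains must name all of %s",
          paste(ALL_CHANNELS, collapse = ", "))
  if (any(spec$channel_gains <= spec$background_mean))
    stopf("all channel gains must exceed background_mean")
  invisible(spec)
}

# horizontal position of the invasive front at (0-based) y; the tumour body
# is the half-plane x < front_x(y), perturbed by three low-frequency
# sinusoids so the boundary is irregular
front_curve <- function(spec, phases, y) {
  base <- spec$width_px * spec$front_position
  pert <- 0
  for (k in 1:3)
    pert <- pert + (spec$front_amplitude_px / k) *
      sin(2 * pi * k * y / spec$height_px + phases[k])
  base + pert
}

# jittered-grid candidate cell positions; the pitch guarantees a minimum
# centroid separation of pitch - 2*jitter, enough that stain discs
# (radius nucleus + 2) of distinct cells never overlap
candidate_sites <- function(spec) {
  r <- spec$nucleus_radius_px
  pitch <- 2 * (r + 2) + 10
  jitter <- 3
  margin <- r + 4
  gx <- seq(margin, spec$width_px - 1 - margin, by = pitch)
  gy <- seq(margin, spec$height_px - 1 - margin, by = pitch)
  g <- expand.grid(x = gx, y = gy)
  g$x <- g$x + runif(nrow(g), -jitter, jitter)
  g$y <- g$y + runif(nrow(g), -jitter, jitter)
  g
}

render_background <- function(spec) {
  n <- spec$height_px * spec$width_px
  if (spec$background_sd > 0) {
    v <- rnorm(n, spec$background_mean, spec$background_sd)
  } else {
    v <- rep(spec$background_mean, n)
  }
  matrix(round(pmin(pmax(v, 0), GREY_MAX)), nrow = spec$height_px)
}

# stain one cell: paint `value` on the disc of `radius` around the centroid
paint_disc <- function(mat, cx, cy, radius, value, spec) {
  idx <- disc_pixels(cx, cy, radius, spec$width_px, spec$height_px)
  mat[idx] <- round(min(max(value, 0), GREY_MAX))
  mat
}

cell_gain <- function(spec, channel) {
  spec$channel_gains[[channel]] * exp(rnorm(1, 0, spec$gain_cv))
}

# marker channels stained by each ground-truth cell class
CLASS_MARKERS <- list(
  epithelial = c("CY3"),
  vim_only   = c("CY5"),
  triple_pos = c("FITC", "CY3", "CY5"),
  double_pos = c("CY3", "CY5")
)

#' Generate one synthetic tumour-stroma boundary field
#'
#' Renders a four-channel field from a \code{\link{field_spec}}: a DAPI
#' nucleus disc for every cell, CY3 (EpCAM) on tumour epithelial cells, CY5
#' (Vimentin) on stromal cells, and all planted marker combinations on
#' disseminating cells, over Gaussian background noise. Ground truth (the
#' tumour-body mask and every cell's centroid, region and class) is
#' attached.
#'
#' @param spec a \code{\link{field_spec}}.
#' @return an object of class \code{field_image}: a list with
#'   \code{channels} (named list of height x width integer grey-level
#'   matrices for DAPI, FITC, CY3, CY5), \code{truth} (list with
#'   \code{tumour_mask}, a logical matrix, and \code{cells}, a data frame
#'   with columns x, y, region, class), \code{marker_map} and \code{spec}.
#' @export
generate_field <- function(spec) {
  validate_field_spec(spec)
  local_seed(spec$seed, {
    phases <- runif(3, 0, 2 * pi)
    sites <- candidate_sites(spec)
    front_at <- front_curve(spec, phases, sites$y)
    d <- sites$x - front_at           # > 0 in the stroma
    tumour_sites <- which(d < -1)
    stroma_sites <- which(d > 1)
    far_sites <- which(d >= spec$stroma_margin_px)

    if (length(tumour_sites) < spec$n_tumour_cells)
      stopf("field too small: %d tumour cells requested, %d sites available",
            spec$n_tumour_cells, length(tumour_sites))
    if (length(stroma_sites) < spec$n_stroma_cells)
      stopf("field too small: %d stromal cells requested, %d sites available",
            spec$n_stroma_cells, length(stroma_sites))

    n_triple <- rbinom(1, spec$n_stroma_cells,
                       spec$planted_triple_positive_density / 1000)
    n_double <- rbinom(1, spec$n_stroma_cells,
                       spec$planted_double_positive_density / 1000)
    if (n_triple + n_double > spec$n_stroma_cells)
      stopf("planted densities drew more disseminating cells (%d) than stromal cells (%d)",
            n_triple + n_double, spec$n_stroma_cells)
    if (n_triple + n_double > length(far_sites))
      stopf("not enough stromal sites beyond stroma_margin_px for %d planted cells",
            n_triple + n_double)

    tum <- sample(tumour_sites, spec$n_tumour_cells)
    # disseminating cells are single scattered cells: greedy selection of
    # far-stroma sites with pairwise separation >= planted_min_sep_px
    sep <- spec$planted_min_sep_px %||% 0
    planted <- integer(0)
    for (cand in sample(far_sites)) {
      if (length(planted) == n_triple + n_double) break
      if (length(planted) == 0 ||
          all((sites$x[cand] - sites$x[planted])^2 +
                (sites$y[cand] - sites$y[planted])^2 >= sep^2))
        planted <- c(planted, cand)
    }
    if (length(planted) < n_triple + n_double)
      stopf("could not place %d disseminating cells %g px apart; enlarge the field or lower the densities",
            n_triple + n_double, sep)
    rest_pool <- setdiff(stroma_sites, planted)
    rest <- sample(rest_pool, spec$n_stroma_cells - n_triple - n_double)

    cells <- rbind(
      data.frame(x = sites$x[tum], y = sites$y[tum],
                 region = "tumour", class = "epithelial"),
      if (n_triple > 0)
        data.frame(x = sites$x[planted[seq_len(n_triple)]],
                   y = sites$y[planted[seq_len(n_triple)]],
                   region = "stroma", class = "triple_pos"),
      if (n_double > 0)
        data.frame(x = sites$x[planted[n_triple + seq_len(n_double)]],
                   y = sites$y[planted[n_triple + seq_len(n_double)]],
                   region = "stroma", class = "double_pos"),
      if (length(rest) > 0)
        data.frame(x = sites$x[rest], y = sites$y[rest],
                   region = "stroma", class = "vim_only"))
    rownames(cells) <- NULL

    # truth mask: pixel (row, col) is tumour iff its centre is left of the
    # front at its own y
    ys <- seq_len(spec$height_px) - 1
    front_rows <- front_curve(spec, phases, ys)
    xs <- seq_len(spec$width_px) - 1
    tumour_mask <- outer(front_rows, xs, FUN = function(f, x) x < f)

    channels <- lapply(setNames(ALL_CHANNELS, ALL_CHANNELS),
                       function(ch) render_background(spec))
    r <- spec$nucleus_radius_px
    for (i in seq_len(nrow(cells))) {
      cx <- cells$x[i]; cy <- cells$y[i]
      channels$DAPI <- paint_disc(channels$DAPI, cx, cy, r,
                                  cell_gain(spec, "DAPI"), spec)
      for (ch in CLASS_MARKERS[[cells$class[i]]])
        channels[[ch]] <- paint_disc(channels[[ch]], cx, cy, r + 2,
                                     cell_gain(spec, ch), spec)
    }

    structure(list(channels = channels,
                   truth = list(tumour_mask = tumour_mask, cells = cells),
                   marker_map = DEFAULT_MARKER_MAP,
                   spec = spec),
              class = "field_image")
  })
}

#' Generate a negative-control field
#'
#' Nuclei are rendered as in \code{\link{generate_field}} but the three
#' marker channels contain background noise only, emulating a slide stained
#' without primary antibodies. Used by \code{\link{compute_thresholds}} to
#' derive per-channel background thresholds.
#'
#' @param spec a \code{\link{field_spec}}; cell counts give the number of
#'   control nuclei.
#' @return a \code{field_image} whose truth cells all have class
#'   \code{"negative"}.
#' @export
generate_negative_control <- function(spec) {
  validate_field_spec(spec)
  local_seed(spec$seed, {
    sites <- candidate_sites(spec)
    n <- min(spec$n_tumour_cells + spec$n_stroma_cells, nrow(sites))
    pick <- sample(nrow(sites), n)
    cells <- data.frame(x = sites$x[pick], y = sites$y[pick],
                        region = "stroma", class = "negative")
    channels <- lapply(setNames(ALL_CHANNELS, ALL_CHANNELS),
                       function(ch) render_background(spec))
    for (i in seq_len(nrow(cells)))
      channels$DAPI <- paint_disc(channels$DAPI, cells$x[i], cells$y[i],
                                  spec$nucleus_radius_px,
                                  cell_gain(spec, "DAPI"), spec)
    structure(list(channels = channels,
                   truth = list(tumour_mask = NULL, cells = cells),
                   marker_map = DEFAULT_MARKER_MAP,
                   spec = spec),
              class = "field_image")
  })
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image> %d x %d px, channels: %s\n", d[2], d[1],
              paste(names(x$channels), collapse = ", ")))
  if (!is.null(x$truth$cells)) {
    tab <- table(x$truth$cells$class)
    cat("  truth cells:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a field to a multi-page TIFF with a JSON sidecar
#'
#' One 16-bit page per channel in the order DAPI, FITC, CY3, CY5; the
#' channel order and marker map are recorded in \code{<path>.json}. The
#' ground-truth tumour mask, when present, is written as a single-page TIFF
#' alongside.
#'
#' @param field a \code{field_image}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  pages <- lapply(field$channels[ALL_CHANNELS], function(m) m / GREY_MAX)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(channel_order = ALL_CHANNELS,
               marker_map = as.list(field$marker_map))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  if (!is.null(field$truth$tumour_mask)) {
    mask_path <- sub("\\.tiff?$", "_truth_mask.tif", path)
    tiff::writeTIFF(field$truth$tumour_mask * 1.0, mask_path,
                    bits.per.sample = 8L)
  }
  invisible(path)
}

#' Read a field written by \code{\link{write_field_tiff}}
#'
#' @param path TIFF path; channel order is taken from the JSON sidecar when
#'   present, otherwise assumed DAPI, FITC, CY3, CY5.
#' @return a \code{field_image} (without ground truth).
#' @export
read_field_tiff <- function(path) {
  if (!file.exists(path)) stopf("field TIFF not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".json")
  order <- ALL_CHANNELS
  marker_map <- DEFAULT_MARKER_MAP
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    order <- meta$channel_order
    marker_map <- unlist(meta$marker_map)
  }
  channels <- lapply(pages, function(p) round(p * GREY_MAX))
  names(channels) <- order
  structure(list(channels = channels[ALL_CHANNELS],
                 truth = list(tumour_mask = NULL, cells = NULL),
                 marker_map = marker_map, spec = NULL),
            class = "field_image")
}
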