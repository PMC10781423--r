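#' Slide-level marker-class proportions
#'
#' Pools QC-passing fields within each slide (total positives over total
#' region cells) and returns one proportion per slide for the requested
#' region and cell class. The slide, not the field, is the biological
#' replicate: fields from one tumour are pseudo-replicates.
#'
#' @param summaries field-summary data frame (QC-passed fields).
#' @param manifest data frame mapping \code{slide_id} to group
#'   \code{label}; when \code{summaries} already carries a label column it
#'   may be omitted.
#' @param region \code{"stroma"} or \code{"tumour"}.
#' @param class \code{"triple"} or \code{"double"}.
#' @return data frame: slide_id, label, n_cells (region cells), proportion.
#' @export
slide_proportions <- function(summaries, manifest = NULL,
                              region = c("stroma", "tumour"),
                              class = c("triple", "double")) {
  region <- match.arg(region); class <- match.arg(class)
  if (!is.null(manifest)) {
    summaries$label <-
      manifest$label[match(summaries$slide_id, manifest$slide_id)]
  }
  if (is.null(summaries$label))
    stopf("no group labels: supply a manifest with slide_id and label")
  num_col <- paste0(region, "_", class)
  den_col <- paste0("n_", region)
  sp <- split(summaries, summaries$slide_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    den <- sum(d[[den_col]])
    data.frame(slide_id = d$slide_id[1], label = d$label[1],
               n_cells = den,
               proportion = if (den > 0) sum(d[[num_col]]) / den
                            else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

# mean and 95% t-based confidence interval of slide-level proportions
mean_ci <- function(p) {
  p <- p[!is.na(p)]
  n <- length(p)
  m <- mean(p)
  if (n < 2) return(c(mean = m, lo = NA_real_, hi = NA_real_, n = n))
  half <- qt(0.975, n - 1) * sd(p) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half, n = n)
}

#' Aggregate proportions per group, region and cell class
#'
#' Slide-level proportions (fields pooled within slide) are averaged per
#' group; the 95\% confidence interval comes from the t distribution over
#' slides. Groups with fewer than two slides are flagged: their CI is
#' undefined.
#'
#' @param summaries QC-passed field summaries.
#' @param manifest slide-to-label manifest (see
#'   \code{\link{slide_proportions}}).
#' @return data frame with one row per (label, region, class): n_slides,
#'   mean proportion, ci_lo, ci_hi, and \code{ci_defined}.
#' @export
aggregate_proportions <- function(summaries, manifest = NULL) {
  grid <- expand.grid(region = c("tumour", "stroma"),
                      class = c("triple", "double"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sp <- slide_proportions(summaries, manifest, grid$region[i],
                            grid$class[i])
    do.call(rbind, lapply(split(sp, sp$label), function(d) {
      ci <- mean_ci(d$proportion)
      data.frame(label = d$label[1], region = grid$region[i],
                 class = grid$class[i], n_slides = as.integer(ci["n"]),
                 mean = ci["mean"], ci_lo = ci["lo"], ci_hi = ci["hi"],
                 ci_defined = as.integer(ci["n"]) >= 2)
    }))
  }))
  rownames(out) <- NULL
  if (any(!out$ci_defined))
    warnf("group(s) with < 2 slides: confidence interval undefined")
  out
}

#' Compare two groups of slide-level proportions
#'
#' Two-tailed two-sample t test on slide-level proportions (Welch's
#' unequal-variance form by default; set \code{var.equal = TRUE} for the
#' classic pooled form). Significance stars follow the usual convention
#' (*** for p < 0.001). When both groups have zero variance and equal
#' means the comparison is degenerate and p = 1 by convention.
#'
#' @param prop_a,prop_b numeric vectors of slide-level proportions (each of
#'   length >= 2), e.g. from \code{\link{slide_proportions}}.
#' @param var.equal use the pooled-variance Student form.
#' @param name_a,name_b labels for reporting.
#' @return an object of class \code{group_comparison}: means, 95\% CIs,
#'   t statistic, degrees of freedom, p value and stars.
#' @export
compare_groups <- function(prop_a, prop_b, var.equal = FALSE,
                           name_a = "group_a", name_b = "group_b") {
  prop_a <- prop_a[!is.na(prop_a)]; prop_b <- prop_b[!is.na(prop_b)]
  if (length(prop_a) < 2 || length(prop_b) < 2)
    stopf("both groups need at least two slides")
  degenerate <- sd(prop_a) == 0 && sd(prop_b) == 0
  if (degenerate) {
    if (mean(prop_a) == mean(prop_b)) {
      tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
                 p.value = 1)
    } else {
      tt <- list(statistic = c(t = sign(mean(prop_a) - mean(prop_b)) * Inf),
                 parameter = c(df = NA_real_), p.value = 0)
    }
  } else {
    tt <- t.test(prop_a, prop_b, var.equal = var.equal)
  }
  p <- tt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
           else if (p < 0.05) "*" else "ns"
  structure(list(name_a = name_a, name_b = name_b,
                 mean_a = mean(prop_a), mean_b = mean(prop_b),
                 ci_a = mean_ci(prop_a)[c("lo", "hi")],
                 ci_b = mean_ci(prop_b)[c("lo", "hi")],
                 n_a = length(prop_a), n_b = length(prop_b),
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = p, stars = stars, var_equal = var.equal),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (mean %.4g, n=%d) vs %s (mean %.4g, n=%d)\n",
              x$name_a, x$mean_a, x$n_a, x$name_b, x$mean_b, x$n_b))
  cat(sprintf("  %s t = %.3f, df = %.2f, p = %.3g %s\n",
              if (x$var_equal) "Student" else "Welch",
              x$t_statistic, x$df, x$p_value, x$stars))
  invisible(x)
}

#' Bar plot of group proportions with CI whiskers
#'
#' @param agg an \code{\link{aggregate_proportions}} result.
#' @param path optional PNG path; when given the plot is written there.
#' @return \code{agg}, invisibly.
#' @export
plot_group_proportions <- function(agg, path = NULL) {
  if (!is.null(path)) {
    png(path, width = 900, height = 500)
    on.exit(dev.off(), add = TRUE)
  }
  lab <- sprintf("%s\n%s %s", agg$label, agg$region, agg$class)
  ylim <- c(0, max(agg$ci_hi, agg$mean, na.rm = TRUE) * 1.15)
  mid <- barplot(100 * agg$mean, names.arg = lab, las = 2,
                 ylab = "% of region cells", ylim = 100 * ylim,
                 cex.names = 0.7)
  ok <- !is.na(agg$ci_lo)
  segments(mid[ok], 100 * agg$ci_lo[ok], mid[ok], 100 * agg$ci_hi[ok])
  invisible(agg)
}
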