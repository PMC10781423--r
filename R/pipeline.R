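default_pipeline_config <- function() {
  list(
    seed = 1,
    out_dir = "emtseek_run",
    stages = c("simulate", "quantify", "stats", "train"),
    cohort = list(n_metastatic_slides = 2, n_nonmetastatic_slides = 2,
                  fields_per_slide = 5,
                  met_stromal_triple_density = 30,
                  nonmet_stromal_triple_density = 2,
                  double_positive_density = 10,
                  field = list(width_px = 320, height_px = 320,
                               n_tumour_cells = 40, n_stroma_cells = 50)),
    quantify = list(multiplier = 1.5, min_fraction = 0.2,
                    cloud_channel = "CY3", fields_dir = NULL,
                    min_component_area_px = 1200),
    ml = list(mode = "cell_intensity", classifier = "ann",
              epochs = 14, train_fraction = 0.7, cv_k = 0)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  for (sec in c("cohort", "quantify", "ml")) {
    bad <- setdiff(names(config[[sec]]),
                   c(names(defaults[[sec]]), "slide_density_cv",
                     "n_control_cells"))
    if (length(bad))
      stopf("unknown config field(s): %s",
            paste(paste0(sec, ".", bad), collapse = ", "))
  }
  modifyList(defaults, config)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> quantify -> stats -> train over a seeded
#' synthetic cohort, writing every intermediate table, the effective
#' configuration, and a machine-readable summary into a run directory.
#' Rerunning with the same configuration and seed reproduces the outputs.
#'
#' @param config a configuration list, or the path of a JSON/YAML file;
#'   omitted fields take package defaults (see the methods vignette).
#' @return the run summary (also written as \code{report.json}),
#'   invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg, file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  report <- list(config = cfg)
  message(sprintf("[emtseek] run dir: %s", cfg$out_dir))

  cohort <- NULL
  if ("simulate" %in% cfg$stages) {
    fs_args <- cfg$cohort$field
    fs_args$seed <- cfg$seed
    cs_args <- cfg$cohort
    cs_args$field <- do.call(field_spec, fs_args)
    cs_args$seed <- cfg$seed
    cohort <- generate_cohort(do.call(cohort_spec, cs_args),
                              output = "images")
    write.csv(cohort$manifest, file.path(cfg$out_dir, "manifest.csv"),
              row.names = FALSE)
    report$simulate <- list(n_slides = nrow(cohort$slides),
                            n_fields = nrow(cohort$manifest))
    message(sprintf("[emtseek] simulated %d fields from %d slides",
                    nrow(cohort$manifest), nrow(cohort$slides)))
  }

  quant <- NULL
  if ("quantify" %in% cfg$stages) {
    if (!is.null(cfg$quantify$fields_dir) &&
        !dir.exists(cfg$quantify$fields_dir))
      stopf("quantify.fields_dir does not exist: %s",
            cfg$quantify$fields_dir)
    if (is.null(cohort))
      stopf("quantify stage needs the simulate stage (or a fields_dir with a manifest, not configured)")
    cp <- dense_cloud_params(
      reference_channel = cfg$quantify$cloud_channel,
      min_component_area_px = cfg$quantify$min_component_area_px)
    quant <- quantify_cohort(cohort, multiplier = cfg$quantify$multiplier,
                             min_fraction = cfg$quantify$min_fraction,
                             cloud_params = cp)
    write.csv(quant$cells, file.path(cfg$out_dir, "cells.csv"),
              row.names = FALSE)
    write.csv(quant$summaries,
              file.path(cfg$out_dir, "field_summaries.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(thresholds = as.list(quant$thresholds$thresholds),
           multiplier = quant$thresholds$multiplier,
           n_control_cells = quant$thresholds$n_cells),
      file.path(cfg$out_dir, "thresholds.json"), auto_unbox = TRUE)
    report$quantify <- list(
      n_cells = nrow(quant$cells),
      n_fields_retained = sum(quant$summaries$qc_pass),
      thresholds = as.list(round(quant$thresholds$thresholds, 3)))
    message(sprintf("[emtseek] quantified %d cells, %d/%d fields pass QC",
                    nrow(quant$cells), sum(quant$summaries$qc_pass),
                    nrow(quant$summaries)))
  }

  if ("stats" %in% cfg$stages) {
    if (is.null(quant)) stopf("stats stage needs the quantify stage")
    agg <- aggregate_proportions(quant$retained, cohort$manifest)
    write.csv(agg, file.path(cfg$out_dir, "aggregate.csv"),
              row.names = FALSE)
    plot_group_proportions(agg, file.path(cfg$out_dir,
                                          "group_proportions.png"))
    sp <- slide_proportions(quant$retained, cohort$manifest,
                            region = "stroma", class = "triple")
    met <- sp$proportion[sp$label == "metastatic"]
    nonmet <- sp$proportion[sp$label == "non_metastatic"]
    report$stats <- list(
      mean_stroma_triple_pct = as.list(round(
        100 * tapply(sp$proportion, sp$label, mean), 4)))
    if (length(met) >= 2 && length(nonmet) >= 2) {
      cmp <- compare_groups(met, nonmet, name_a = "metastatic_stroma",
                            name_b = "non_metastatic_stroma")
      report$stats$comparison <- list(t = cmp$t_statistic, p = cmp$p_value,
                                      stars = cmp$stars)
      write.csv(data.frame(a = cmp$name_a, b = cmp$name_b,
                           mean_a = cmp$mean_a, mean_b = cmp$mean_b,
                           t = cmp$t_statistic, df = cmp$df,
                           p = cmp$p_value, stars = cmp$stars),
                file.path(cfg$out_dir, "comparisons.csv"),
                row.names = FALSE)
      message(sprintf("[emtseek] metastatic vs non-metastatic stroma: p = %.3g %s",
                      cmp$p_value, cmp$stars))
    } else {
      report$stats$comparison <- "skipped: fewer than 2 slides per group"
    }
  }

  if ("train" %in% cfg$stages) {
    if (is.null(quant)) stopf("train stage needs the quantify stage")
    retained_cells <- quant$cells[quant$cells$field_id %in%
                                    quant$retained$field_id, ]
    ft <- build_feature_matrix(retained_cells, mode = cfg$ml$mode,
                               manifest = cohort$manifest,
                               thresholds = quant$thresholds)
    parts <- split_train_validation(ft, cfg$ml$train_fraction,
                                    seed = cfg$seed)
    if (cfg$ml$classifier == "ann") {
      model <- train_ann(parts$train, epochs = cfg$ml$epochs,
                         seed = cfg$seed, validation = parts$validation)
      write.csv(model$history, file.path(cfg$out_dir, "ann_history.csv"),
                row.names = FALSE)
      plot(model, path = file.path(cfg$out_dir, "ann_history.png"))
    } else {
      model <- fit_classifier(parts$train, cfg$ml$classifier,
                              params = list())
    }
    roc <- compute_roc(model, parts$validation)
    plot(roc, path = file.path(cfg$out_dir, "roc.png"))
    report$train <- list(classifier = cfg$ml$classifier, mode = cfg$ml$mode,
                         n_train_fields = nrow(parts$train$x),
                         n_validation_fields = nrow(parts$validation$x),
                         auc = roc$auc, sensitivity = roc$sensitivity,
                         specificity = roc$specificity)
    if (cfg$ml$cv_k >= 2) {
      cv <- cross_validate(ft, cfg$ml$classifier, k = cfg$ml$cv_k,
                           seed = cfg$seed)
      report$train$cv_mean_f1 <- cv$mean_f1
    }
    # majority-vote calls on the held-out slides
    votes <- lapply(unique(parts$validation$slide_id), function(sid) {
      sel <- parts$validation[parts$validation$slide_id == sid]
      pv <- suppressWarnings(
        predict_slide(model, sel, n = cfg$cohort$fields_per_slide))
      data.frame(slide_id = sid, truth = sel$label[1],
                 predicted = pv$label, mean_prob = pv$mean_prob)
    })
    votes <- do.call(rbind, votes)
    write.csv(votes, file.path(cfg$out_dir, "slide_votes.csv"),
              row.names = FALSE)
    report$train$slide_vote_accuracy <-
      mean(votes$truth == votes$predicted)
    message(sprintf("[emtseek] %s AUC = %.3f, slide-vote accuracy = %.2f",
                    cfg$ml$classifier, roc$auc,
                    report$train$slide_vote_accuracy))
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}
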