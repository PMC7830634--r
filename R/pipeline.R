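#' Simulate a cohort and write it to disk
#'
#' Wraps [generate_cohort()] and [write_cohort()]: one CSV per leg per
#' trial, a JSON annotation sidecar per trial and a cohort manifest.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if missing).
#' @param seed Master seed.
#' @return Invisible manifest data frame.
#' @export
fog_simulate <- function(config = cohort_config(), dir, seed = 1) {
  cohort <- generate_cohort(config, seed = seed)
  write_cohort(cohort, dir)
}

#' Run the full analysis on a cohort
#'
#' Executes the pipeline end to end: feature extraction, step labeling,
#' and the requested validation protocols per therapy condition, plus (for
#' the prediction task) FN-cost tuning, the SVM+LDA OR-ensemble,
#' selected-feature Spearman correlations and pre-FOG detection latency.
#'
#' @param input A cohort directory (containing `manifest.csv`) or a cohort
#'   list as returned by [generate_cohort()].
#' @param task `"detection"` (gait vs FOG) or `"prediction"` (gait vs
#'   pre-FOG).
#' @param window_s Pre-FOG window length, seconds.
#' @param protocols Subset of `"kfold10"`, `"split7030"`, `"loso"`.
#' @param spec Base classifier specification.
#' @param split_repeats Repetitions for the 70/30 protocol (the printed
#'   procedure uses 20; smaller values keep exploratory runs fast).
#' @param f_range,c_range Inner tuning grid for the 70/30 protocol.
#' @param seed Master seed (expanded into per-stage seeds).
#' @param out_dir Optional output directory for the JSON summary and
#'   per-fold CSVs.
#' @return List with `features`, per-condition protocol reports, and (for
#'   prediction) `fn_cost`, `correlations` and `latency` blocks.
#' @export
fog_run <- function(input, task = c("prediction", "detection"),
                    window_s = 2,
                    protocols = c("kfold10", "split7030", "loso"),
                    spec = fog_model_spec("svm"),
                    split_repeats = 5, f_range = c(2, 4, 8, 16),
                    c_range = c(1, 5, 10, 20), seed = 1,
                    out_dir = NULL) {
  task <- match.arg(task)
  cohort <- if (is.character(input)) read_cohort(input) else input
  features <- extract_cohort_features(cohort)
  ann <- cohort_annotations(cohort)
  cfg <- labeling_config(prefog_window_s = window_s, task = task)
  data <- label_steps(features, ann, cfg)
  conditions <- sort(unique(data$condition))
  out <- list(task = task, window_s = window_s, n_steps = nrow(data),
              features = features)
  for (cond in conditions) {
    dc <- data[data$condition == cond, , drop = FALSE]
    res <- list()
    if ("kfold10" %in% protocols) {
      d <- split_xy(dc)
      res$kfold10 <- cv_metrics(d$x, d$y, spec, folds = 10,
                                seed = derive_seed(seed, 11L))
    }
    if ("split7030" %in% protocols) {
      res$split7030 <- run_algorithm1(dc, k = split_repeats,
                                      f_range = f_range,
                                      c_range = c_range, folds = 5,
                                      seed = derive_seed(seed, 12L))
    }
    if ("loso" %in% protocols) {
      res$loso <- loso_validate(dc, spec = spec,
                                seed = derive_seed(seed, 13L))
    }
    out[[paste0("condition_", cond)]] <- res
  }
  if (task == "prediction" && "loso" %in% protocols) {
    # interpretability block on the pooled data: frequent features,
    # their correlation with the class label, and detection latency
    loso_all <- loso_validate(data, spec = spec,
                              seed = derive_seed(seed, 14L))
    freq <- frequent_features(loso_all)
    out$selection_frequency <- loso_all$selection_frequency
    if (length(freq)) {
      out$correlations <- spearman_feature_correlation(data, freq)
    }
    pred <- integer(nrow(data))
    pred[loso_all$pooled_scores$row] <- loso_all$pooled_scores$predicted
    ann_pred <- lapply(ann, function(ep) exclude_gait_initiation(ep)$annotations)
    out$latency <- detection_latency(pred, data, ann_pred,
                                     window_s = window_s)
    out$loso_pooled <- loso_all$pooled
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    summary <- out
    summary$features <- NULL
    jsonlite::write_json(
      strip_for_json(summary),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
  }
  out
}

# Drop heavy/recursive members before JSON serialization.
strip_for_json <- function(x) {
  if (inherits(x, "validation_report")) {
    return(list(protocol = x$protocol,
                aggregate = x$aggregate,
                pooled = if (!is.null(x$pooled))
                  x$pooled[metric_names] else NULL))
  }
  if (is.list(x) && !is.data.frame(x)) {
    x <- x[!vapply(x, is.function, NA)]
    return(lapply(x, strip_for_json))
  }
  x
}
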