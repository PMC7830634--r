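#' Confusion counts from predictions and reference labels
#'
#' @param predicted,actual Integer 0/1 vectors of equal length.
#' @return An object of class `confusion_counts`: list `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion_counts <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  structure(list(tp = sum(predicted == 1 & actual == 1),
                 tn = sum(predicted == 0 & actual == 0),
                 fp = sum(predicted == 1 & actual == 0),
                 fn = sum(predicted == 0 & actual == 1)),
            class = "confusion_counts")
}

#' Confusion-based performance metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy, positive
#' and negative predictive values, F-score (harmonic mean of sensitivity
#' and PPV) and the Youden index (sensitivity + specificity - 100), all
#' reported as percentages. A metric whose denominator is zero is returned
#' as `NA` (flagged undefined), never as 0 or 100.
#'
#' @param counts A `confusion_counts` (or list with `tp`, `tn`, `fp`,
#'   `fn`).
#' @return Named list of the seven metrics (percent).
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  if (n == 0) stop("all-zero confusion counts")
  div <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  ppv <- div(tp, tp + fp)
  npv <- div(tn, tn + fn)
  acc <- div(tp + tn, n)
  f <- if (!is.na(sens) && !is.na(ppv) && (sens + ppv) > 0) {
    2 * sens * ppv / (sens + ppv)
  } else NA_real_
  youden <- if (!is.na(sens) && !is.na(spec)) sens + spec - 100 else
    NA_real_
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       ppv = ppv, npv = npv, f_score = f, youden = youden)
}

#' ROC curve and AUC from continuous scores
#'
#' Threshold sweep over the unique score values (ties collapse to one
#' threshold); AUC by trapezoid over the false-positive-rate axis, which
#' on tie-free data equals the Mann-Whitney U statistic normalized by
#' `n_pos * n_neg`.
#'
#' @param scores Continuous classifier scores (larger = more positive).
#' @param labels Integer 0/1 reference labels; both classes required.
#' @return List `roc_points` (data frame `fpr`, `tpr`, in percent) and
#'   `auc` (fraction in `[0, 1]`).
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("ROC requires both classes present")
  }
  np <- sum(labels == 1); nn <- sum(labels == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nn, 0)
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  if (utils::tail(fpr, 1) != 1 || utils::tail(tpr, 1) != 1) {
    fpr <- c(fpr, 1); tpr <- c(tpr, 1)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = 100 * fpr, tpr = 100 * tpr),
       auc = auc)
}

#' Spearman correlation between features and the class label
#'
#' Rank correlation (average ranks on ties) of each feature against the
#' 0/1 label, with the large-sample t approximation for the p-value. By
#' the label convention (0 = gait, 1 = pre-FOG), negative coefficients
#' mean the feature decreases as FOG approaches.
#'
#' @param data Labeled feature data frame (with a `label` column).
#' @param features Character vector of feature columns to test (typically
#'   the features selected in at least 80% of LOSO folds).
#' @return Data frame `feature`, `rho`, `p_value`; constant features get
#'   `NA` (flagged undefined).
#' @export
spearman_feature_correlation <- function(data, features) {
  res <- lapply(features, function(f) {
    x <- data[[f]]
    if (length(unique(x)) < 2) {
      return(data.frame(feature = f, rho = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, data$label, method = "spearman", exact = FALSE))
    data.frame(feature = f, rho = unname(ct$estimate),
               p_value = ct$p.value)
  })
  do.call(rbind, c(res, make.row.names = FALSE))
}

#' Pre-FOG detection latency in steps
#'
#' For each FOG episode, latency is the number of consecutive steps
#' immediately preceding the onset that were predicted pre-FOG, counting
#' backwards from the last pre-onset step until the first gait
#' prediction. The looser variant (`mode = "first_in_window"`) instead
#' counts from the earliest positive prediction within the pre-FOG window.
#'
#' @param predictions Integer 0/1 predicted labels, one per step row.
#' @param steps Data frame with `trial_id` and `peak_time_s` for the same
#'   rows.
#' @param episodes Named list mapping trial id to its episode data frame.
#' @param window_s Pre-FOG window length (only used by the loose mode).
#' @param mode `"consecutive"` (default, strict) or `"first_in_window"`.
#' @return List `per_episode` (data frame `trial_id`, `onset_s`,
#'   `latency_steps`, `n_pre_steps`), `mean`, `sd` (over episodes with at
#'   least one pre-onset step) and `n_covered`.
#' @export
detection_latency <- function(predictions, steps, episodes, window_s = 2,
                              mode = c("consecutive", "first_in_window")) {
  mode <- match.arg(mode)
  rows <- list()
  for (tid in names(episodes)) {
    ep <- episodes[[tid]]
    if (is.null(ep) || nrow(ep) == 0) next
    sel <- steps$trial_id == tid
    tt <- steps$peak_time_s[sel]
    pp <- predictions[sel]
    o <- order(tt)
    tt <- tt[o]; pp <- pp[o]
    for (i in seq_len(nrow(ep))) {
      pre <- which(tt < ep$start_s[i])
      if (mode == "first_in_window") {
        pre <- pre[tt[pre] >= ep$start_s[i] - window_s]
      }
      lat <- 0L
      if (length(pre)) {
        if (mode == "consecutive") {
          for (j in rev(pre)) {
            if (pp[j] == 1) lat <- lat + 1L else break
          }
        } else {
          pos <- pre[pp[pre] == 1]
          if (length(pos)) lat <- length(pre) - match(pos[1], pre) + 1L
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        trial_id = tid, onset_s = ep$start_s[i],
        latency_steps = lat, n_pre_steps = length(pre))
    }
  }
  per <- if (length(rows)) do.call(rbind, c(rows,
                                            make.row.names = FALSE)) else
    data.frame(trial_id = character(0), onset_s = numeric(0),
               latency_steps = integer(0), n_pre_steps = integer(0))
  covered <- per[per$n_pre_steps > 0, , drop = FALSE]
  list(per_episode = per,
       mean = if (nrow(covered)) mean(covered$latency_steps) else NA_real_,
       sd = if (nrow(covered) > 1) stats::sd(covered$latency_steps) else
         NA_real_,
       n_covered = nrow(covered))
}
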