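# ---- helpers ----------------------------------------------------------

# Split a labeled dataset into feature matrix and labels. By default the
# canonical 16 step features are used when present; otherwise every
# numeric non-metadata column counts as a feature, so the protocols also
# run on externally supplied feature tables.
split_xy <- function(data, features = NULL) {
  if (is.null(features)) {
    if (all(fog_feature_names() %in% names(data))) {
      features <- fog_feature_names()
    } else {
      meta <- c("label", "subject_id", "condition", "trial_id", "leg",
                "peak_time_s")
      features <- setdiff(names(data)[vapply(data, is.numeric, NA)], meta)
    }
  }
  missing <- setdiff(c(features, "label"), names(data))
  if (length(missing)) {
    stop("labeled dataset lacks columns: ", paste(missing, collapse = ", "))
  }
  list(x = as.matrix(data[, features, drop = FALSE]),
       y = as.integer(data$label))
}

# Pooled confusion + metrics from per-row predictions.
report_from_predictions <- function(predicted, actual, scores = NULL) {
  counts <- confusion_counts(predicted, actual)
  rep <- compute_metrics(counts)
  rep$counts <- counts
  if (!is.null(scores) && length(unique(actual)) == 2 &&
      length(unique(scores)) > 1) {
    roc <- roc_curve(scores, actual)
    rep$auc <- roc$auc
    rep$roc_points <- roc$roc_points
  }
  rep
}

metric_names <- c("sensitivity", "specificity", "accuracy", "ppv", "npv",
                  "f_score", "youden")

aggregate_reports <- function(reports) {
  m <- sapply(reports, function(r) unlist(r[metric_names]))
  data.frame(metric = metric_names,
             mean = apply(m, 1, mean, na.rm = TRUE),
             sd = apply(m, 1, stats::sd, na.rm = TRUE),
             n_defined = apply(m, 1, function(z) sum(!is.na(z))))
}

# ---- inner tuning ------------------------------------------------------

#' Inner grid tuning of feature count and SVM regularization
#'
#' Exhaustive grid over the number of top-ranked features `f` and the SVM
#' box constraint `c`, scored by misclassification error in stratified
#' k-fold cross-validation on the training rows only. Ties prefer the
#' smaller `f`, then the smaller `c`.
#'
#' @param x,y Training features and 0/1 labels.
#' @param ranking Feature names in decreasing relevance (see
#'   [rank_features_dt()]).
#' @param f_range,c_range Grid values (defaults: 1 to all features, cost
#'   1..20).
#' @param folds Number of CV folds (reduced with a warning when the
#'   smaller class is too small).
#' @param kernel SVM kernel used during tuning.
#' @param seed Seed for the fold draw.
#' @return List `best_f`, `best_c`, `error_surface` (matrix f x c).
#' @export
tune_inner <- function(x, y, ranking, f_range = seq_len(ncol(x)),
                       c_range = 1:20, folds = 10, kernel = "linear",
                       seed = NULL) {
  x <- as.matrix(x)
  n_min <- min(table(y))
  if (n_min < folds) {
    warning("reducing fold count to the smaller class size (", n_min, ")")
    folds <- max(2, n_min)
  }
  fold_id <- with_seed(seed, stratified_folds(y, folds))
  err <- matrix(NA_real_, length(f_range), length(c_range),
                dimnames = list(f = f_range, c = c_range))
  for (fi in seq_along(f_range)) {
    feats <- ranking[seq_len(f_range[fi])]
    for (ci in seq_along(c_range)) {
      spec <- fog_model_spec("svm", kernel = kernel,
                             box_constraint = c_range[ci])
      wrong <- 0L
      for (k in seq_len(folds)) {
        tr <- fold_id != k
        if (length(unique(y[tr])) < 2) next
        m <- fit_fog_model(x[tr, feats, drop = FALSE], y[tr], spec)
        p <- predict(m, x[!tr, feats, drop = FALSE])
        wrong <- wrong + sum(p$label != y[!tr])
      }
      err[fi, ci] <- wrong / length(y)
    }
  }
  best <- which(err == min(err), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(best_f = f_range[best[1]], best_c = c_range[best[2]],
       error_surface = err)
}

# ---- Algorithm-1 repeated 70/30 ---------------------------------------

#' Repeated stratified 70/30 train-test evaluation
#'
#' `k` independent stratified splits; in each repetition the decision-tree
#' feature ranking and the inner (feature count x SVM cost) grid tuning
#' use the training rows only, the tuned model is refit on the training
#' rows and scored on the held-out 30%.
#'
#' @param data Labeled feature data frame (see [label_steps()]).
#' @param k Number of repetitions (default 20).
#' @param test_frac Held-out fraction (default 0.3).
#' @param f_range,c_range,folds Inner tuning grid, see [tune_inner()].
#' @param kernel SVM kernel.
#' @param seed Master seed; each repetition derives its own.
#' @return A `validation_report`: protocol name, per-split reports and
#'   chosen configurations, aggregate mean/sd table, and per-split row
#'   provenance (train/test indices plus the rows seen by ranking and
#'   tuning).
#' @export
run_algorithm1 <- function(data, k = 20, test_frac = 0.3,
                           f_range = NULL, c_range = 1:20, folds = 10,
                           kernel = "linear", seed = 1) {
  d <- split_xy(data)
  if (is.null(f_range)) f_range <- seq_len(ncol(d$x))
  reports <- list()
  provenance <- list()
  configs <- list()
  for (rep_i in seq_len(k)) {
    s <- derive_seed(seed, rep_i)
    split <- with_seed(s, stratified_split(d$y, test_frac))
    tr <- split$train; te <- split$test
    ranking <- rank_features_dt(d$x[tr, , drop = FALSE], d$y[tr])
    tuned <- tune_inner(d$x[tr, , drop = FALSE], d$y[tr], ranking,
                        f_range = f_range, c_range = c_range,
                        folds = folds, kernel = kernel,
                        seed = derive_seed(s, 2L))
    feats <- ranking[seq_len(tuned$best_f)]
    spec <- fog_model_spec("svm", kernel = kernel,
                           box_constraint = tuned$best_c)
    m <- fit_fog_model(d$x[tr, feats, drop = FALSE], d$y[tr], spec)
    p <- predict(m, d$x[te, feats, drop = FALSE])
    reports[[rep_i]] <- report_from_predictions(p$label, d$y[te], p$score)
    configs[[rep_i]] <- list(f = tuned$best_f, c = tuned$best_c,
                             features = feats)
    provenance[[rep_i]] <- list(train = tr, test = te,
                                ranking_rows = tr, tuning_rows = tr)
  }
  structure(list(protocol = "split7030", reports = reports,
                 configs = configs, aggregate = aggregate_reports(reports),
                 provenance = provenance),
            class = "validation_report")
}

# ---- LOSO --------------------------------------------------------------

#' Leave-one-subject-out validation
#'
#' One fold per subject: the held-out subject's rows touch no training
#' stage (feature ranking, feature-count tuning, model fitting). Within
#' each fold the features are re-ranked on the training subjects and the
#' feature count is tuned over `f_grid` by stratified inner
#' cross-validation with the supplied model spec; per-fold selected
#' feature lists feed the selection-frequency analysis.
#'
#' @param data Labeled feature data frame with `subject_id`.
#' @param spec Classifier specification used in every fold.
#' @param f_grid Candidate feature counts for the per-fold tuning.
#' @param inner_folds Inner CV folds for the feature-count tuning.
#' @param seed Master seed.
#' @return A `validation_report` with per-fold reports, pooled metrics
#'   over all held-out predictions (`pooled`), the per-fold selected
#'   features, a `selection_frequency` table (fraction of folds selecting
#'   each feature), pooled held-out scores, and per-fold provenance.
#' @export
loso_validate <- function(data, spec = fog_model_spec("svm"),
                          f_grid = c(1, 2, 3, 4, 6, 8, 10, 12, 16),
                          inner_folds = 5, seed = 1) {
  subjects <- unique(data$subject_id)
  if (length(subjects) < 2) stop("LOSO requires at least 2 subjects")
  d <- split_xy(data)
  f_grid <- f_grid[f_grid <= ncol(d$x)]
  reports <- list(); provenance <- list(); selected <- list()
  pooled_pred <- integer(0); pooled_y <- integer(0)
  pooled_score <- numeric(0); pooled_rows <- integer(0)
  for (si in seq_along(subjects)) {
    te <- which(data$subject_id == subjects[si])
    tr <- which(data$subject_id != subjects[si])
    s <- derive_seed(seed, si)
    ranking <- rank_features_dt(d$x[tr, , drop = FALSE], d$y[tr])
    # tune the feature count only, with the fixed model spec
    fold_id <- with_seed(s, stratified_folds(d$y[tr], inner_folds))
    errs <- vapply(f_grid, function(f) {
      feats <- ranking[seq_len(f)]
      wrong <- 0L
      for (k in seq_len(inner_folds)) {
        itr <- tr[fold_id != k]; ite <- tr[fold_id == k]
        if (length(unique(d$y[itr])) < 2) next
        m <- fit_fog_model(d$x[itr, feats, drop = FALSE], d$y[itr], spec)
        wrong <- wrong + sum(predict(
          m, d$x[ite, feats, drop = FALSE])$label != d$y[ite])
      }
      wrong / length(tr)
    }, 0)
    best_f <- f_grid[which.min(errs)]
    feats <- ranking[seq_len(best_f)]
    m <- fit_fog_model(d$x[tr, feats, drop = FALSE], d$y[tr], spec)
    p <- predict(m, d$x[te, feats, drop = FALSE])
    rep <- report_from_predictions(p$label, d$y[te], p$score)
    rep$subject <- subjects[si]
    rep$single_class_test <- length(unique(d$y[te])) < 2
    reports[[si]] <- rep
    selected[[si]] <- feats
    pooled_pred <- c(pooled_pred, p$label)
    pooled_y <- c(pooled_y, d$y[te])
    pooled_score <- c(pooled_score, p$score)
    pooled_rows <- c(pooled_rows, te)
    provenance[[si]] <- list(train = tr, test = te, ranking_rows = tr,
                             tuning_rows = tr)
  }
  freq <- table(unlist(selected)) / length(subjects)
  structure(list(protocol = "loso", reports = reports,
                 aggregate = aggregate_reports(reports),
                 pooled = report_from_predictions(pooled_pred, pooled_y,
                                                  pooled_score),
                 selected_features = selected,
                 selection_frequency = freq,
                 pooled_scores = data.frame(row = pooled_rows,
                                            score = pooled_score,
                                            predicted = pooled_pred,
                                            label = pooled_y),
                 provenance = provenance),
            class = "validation_report")
}

#' Features selected in at least a given fraction of LOSO folds
#'
#' @param report A LOSO `validation_report`.
#' @param min_frequency Minimum selection frequency (default 0.8).
#' @return Character vector of feature names.
#' @export
frequent_features <- function(report, min_frequency = 0.8) {
  names(report$selection_frequency)[
    report$selection_frequency >= min_frequency]
}

# ---- window x model selection -----------------------------------------

# Draw one random hyperparameter configuration within the documented
# ranges for `family` (log-uniform for scale-like parameters).
sample_model_spec <- function(family) {
  lu <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  switch(family,
         svm = fog_model_spec("svm",
                              kernel = sample(c("linear", "quadratic",
                                                "gaussian"), 1),
                              kernel_scale = lu(0.001, 100),
                              box_constraint = lu(0.01, 100)),
         knn = fog_model_spec("knn", k = sample(1:50, 1),
                              metric = sample(c("euclidean",
                                                "manhattan"), 1),
                              weight = sample(c("equal", "inverse",
                                                "squared_inverse"), 1)),
         lda = fog_model_spec("lda", gamma = stats::runif(1, 0.01, 1),
                              delta = lu(0.01, 100)),
         logistic = fog_model_spec("logistic", lambda = lu(0.01, 100)),
         stop("unknown family: ", family))
}

cv_metrics <- function(x, y, spec, folds, seed) {
  fold_id <- with_seed(seed, stratified_folds(y, folds))
  pred <- integer(length(y))
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    if (length(unique(y[tr])) < 2) { pred[!tr] <- 0L; next }
    m <- fit_fog_model(x[tr, , drop = FALSE], y[tr], spec)
    pred[!tr] <- predict(m, x[!tr, , drop = FALSE])$label
  }
  report_from_predictions(pred, y)
}

#' Joint pre-FOG window length and model family selection
#'
#' For every window length the dataset is relabeled; for every family a
#' seeded random search over the documented hyperparameter ranges (fixed
#' evaluation budget) scores configurations by stratified k-fold CV
#' accuracy. Returns the full window x family accuracy table and the
#' arg-max cell (ties prefer the shorter window, then family order).
#'
#' @param dataset_builder Function `window_s -> labeled data frame`
#'   (typically wrapping [label_steps()] with the prediction task).
#' @param windows Window lengths in seconds (default 2..5).
#' @param families Model families to compare.
#' @param budget Random-search evaluations per cell (default 30).
#' @param folds CV folds for the reported accuracy (default 10).
#' @param screen_folds,n_finalists Every sampled configuration is first
#'   screened with a cheap `screen_folds`-fold CV; only the `n_finalists`
#'   best screened configurations receive the full `folds`-fold
#'   evaluation. The reported cell accuracy is always full-fold CV.
#' @param seed Master seed.
#' @return List `accuracy` (windows x families matrix, percent),
#'   `best_window_s`, `best_family`, `best_specs` (per-cell tuned specs).
#' @export
select_window_and_model <- function(dataset_builder, windows = c(2, 3, 4, 5),
                                    families = c("svm", "knn", "lda",
                                                 "logistic"),
                                    budget = 30, folds = 10,
                                    screen_folds = 2, n_finalists = 6,
                                    seed = 1) {
  acc <- matrix(NA_real_, length(windows), length(families),
                dimnames = list(window_s = windows, family = families))
  best_specs <- list()
  for (wi in seq_along(windows)) {
    data <- dataset_builder(windows[wi])
    if (sum(data$label == 1) == 0) {
      stop("empty pre-FOG class at window ", windows[wi], " s")
    }
    d <- split_xy(data)
    for (mi in seq_along(families)) {
      cell_seed <- derive_seed(seed, wi * 100L + mi)
      specs <- lapply(seq_len(budget), function(b) {
        with_seed(derive_seed(cell_seed, b),
                  sample_model_spec(families[mi]))
      })
      screen <- vapply(seq_len(budget), function(b) {
        rep <- cv_metrics(d$x, d$y, specs[[b]], screen_folds,
                          derive_seed(cell_seed, 500L + b))
        if (is.na(rep$accuracy)) -Inf else rep$accuracy
      }, 0)
      finalists <- order(-screen, seq_len(budget))[
        seq_len(min(n_finalists, budget))]
      best_acc <- -Inf; best_spec <- NULL
      for (b in finalists) {
        rep <- cv_metrics(d$x, d$y, specs[[b]], folds,
                          derive_seed(cell_seed, 1000L + b))
        if (!is.na(rep$accuracy) && rep$accuracy > best_acc) {
          best_acc <- rep$accuracy; best_spec <- specs[[b]]
        }
      }
      acc[wi, mi] <- best_acc
      best_specs[[paste(windows[wi], families[mi], sep = "_")]] <- best_spec
    }
  }
  best <- which(acc == max(acc), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(accuracy = acc, best_window_s = windows[best[1]],
       best_family = families[best[2]], best_specs = best_specs)
}

# ---- FN-cost tuning ----------------------------------------------------

#' Tune the false-negative cost
#'
#' Sweeps the FN cost over `costs`, computing pooled sensitivity, accuracy
#' and F-score by stratified k-fold CV at each value. The chosen cost
#' maximizes sensitivity subject to the F-score staying within
#' `f_tolerance` points of its value at cost 1 (ties prefer the smaller
#' cost), trading false negatives for false positives while keeping
#' accuracy and F-score high.
#'
#' @param data Labeled feature data frame, or pass `x` and `y` directly.
#' @param spec Base [fog_model_spec()] (its `fn_cost` is overridden).
#' @param costs Cost grid (default 1..10).
#' @param folds CV folds.
#' @param f_tolerance Allowed F-score drop in points (default 5).
#' @param seed Seed for the fold draws (same folds across costs).
#' @return List `curve` (data frame cost, sensitivity, accuracy, f_score),
#'   `chosen_cost`, `degenerate` (costs predicting everything positive).
#' @export
tune_fn_cost <- function(data, spec, costs = 1:10, folds = 10,
                         f_tolerance = 5, seed = 1) {
  d <- split_xy(data)
  rows <- list()
  degenerate <- integer(0)
  for (cost in costs) {
    sp <- spec
    sp$fn_cost <- cost
    rep <- cv_metrics(d$x, d$y, sp, folds, seed)
    if (!is.na(rep$specificity) && rep$specificity == 0) {
      degenerate <- c(degenerate, cost)
    }
    rows[[length(rows) + 1]] <- data.frame(
      cost = cost, sensitivity = rep$sensitivity,
      accuracy = rep$accuracy, f_score = rep$f_score)
  }
  curve <- do.call(rbind, c(rows, make.row.names = FALSE))
  f_ref <- curve$f_score[curve$cost == min(costs)]
  ok <- !is.na(curve$f_score) & curve$f_score >= f_ref - f_tolerance
  cand <- curve[ok, , drop = FALSE]
  chosen <- if (nrow(cand)) {
    cand$cost[order(-cand$sensitivity, cand$cost)][1]
  } else min(costs)
  list(curve = curve, chosen_cost = chosen, degenerate = degenerate)
}

# ---- OR-ensemble -------------------------------------------------------

#' OR-combination of classifiers
#'
#' A step is classified positive (pre-FOG) if at least one model yields a
#' positive decision; scores are combined by the maximum.
#'
#' @param models List of fitted `fog_model`s (>= 2) sharing the training
#'   schema.
#' @param newdata Feature matrix/data frame.
#' @return List `label`, `score`, and the per-model label matrix.
#' @export
combine_or <- function(models, newdata) {
  stopifnot(length(models) >= 2)
  preds <- lapply(models, predict, newdata = newdata)
  labs <- sapply(preds, `[[`, "label")
  scores <- sapply(preds, `[[`, "score")
  list(label = as.integer(rowSums(labs) > 0),
       score = apply(scores, 1, max),
       per_model = labs)
}

# ---- cross-condition transfer -----------------------------------------

#' Train on one therapy condition, test on the other
#'
#' The full pipeline (decision-tree ranking, feature-count tuning, model
#' fit) runs on the training condition's rows only; the other condition's
#' rows are used exclusively for evaluation.
#'
#' @param data Labeled feature data frame with a `condition` column.
#' @param train_condition,test_condition Condition labels (e.g. `"on"`,
#'   `"off"`).
#' @param spec Classifier specification.
#' @param f_grid,inner_folds Feature-count tuning controls (see
#'   [loso_validate()]).
#' @param seed Seed.
#' @return List `report` (pooled metrics on the test condition), `spec`,
#'   `features` (selected), `provenance` (train/test row indices).
#' @export
cross_condition <- function(data, train_condition, test_condition,
                            spec = fog_model_spec("svm"),
                            f_grid = c(1, 2, 3, 4, 6, 8, 10, 12, 16),
                            inner_folds = 5, seed = 1) {
  tr <- which(data$condition == train_condition)
  te <- which(data$condition == test_condition)
  if (!length(tr)) stop("no rows for training condition ", train_condition)
  if (!length(te)) stop("no rows for test condition ", test_condition)
  d <- split_xy(data)
  f_grid <- f_grid[f_grid <= ncol(d$x)]
  ranking <- rank_features_dt(d$x[tr, , drop = FALSE], d$y[tr])
  fold_id <- with_seed(seed, stratified_folds(d$y[tr], inner_folds))
  errs <- vapply(f_grid, function(f) {
    feats <- ranking[seq_len(f)]
    wrong <- 0L
    for (k in seq_len(inner_folds)) {
      itr <- tr[fold_id != k]; ite <- tr[fold_id == k]
      if (length(unique(d$y[itr])) < 2) next
      m <- fit_fog_model(d$x[itr, feats, drop = FALSE], d$y[itr], spec)
      wrong <- wrong + sum(predict(
        m, d$x[ite, feats, drop = FALSE])$label != d$y[ite])
    }
    wrong / length(tr)
  }, 0)
  feats <- ranking[seq_len(f_grid[which.min(errs)])]
  m <- fit_fog_model(d$x[tr, feats, drop = FALSE], d$y[tr], spec)
  p <- predict(m, d$x[te, feats, drop = FALSE])
  list(report = report_from_predictions(p$label, d$y[te], p$score),
       spec = spec, features = feats,
       predictions = data.frame(row = te, predicted = p$label,
                                score = p$score, label = d$y[te]),
       provenance = list(train = tr, test = te, ranking_rows = tr,
                         tuning_rows = tr))
}
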