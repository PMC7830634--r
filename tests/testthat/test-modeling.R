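test_that("inner grid tuning finds a zero-error cell on separable data", {
  d <- planted_feature_data(n = 120, n_informative = 3, effect = 4,
                            seed = 21)
  xy <- fogpredict:::split_xy(d, paste0("f", 1:16))
  ranking <- rank_features_dt(xy$x, xy$y)
  tuned <- tune_inner(xy$x, xy$y, ranking, f_range = c(1, 2, 4, 8, 16),
                      c_range = c(1, 5, 10), folds = 5, seed = 3)
  expect_equal(dim(tuned$error_surface), c(5, 3))
  expect_equal(min(tuned$error_surface), 0)
  # tie-break: the smallest f among zero-error cells
  zero_f <- which(apply(tuned$error_surface == 0, 1, any))[1]
  expect_equal(tuned$best_f, c(1, 2, 4, 8, 16)[zero_f])
})

test_that("feature-count selection stays small when few features inform", {
  hits <- 0
  for (s in 1:5) {
    d <- planted_feature_data(n = 200, n_informative = 3, effect = 3,
                              seed = 100 + s)
    xy <- fogpredict:::split_xy(d, paste0("f", 1:16))
    ranking <- rank_features_dt(xy$x, xy$y)
    tuned <- tune_inner(xy$x, xy$y, ranking,
                        f_range = c(1, 2, 3, 4, 6, 8, 12, 16),
                        c_range = c(1, 10), folds = 5, seed = s)
    if (tuned$best_f <= 6) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("repeated 70/30 splits are disjoint, stratified and accurate", {
  d <- planted_feature_data(n = 200, n_informative = 3, effect = 4,
                            seed = 31)
  rep <- run_algorithm1(d, k = 5, f_range = c(2, 4, 8), c_range = c(1, 10),
                        folds = 5, seed = 7)
  expect_length(rep$reports, 5)
  for (pr in rep$provenance) {
    expect_length(intersect(pr$train, pr$test), 0)
    expect_setequal(c(pr$train, pr$test), seq_len(nrow(d)))
  }
  agg <- rep$aggregate
  expect_gte(agg$mean[agg$metric == "accuracy"], 95)
})

test_that("LOSO isolates the held-out subject completely", {
  d <- planted_feature_data(n = 240, n_informative = 3, effect = 3,
                            n_subjects = 6, seed = 41)
  rep <- loso_validate(d, spec = fog_model_spec("svm"),
                       f_grid = c(2, 4, 8, 16), inner_folds = 3, seed = 5)
  expect_length(rep$reports, 6)
  expect_equal(rep$protocol, "loso")
  for (i in seq_along(rep$provenance)) {
    pr <- rep$provenance[[i]]
    expect_length(intersect(d$subject_id[pr$train],
                            d$subject_id[pr$test]), 0)
    expect_true(all(pr$ranking_rows %in% pr$train))
    expect_true(all(pr$tuning_rows %in% pr$train))
  }
  expect_true(all(unlist(rep$selected_features) %in% paste0("f", 1:16)))
  expect_equal(sum(rep$pooled$counts$tp + rep$pooled$counts$tn +
                     rep$pooled$counts$fp + rep$pooled$counts$fn),
               nrow(d))
})

test_that("window/model selection returns the full grid deterministically", {
  f <- small_features()
  ann <- cohort_annotations(small_cohort())
  builder <- function(w) label_steps(f, ann,
                                     labeling_config(w, "prediction"))
  sel <- select_window_and_model(builder, windows = c(2, 4),
                                 families = c("lda", "logistic"),
                                 budget = 4, folds = 5, seed = 9)
  expect_equal(dim(sel$accuracy), c(2, 2))
  expect_true(all(is.finite(sel$accuracy)))
  sel2 <- select_window_and_model(builder, windows = c(2, 4),
                                  families = c("lda", "logistic"),
                                  budget = 4, folds = 5, seed = 9)
  expect_identical(sel$accuracy, sel2$accuracy)
  expect_true(sel$best_window_s %in% c(2, 4))
})

test_that("the FN-cost sweep has the right shape and neutral baseline", {
  d <- planted_feature_data(n = 200, n_informative = 2, effect = 1.5,
                            seed = 51)
  spec <- fog_model_spec("svm", kernel = "linear")
  out <- tune_fn_cost(d, spec, costs = 1:10, folds = 5, seed = 3)
  expect_equal(nrow(out$curve), 10)
  expect_equal(out$curve$cost, 1:10)
  expect_true(out$chosen_cost %in% 1:10)
  # cost 1 must reproduce the unweighted model's CV metrics
  xy <- fogpredict:::split_xy(d, paste0("f", 1:16))
  base <- fogpredict:::cv_metrics(xy$x, xy$y, spec, 5, 3)
  expect_equal(out$curve$sensitivity[1], base$sensitivity)
  expect_equal(out$curve$accuracy[1], base$accuracy)
})

test_that("the OR rule combines decisions and can only add positives", {
  d <- planted_feature_data(n = 160, n_informative = 3, effect = 1.5,
                            seed = 61)
  xy <- fogpredict:::split_xy(d, paste0("f", 1:16))
  tr <- seq_len(110); te <- 111:160
  m_svm <- fit_fog_model(xy$x[tr, ], xy$y[tr],
                         fog_model_spec("svm", kernel = "linear"))
  m_lda <- fit_fog_model(xy$x[tr, ], xy$y[tr], fog_model_spec("lda"))
  comb <- combine_or(list(m_svm, m_lda), xy$x[te, ])
  p_svm <- predict(m_svm, xy$x[te, ])$label
  p_lda <- predict(m_lda, xy$x[te, ])$label
  expect_equal(comb$label, as.integer(p_svm | p_lda))
  sens <- function(p) sum(p == 1 & xy$y[te] == 1) / sum(xy$y[te] == 1)
  expect_gte(sens(comb$label), max(sens(p_svm), sens(p_lda)))
  expect_error(combine_or(list(m_svm), xy$x[te, ]), "length")
})

test_that("cross-condition training never touches test-condition rows", {
  d <- planted_feature_data(n = 200, n_informative = 3, effect = 3,
                            seed = 71)
  out <- cross_condition(d, "on", "off",
                         spec = fog_model_spec("svm"),
                         f_grid = c(2, 4, 8), inner_folds = 3, seed = 1)
  expect_true(all(d$condition[out$provenance$train] == "on"))
  expect_true(all(d$condition[out$provenance$test] == "off"))
  expect_length(intersect(out$provenance$train, out$provenance$test), 0)
  expect_false(is.na(out$report$accuracy))
  expect_error(cross_condition(d, "on", "nope"), "test condition")
})

test_that("a tuned linear SVM matches the optimal threshold rule", {
  set.seed(81)
  n <- 400
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "f1"))
  x[, 1] <- x[, 1] + 3 * y
  tr <- sample(n, 280); te <- setdiff(seq_len(n), tr)
  # brute-force optimal threshold on the training data
  cand <- sort(x[tr, 1])
  errs <- vapply(cand, function(t) mean((x[tr, 1] > t) != y[tr]), 0)
  thr <- cand[which.min(errs)]
  oracle <- as.integer(x[te, 1] > thr)
  m <- fit_fog_model(x[tr, , drop = FALSE], y[tr],
                     fog_model_spec("svm", kernel = "linear",
                                    box_constraint = 5))
  p <- predict(m, x[te, , drop = FALSE])
  expect_gte(mean(p$label == oracle), 0.95)
})
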