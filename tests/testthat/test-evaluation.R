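test_that("metrics match the worked confusion example exactly", {
  rep <- compute_metrics(list(tp = 8, fn = 2, tn = 9, fp = 1))
  expect_equal(rep$sensitivity, 80)
  expect_equal(rep$specificity, 90)
  expect_equal(rep$accuracy, 85)
  expect_equal(rep$ppv, 100 * 8 / 9)
  expect_equal(rep$npv, 100 * 9 / 11)
  expect_equal(rep$f_score, 2 * 80 * (800 / 9) / (80 + 800 / 9))
  expect_equal(rep$youden, 70)
})

test_that("a perfect classifier scores 100 on every metric", {
  rep <- compute_metrics(list(tp = 5, fn = 0, tn = 7, fp = 0))
  for (m in c("sensitivity", "specificity", "accuracy", "ppv", "npv",
              "f_score")) {
    expect_equal(rep[[m]], 100)
  }
  expect_equal(rep$youden, 100)
})

test_that("zero denominators flag metrics as undefined", {
  rep <- compute_metrics(list(tp = 0, fn = 0, tn = 9, fp = 1))
  expect_true(is.na(rep$sensitivity))
  expect_true(is.na(rep$youden))
  expect_false(is.na(rep$specificity))
  expect_error(compute_metrics(list(tp = 0, fn = 0, tn = 0, fp = 0)),
               "all-zero")
})

test_that("the Youden identity holds on random confusion matrices", {
  set.seed(91)
  for (i in 1:1000) {
    cts <- as.list(stats::setNames(sample(0:50, 4, replace = TRUE),
                                   c("tp", "fn", "tn", "fp")))
    if (sum(unlist(cts)) == 0) next
    rep <- compute_metrics(cts)
    if (is.na(rep$youden)) next
    expect_equal(rep$youden, rep$sensitivity + rep$specificity - 100,
                 tolerance = 1e-9)
  }
})

test_that("ROC endpoints and antisymmetry behave", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  r <- roc_curve(scores, labels)
  expect_equal(r$auc, 1)
  rneg <- roc_curve(-scores, labels)
  expect_equal(rneg$auc, 1 - r$auc)
  expect_error(roc_curve(scores, rep(1, 6)), "both classes")
})

test_that("AUC equals the normalized Mann-Whitney statistic", {
  set.seed(92)
  for (i in 1:20) {
    n1 <- 30; n0 <- 40
    s <- c(rnorm(n0), rnorm(n1, mean = 0.5))
    y <- rep(c(0, 1), c(n0, n1))
    if (anyDuplicated(s)) next
    u <- sum(outer(s[y == 1], s[y == 0], ">"))
    expect_equal(roc_curve(s, y)$auc, u / (n1 * n0), tolerance = 1e-9)
  }
})

test_that("AUC is near one-half under label-score independence", {
  set.seed(93)
  s <- rnorm(1e4)
  y <- rep(0:1, 5000)
  expect_equal(roc_curve(s, y)$auc, 0.5, tolerance = 0.02)
})

test_that("our ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(94)
  s <- rnorm(300)
  y <- as.integer(s + rnorm(300) > 0)
  ours <- roc_curve(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("Spearman correlation signs follow the rank ordering", {
  set.seed(95)
  n <- 200
  d <- data.frame(label = rep(0:1, each = n / 2))
  d$down <- ifelse(d$label == 1, stats::runif(n, 0, 1),
                   stats::runif(n, 2, 3))
  d$flat <- rep(1, n)
  out <- spearman_feature_correlation(d, c("down", "flat"))
  expect_lt(out$rho[1], 0)
  expect_lt(out$p_value[1], 0.001)
  expect_true(is.na(out$rho[2]))
})

test_that("independent features rarely show spurious correlation", {
  set.seed(96)
  hits <- 0
  for (i in 1:10) {
    d <- data.frame(label = rep(0:1, 250), x = rnorm(500))
    out <- spearman_feature_correlation(d, "x")
    if (abs(out$rho) < 0.1 && out$p_value > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("latency counts the consecutive pre-onset positive run", {
  steps <- data.frame(trial_id = "T1", peak_time_s = seq(14, 19, by = 1))
  eps <- list(T1 = data.frame(start_s = 20, end_s = 24))
  lat <- detection_latency(c(0, 0, 1, 1, 1, 1), steps, eps)
  expect_equal(lat$per_episode$latency_steps, 4)
  expect_equal(lat$mean, 4)
  none <- detection_latency(rep(0, 6), steps, eps)
  expect_equal(none$per_episode$latency_steps, 0)
  # an interior gait prediction truncates the run
  gap <- detection_latency(c(1, 1, 1, 0, 1, 1), steps, eps)
  expect_equal(gap$per_episode$latency_steps, 2)
})

test_that("flipping a positive prediction never increases latency", {
  set.seed(97)
  steps <- data.frame(trial_id = "T1", peak_time_s = 1:10)
  eps <- list(T1 = data.frame(start_s = 10.5, end_s = 12))
  pred <- rep(1L, 10)
  base <- detection_latency(pred, steps, eps)$mean
  for (i in 1:10) {
    flipped <- pred
    flipped[i] <- 0L
    expect_lte(detection_latency(flipped, steps, eps)$mean, base)
  }
})

test_that("the loose latency mode counts from the earliest window hit", {
  steps <- data.frame(trial_id = "T1", peak_time_s = seq(15, 19, by = 1))
  eps <- list(T1 = data.frame(start_s = 20, end_s = 24))
  pred <- c(0, 1, 0, 0, 1)
  strict <- detection_latency(pred, steps, eps, window_s = 5)
  loose <- detection_latency(pred, steps, eps, window_s = 5,
                             mode = "first_in_window")
  expect_equal(strict$per_episode$latency_steps, 1)
  expect_equal(loose$per_episode$latency_steps, 4)
})

test_that("episodes without pre-onset steps are excluded from aggregates", {
  steps <- data.frame(trial_id = "T1", peak_time_s = c(25, 26))
  eps <- list(T1 = data.frame(start_s = c(20, 30), end_s = c(24, 33)))
  lat <- detection_latency(c(1, 1), steps, eps)
  expect_equal(lat$n_covered, 1)
  expect_equal(nrow(lat$per_episode), 2)
})
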