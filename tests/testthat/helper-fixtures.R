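# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small mixed cohort (4 subjects x 2 trials, 40 s) for unit tests.
small_cohort <- function() cached("small_cohort", {
  generate_cohort(cohort_config(n_subjects = 4, trials_per_subject = 2,
                                trial_duration_s = 40), seed = 101)
})

small_features <- function() cached("small_features", {
  extract_cohort_features(small_cohort())
})

small_prediction_data <- function(window_s = 2) {
  key <- paste0("small_pred_", window_s)
  cached(key, label_steps(
    small_features(), cohort_annotations(small_cohort()),
    labeling_config(window_s, "prediction")))
}

# Default-scale cohort (10 x 2) shared by the acceptance tests.
default_cohort <- function() cached("default_cohort", {
  generate_cohort(cohort_config(), seed = 2024)
})

default_features <- function() cached("default_features", {
  extract_cohort_features(default_cohort())
})

default_prediction_data <- function(window_s = 2) {
  key <- paste0("default_pred_", window_s)
  cached(key, label_steps(
    default_features(), cohort_annotations(default_cohort()),
    labeling_config(window_s, "prediction")))
}

# Synthetic feature matrix where exactly `n_informative` columns carry
# class signal; the rest are pure noise. Used for selection/tuning tests.
planted_feature_data <- function(n = 300, n_features = 16,
                                 n_informative = 3, effect = 2,
                                 n_subjects = 6, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(rnorm(n * n_features), n, n_features,
              dimnames = list(NULL, paste0("f", seq_len(n_features))))
  for (j in seq_len(n_informative)) {
    x[y == 1, j] <- x[y == 1, j] + effect
  }
  d <- as.data.frame(x)
  d$label <- y
  d$subject_id <- rep_len(sprintf("P%d", seq_len(n_subjects)), n)
  d$condition <- rep(c("on", "off"), each = ceiling(n / 2))[seq_len(n)]
  d
}

# Brute-force DTW by recursive path enumeration (tiny inputs only).
dtw_bruteforce <- function(a, b) {
  rec <- function(i, j) {
    cost <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(cost)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    cost + best
  }
  rec(length(a), length(b))
}
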