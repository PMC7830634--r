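#' Raw angular-velocity trace
#'
#' @param samples Numeric vector of angular-velocity samples (x-axis
#'   gyroscope channel, degrees/s for real recordings; arbitrary units for
#'   synthetic ones).
#' @param sample_rate_hz Sampling rate, Hz.
#' @param leg `"left"` or `"right"`.
#' @param t0 Recording start offset in seconds (device clock vs trial
#'   clock).
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(samples, sample_rate_hz, leg = c("left", "right"),
                      t0 = 0) {
  leg <- match.arg(leg)
  stopifnot(sample_rate_hz > 0, length(samples) > 0, is.numeric(samples))
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = sample_rate_hz, leg = leg, t0 = t0),
            class = "raw_trace")
}

#' Mean-range normalization of an angular-velocity trace
#'
#' Subtracts the trace mean and divides by the trace range, yielding a
#' zero-mean, unit-range, unitless signal. The map is affine, so signal
#' shape and peak ordering are preserved; normalizing per trial and per leg
#' makes downstream peak thresholds subject-independent.
#'
#' @param trace A `raw_trace` (or `normalized_trace`; normalization is
#'   idempotent up to numerical tolerance).
#' @return A `normalized_trace` with the same sample rate and leg.
#' @export
normalize_signal <- function(trace) {
  stopifnot(inherits(trace, c("raw_trace", "normalized_trace")))
  x <- trace$samples
  rng <- max(x) - min(x)
  if (rng == 0) stop("cannot normalize a constant (zero-range) signal")
  structure(list(samples = (x - mean(x)) / rng,
                 sample_rate_hz = trace$sample_rate_hz, leg = trace$leg,
                 t0 = trace$t0 %||% 0),
            class = "normalized_trace")
}

# Locate the sit-to-stand transient: index of max |signal| within the first
# `window_s` seconds. Errors if that maximum does not clearly dominate the
# trace (no detectable stand-up peak).
find_standup_peak <- function(trace, window_s = 10, min_prominence = 5) {
  x <- trace$samples
  fs <- trace$sample_rate_hz
  n_win <- min(length(x), round(window_s * fs))
  seg <- abs(x[seq_len(n_win)])
  i <- which.max(seg)
  floor_amp <- stats::median(abs(x))
  if (seg[i] < min_prominence * max(floor_amp, .Machine$double.eps)) {
    stop("no detectable stand-up peak in the early window")
  }
  i
}

#' Synchronize the two leg traces via the sit-to-stand peak
#'
#' Both devices record the same stand-up transient; superimposing the two
#' stand-up peaks recovers the inter-device start delay. The later-starting
#' trace is shifted so the peaks coincide, and both traces are trimmed to
#' their common overlap.
#'
#' @param left,right Traces of class `raw_trace` or `normalized_trace`.
#' @param window_s Early window searched for the stand-up peak, seconds.
#' @param min_prominence Required ratio of the stand-up peak to the trace's
#'   median absolute amplitude.
#' @return List with `left`, `right` (aligned, equal-length traces sharing
#'   the left trace's clock) and `estimated_delay_s` (positive when the
#'   right device started later: its stand-up peak appears earlier in its
#'   own recording).
#' @export
synchronize_legs <- function(left, right, window_s = 10,
                             min_prominence = 5) {
  stopifnot(left$sample_rate_hz == right$sample_rate_hz)
  fs <- left$sample_rate_hz
  i_l <- find_standup_peak(left, window_s, min_prominence)
  i_r <- find_standup_peak(right, window_s, min_prominence)
  shift <- i_l - i_r           # samples to drop from the front of `left`
  delay_s <- shift / fs
  xl <- left$samples
  xr <- right$samples
  if (shift > 0) {
    xl <- xl[-seq_len(shift)]
  } else if (shift < 0) {
    xr <- xr[-seq_len(-shift)]
  }
  n <- min(length(xl), length(xr))
  # aligned traces stay on the left device's clock: when samples are
  # dropped from the front of `left`, the aligned clock starts that much
  # later within it
  t0_aligned <- (left$t0 %||% 0) + max(shift, 0) / fs
  aligned <- function(x, tmpl) structure(
    list(samples = x[seq_len(n)], sample_rate_hz = fs, leg = tmpl$leg,
         t0 = t0_aligned),
    class = class(tmpl))
  list(left = aligned(xl, left), right = aligned(xr, right),
       estimated_delay_s = delay_s,
       standup_index = min(i_l, i_r))
}

#' Write a trial's traces and annotations to disk
#'
#' One CSV per leg (`<trial_id>_left.csv`, `<trial_id>_right.csv`, columns
#' `time_s`, `omega_x`) plus a JSON annotation sidecar holding the FOG
#' episodes and the generator ground truth when present.
#'
#' @param trial A `fog_trial`.
#' @param dir Output directory (created if missing).
#' @param digits Decimal digits used for samples in the CSV.
#' @return Invisible named list of the written paths.
#' @export
write_trial_csv <- function(trial, dir, digits = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (leg in c("left", "right")) {
    tr <- trial[[leg]]
    tt <- tr$t0 + (seq_along(tr$samples) - 1) / tr$sample_rate_hz
    df <- data.frame(time_s = round(tt, 6),
                     omega_x = round(tr$samples, digits))
    p <- file.path(dir, sprintf("%s_%s.csv", trial$trial_id, leg))
    utils::write.csv(df, p, row.names = FALSE)
    paths[[leg]] <- p
  }
  ann <- list(
    episodes = trial$annotations,
    subject_id = trial$subject_id,
    condition = trial$condition,
    trial_id = trial$trial_id,
    sample_rate_hz = trial$sample_rate_hz
  )
  if (!is.null(trial$truth)) ann$truth <- trial$truth
  pa <- file.path(dir, sprintf("%s_annotations.json", trial$trial_id))
  jsonlite::write_json(ann, pa, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  paths$annotations <- pa
  invisible(paths)
}

read_leg_csv <- function(path, leg, sample_rate_hz) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (nrow(df) == 0) stop("empty trial file: ", path)
  if (!"omega_x" %in% names(df)) {
    alt <- paste0("omega_x_", leg)
    if (alt %in% names(df)) {
      df$omega_x <- df[[alt]]
    } else {
      stop("missing required column 'omega_x' in ", path)
    }
  }
  gaps <- data.frame(after_row = integer(0), gap_s = numeric(0))
  t0 <- 0
  if ("time_s" %in% names(df)) {
    tt <- df$time_s
    if (is.unsorted(tt, strictly = TRUE)) {
      stop("non-monotonic time column in ", path)
    }
    t0 <- tt[1]
    dt <- diff(tt)
    thr <- 1.5 / sample_rate_hz
    bad <- which(dt > thr)
    if (length(bad)) {
      gaps <- data.frame(after_row = bad, gap_s = dt[bad])
    }
  }
  list(trace = raw_trace(df$omega_x, sample_rate_hz, leg, t0 = t0),
       gaps = gaps)
}

#' Read a trial from CSV traces and a JSON annotation sidecar
#'
#' Accepts one file per leg (columns `time_s`, `omega_x`) or a single file
#' with `omega_x_left` / `omega_x_right` columns. Gaps in the time column
#' larger than 1.5 sample periods are reported in the attached gap log, not
#' repaired.
#'
#' @param left_path,right_path CSV paths (pass the same path twice for a
#'   combined two-leg file).
#' @param annotation_path JSON sidecar path (optional; `NULL` for no
#'   annotations).
#' @param sample_rate_hz Declared sampling rate.
#' @param subject_id,condition,trial_id Metadata; values in the annotation
#'   sidecar take precedence.
#' @return A `fog_trial` with a `gap_log` data frame attached.
#' @export
read_trial_csv <- function(left_path, right_path,
                           annotation_path = NULL, sample_rate_hz = 60,
                           subject_id = NA_character_,
                           condition = NA_character_,
                           trial_id = NA_character_) {
  ann <- NULL
  if (!is.null(annotation_path)) {
    if (!file.exists(annotation_path)) {
      stop("annotation file not found: ", annotation_path)
    }
    ann <- jsonlite::read_json(annotation_path, simplifyVector = TRUE)
    subject_id <- ann$subject_id %||% subject_id
    condition <- ann$condition %||% condition
    trial_id <- ann$trial_id %||% trial_id
    sample_rate_hz <- ann$sample_rate_hz %||% sample_rate_hz
  }
  l <- read_leg_csv(left_path, "left", sample_rate_hz)
  r <- read_leg_csv(right_path, "right", sample_rate_hz)
  episodes <- if (!is.null(ann) && length(ann$episodes)) {
    as.data.frame(ann$episodes)
  } else {
    data.frame(start_s = numeric(0), end_s = numeric(0),
               phenotype = character(0), at_gait_initiation = logical(0))
  }
  gap_log <- rbind(
    if (nrow(l$gaps)) cbind(leg = "left", l$gaps),
    if (nrow(r$gaps)) cbind(leg = "right", r$gaps)
  )
  if (is.null(gap_log)) {
    gap_log <- data.frame(leg = character(0), after_row = integer(0),
                          gap_s = numeric(0))
  }
  truth <- if (!is.null(ann$truth)) {
    tr <- ann$truth
    if (!is.null(tr$steps)) tr$steps <- as.data.frame(tr$steps)
    tr
  } else NULL
  structure(list(left = l$trace, right = r$trace, annotations = episodes,
                 truth = truth, subject_id = subject_id,
                 condition = condition, trial_id = trial_id,
                 sample_rate_hz = sample_rate_hz, gap_log = gap_log),
            class = "fog_trial")
}

#' Write a cohort (trials, annotations, manifest) to a directory
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Target directory.
#' @return Invisible manifest data frame with file paths added.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$left_file <- NA_character_
  man$right_file <- NA_character_
  man$annotation_file <- NA_character_
  for (i in seq_len(nrow(man))) {
    p <- write_trial_csv(cohort$trials[[man$trial_id[i]]], dir)
    man$left_file[i] <- basename(p$left)
    man$right_file[i] <- basename(p$right)
    man$annotation_file[i] <- basename(p$annotations)
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a cohort back from a manifest directory
#'
#' @param dir Directory containing `manifest.csv` and the per-trial files.
#' @return List with `trials` and `manifest`, mirroring
#'   [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("manifest.csv not found in ", dir)
  man <- utils::read.csv(man_path)
  trials <- list()
  for (i in seq_len(nrow(man))) {
    trials[[man$trial_id[i]]] <- read_trial_csv(
      file.path(dir, man$left_file[i]),
      file.path(dir, man$right_file[i]),
      file.path(dir, man$annotation_file[i])
    )
  }
  list(trials = trials, manifest = man)
}
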