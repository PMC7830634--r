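#' Names of the 16 per-step features
#'
#' Time domain: standard deviation, range and RMS of the Type I slice;
#' angular jerk and normalized jerk of the Type II slice; dynamic time
#' warping stride similarity between consecutive same-leg Type I slices;
#' step and stride time from peak-to-peak intervals; peak height and
#' half-power width of the Type II lobe. Frequency domain (Type I slice):
#' power spectral entropy, principal harmonic frequency/amplitude/width,
#' weighted power spectral peak (amplitude x frequency) and low power
#' frequency (fraction of spectral power below 2 Hz).
#'
#' @return Character vector of the 16 feature column names, in canonical
#'   order.
#' @export
fog_feature_names <- function() {
  c("std", "range", "rms", "angular_jerk", "normalized_jerk",
    "stride_similarity", "step_time_s", "stride_time_s",
    "peak_height", "peak_width_s",
    "power_spectral_entropy", "principal_harmonic_freq_hz",
    "principal_harmonic_amp", "principal_harmonic_width_hz",
    "weighted_power_spectral_peak", "low_power_frequency")
}

#' Basic time-domain statistics of a Type I slice
#'
#' @param x Numeric slice (length >= 2).
#' @return Named list: `std` (population standard deviation), `range`
#'   (max - min), `rms`.
#' @export
basic_stats <- function(x) {
  if (length(x) < 2) stop("slice too short for basic statistics")
  list(std = sqrt(mean((x - mean(x))^2)),
       range = max(x) - min(x),
       rms = sqrt(mean(x^2)))
}

#' Angular jerk of a Type II slice
#'
#' The rate of variation of angular acceleration, `0.5 * integral of the
#' squared second derivative of angular velocity over the slice`. The
#' second derivative is estimated by central second differences scaled by
#' the squared sample rate; the integral uses the trapezoid rule over the
#' interior samples.
#'
#' @param x Numeric slice (length >= 3).
#' @param sample_rate_hz Sampling rate, Hz.
#' @return Non-negative scalar.
#' @export
angular_jerk <- function(x, sample_rate_hz) {
  n <- length(x)
  if (n < 3) stop("slice too short for a second difference")
  d2 <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * sample_rate_hz^2
  v <- d2^2
  dt <- 1 / sample_rate_hz
  integral <- if (length(v) == 1) v * dt else
    sum((v[-1] + v[-length(v)]) / 2) * dt
  0.5 * integral
}

#' Angular jerk normalized by the slice duration
#'
#' @inheritParams angular_jerk
#' @return `angular_jerk(x) / duration`, duration = `(length(x) - 1) /
#'   sample_rate_hz`.
#' @export
normalized_jerk <- function(x, sample_rate_hz) {
  dur <- (length(x) - 1) / sample_rate_hz
  if (dur <= 0) stop("slice duration must be positive")
  angular_jerk(x, sample_rate_hz) / dur
}

#' Dynamic time warping alignment cost between two strides
#'
#' Classic DTW with absolute-difference local cost and the symmetric
#' match/insert/delete step pattern, no window constraint. The cumulative
#' alignment cost is 0 iff the sequences are identical and grows with
#' stride-to-stride dissimilarity (the paper's "inversely proportional to
#' similarity" convention).
#'
#' @param a,b Numeric sequences (non-empty).
#' @return Scalar alignment cost.
#' @export
dtw_distance <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) stop("DTW inputs must be non-empty")
  # rolling two-row DP over the local cost lattice
  prev <- numeric(m)
  cur <- numeric(m)
  prev[1] <- abs(a[1] - b[1])
  if (m > 1) for (j in 2:m) prev[j] <- prev[j - 1] + abs(a[1] - b[j])
  if (n > 1) {
    for (i in 2:n) {
      cur[1] <- prev[1] + abs(a[i] - b[1])
      if (m > 1) {
        for (j in 2:m) {
          cur[j] <- abs(a[i] - b[j]) + min(prev[j], cur[j - 1], prev[j - 1])
        }
      }
      prev <- cur
    }
  }
  prev[m]
}

#' Step and stride times from peak timing
#'
#' Step time is the interval from the previous contralateral peak to the
#' current peak; stride time is the interval from the previous same-leg
#' peak.
#'
#' @param segment A `step_segment`.
#' @return Named list `step_time_s` (NA when no earlier contralateral peak
#'   exists) and `stride_time_s`.
#' @export
step_and_stride_times <- function(segment) {
  list(step_time_s = segment$peak_time_s -
         segment$prev_contralateral_peak_time_s,
       stride_time_s = segment$peak_time_s - segment$prev_peak_time_s)
}

#' Height and half-power width of the Type II lobe
#'
#' Height is the maximum sample (relative to zero); width is the duration
#' over which the slice exceeds `height / sqrt(2)` (half power in
#' amplitude), with the crossing instants linearly interpolated.
#'
#' @param x Positive-lobe slice containing its maximum.
#' @param sample_rate_hz Sampling rate, Hz.
#' @return Named list `peak_height`, `peak_width_s`.
#' @export
peak_geometry <- function(x, sample_rate_hz) {
  if (max(x) <= 0) stop("non-positive slice: no peak to measure")
  h <- max(x)
  thr <- h / sqrt(2)
  i_max <- which.max(x)
  lo <- i_max
  while (lo > 1 && x[lo - 1] >= thr) lo <- lo - 1
  hi <- i_max
  while (hi < length(x) && x[hi + 1] >= thr) hi <- hi + 1
  t_lo <- lo
  if (lo > 1) t_lo <- lo - (thr - x[lo]) / (x[lo - 1] - x[lo])  # interp
  t_hi <- hi
  if (hi < length(x)) t_hi <- hi + (x[hi] - thr) / (x[hi] - x[hi + 1])
  list(peak_height = h, peak_width_s = (t_hi - t_lo) / sample_rate_hz)
}

#' One-sided normalized power spectrum of a Type I slice
#'
#' The mean-removed slice is zero-padded to `n_fft` samples; the squared
#' FFT magnitude over the non-negative frequencies is normalized to unit
#' sum.
#'
#' @param x Numeric slice (length >= 4).
#' @param sample_rate_hz Sampling rate, Hz.
#' @param n_fft FFT length (slices longer than `n_fft` are not truncated;
#'   the next power of two is used instead).
#' @return List `power` (normalized spectrum, sums to 1) and `freq_hz`.
#' @export
spectrum_type1 <- function(x, sample_rate_hz, n_fft = 512) {
  if (length(x) < 4) stop("slice too short for a spectrum")
  x <- x - mean(x)
  if (all(x == 0)) stop("zero slice after mean removal: spectrum undefined")
  if (length(x) > n_fft) n_fft <- 2^ceiling(log2(length(x)))
  xp <- c(x, numeric(n_fft - length(x)))
  p <- Mod(stats::fft(xp))^2
  half <- p[seq_len(n_fft %/% 2 + 1)]
  list(power = half / sum(half),
       freq_hz = (0:(n_fft %/% 2)) * sample_rate_hz / n_fft)
}

#' Power spectral entropy
#'
#' Shannon entropy of the normalized spectrum, `-sum(P * log(P + eps))`
#' with natural logarithm; the small `eps` keeps the value finite on empty
#' bins.
#'
#' @param power Normalized spectrum (sums to 1 within 1e-6).
#' @param eps Stabilizing constant (default 0.001).
#' @return Scalar entropy (nats).
#' @export
power_spectral_entropy <- function(power, eps = 0.001) {
  if (abs(sum(power) - 1) > 1e-6) stop("spectrum must be normalized")
  -sum(power * log(power + eps))
}

#' Principal harmonic of a normalized spectrum
#'
#' The highest non-DC spectral bin, its frequency, the half-power width of
#' the surrounding peak (interpolated at `amplitude / 2` crossings) and the
#' amplitude x frequency product.
#'
#' @param power Normalized spectrum.
#' @param freq_hz Frequency axis.
#' @return List `freq_hz`, `amplitude`, `width_hz`, `weighted_peak`.
#' @export
principal_harmonic <- function(power, freq_hz) {
  if (length(power) < 3) stop("spectrum too short")
  p <- power[-1]                      # exclude the DC bin from the search
  if (all(p <= 0)) stop("no non-DC spectral content")
  i <- which.max(p) + 1L
  amp <- power[i]
  thr <- amp / 2
  df <- freq_hz[2] - freq_hz[1]
  lo <- i
  while (lo > 1 && power[lo - 1] >= thr) lo <- lo - 1
  f_lo <- freq_hz[lo]
  if (lo > 1) {
    f_lo <- freq_hz[lo] - df * (power[lo] - thr) / (power[lo] - power[lo - 1])
  }
  hi <- i
  while (hi < length(power) && power[hi + 1] >= thr) hi <- hi + 1
  f_hi <- freq_hz[hi]
  if (hi < length(power)) {
    f_hi <- freq_hz[hi] + df * (power[hi] - thr) / (power[hi] - power[hi + 1])
  }
  list(freq_hz = freq_hz[i], amplitude = amp, width_hz = f_hi - f_lo,
       weighted_peak = amp * freq_hz[i])
}

#' Low power frequency: fraction of spectral power below 2 Hz
#'
#' @param power Normalized spectrum.
#' @param freq_hz Frequency axis.
#' @param band Upper band edge in Hz (default 2).
#' @return Ratio in `[0, 1]`.
#' @export
low_power_frequency <- function(power, freq_hz, band = 2) {
  sum(power[freq_hz <= band])
}

#' Extract the 16-feature vector for one step segment
#'
#' @param segment A `step_segment` (see [segment_steps()]).
#' @param sample_rate_hz Sampling rate, Hz.
#' @param n_fft FFT length for the spectral features.
#' @return Named list of the 16 features; `stride_similarity` and
#'   `step_time_s` are `NA` when the previous same-leg stride or
#'   contralateral peak is missing (such steps are dropped by
#'   [extract_trial_features()]).
#' @export
extract_features <- function(segment, sample_rate_hz, n_fft = 512) {
  bs <- basic_stats(segment$type1)
  sp <- spectrum_type1(segment$type1, sample_rate_hz, n_fft)
  ph <- principal_harmonic(sp$power, sp$freq_hz)
  pg <- peak_geometry(segment$type2, sample_rate_hz)
  tm <- step_and_stride_times(segment)
  ss <- if (is.null(segment$prev_type1)) NA_real_ else
    dtw_distance(segment$type1, segment$prev_type1)
  list(
    std = bs$std, range = bs$range, rms = bs$rms,
    angular_jerk = angular_jerk(segment$type2, sample_rate_hz),
    normalized_jerk = normalized_jerk(segment$type2, sample_rate_hz),
    stride_similarity = ss,
    step_time_s = tm$step_time_s,
    stride_time_s = tm$stride_time_s,
    peak_height = pg$peak_height,
    peak_width_s = pg$peak_width_s,
    power_spectral_entropy = power_spectral_entropy(sp$power),
    principal_harmonic_freq_hz = ph$freq_hz,
    principal_harmonic_amp = ph$amplitude,
    principal_harmonic_width_hz = ph$width_hz,
    weighted_power_spectral_peak = ph$weighted_peak,
    low_power_frequency = low_power_frequency(sp$power, sp$freq_hz)
  )
}

#' Full per-trial feature matrix
#'
#' Normalizes both legs, synchronizes them on the stand-up transient,
#' detects mid-swing peaks outside the non-gait prefix (everything up to
#' the stand-up time plus `settle_s`), segments each leg and computes the
#' 16 features per step. Steps lacking a previous same-leg stride or a
#' previous contralateral peak (the first one or two steps per leg) are
#' dropped rather than imputed.
#'
#' @param trial A `fog_trial`.
#' @param settle_s Non-gait settling time after the stand-up transient.
#' @param n_fft FFT length.
#' @param min_height_frac,min_separation_s Peak-detection thresholds, see
#'   [detect_peaks()].
#' @return Data frame: metadata columns (`subject_id`, `condition`,
#'   `trial_id`, `leg`, `peak_time_s`, in the aligned trial clock) followed
#'   by the 16 feature columns.
#' @export
extract_trial_features <- function(trial, settle_s = 3.5, n_fft = 512,
                                   min_height_frac = 0.2,
                                   min_separation_s = 0.35) {
  fs <- trial$sample_rate_hz
  nl <- normalize_signal(trial$left)
  nr <- normalize_signal(trial$right)
  sync <- synchronize_legs(nl, nr)
  standup_s <- (sync$left$t0 %||% 0) + (sync$standup_index - 1) / fs
  excl <- standup_s + settle_s
  pk <- lapply(list(left = sync$left, right = sync$right), detect_peaks,
               min_height_frac = min_height_frac,
               min_separation_s = min_separation_s,
               exclude_before_s = excl)
  segs <- c(segment_steps(sync$left, pk$left, pk$right),
            segment_steps(sync$right, pk$right, pk$left))
  rows <- lapply(segs, function(sg) {
    # degenerate segments (a positive lobe too short for a second
    # difference, or a stride slice too short for a spectrum) carry no
    # usable swing and are dropped like other incomplete steps
    if (length(sg$type2) < 3 || length(sg$type1) < 4) return(NULL)
    fv <- tryCatch(extract_features(sg, fs, n_fft), error = function(e) NULL)
    if (is.null(fv)) return(NULL)
    if (is.na(fv$stride_similarity) || is.na(fv$step_time_s)) return(NULL)
    cbind(data.frame(subject_id = trial$subject_id,
                     condition = trial$condition,
                     trial_id = trial$trial_id,
                     leg = sg$leg,
                     peak_time_s = sg$peak_time_s),
          as.data.frame(fv))
  })
  rows <- rows[!vapply(rows, is.null, NA)]
  if (!length(rows)) {
    out <- cbind(data.frame(subject_id = character(0),
                            condition = character(0),
                            trial_id = character(0), leg = character(0),
                            peak_time_s = numeric(0)),
                 as.data.frame(stats::setNames(
                   rep(list(numeric(0)), 16), fog_feature_names())))
    return(out)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Feature matrix for a whole cohort
#'
#' @param cohort List with `trials` (as from [generate_cohort()] or
#'   [read_cohort()]).
#' @param ... Passed to [extract_trial_features()].
#' @return Row-bound feature data frame over all trials.
#' @export
extract_cohort_features <- function(cohort, ...) {
  do.call(rbind, c(lapply(cohort$trials, extract_trial_features, ...),
                   make.row.names = FALSE))
}
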