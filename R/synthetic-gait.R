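#' Gait morphology profile for the synthetic generator
#'
#' Describes one subject's normal-gait signal morphology: alternating-leg
#' swing peaks (raised-cosine positive lobe at mid-swing, smaller negative
#' trough between swings) in the shank angular-velocity channel.
#'
#' @param cadence_hz Stride frequency per leg in Hz (typical 0.8--1.2; each
#'   leg produces one swing peak per stride, the two legs alternate).
#' @param swing_amp Peak angular-velocity amplitude of a swing lobe
#'   (arbitrary units; downstream analysis normalizes them away).
#' @param swing_duration_s Duration of the positive swing lobe, seconds.
#' @param trough_amp Amplitude of the negative inter-swing lobe, as a
#'   fraction of `swing_amp`.
#' @param noise_sd Standard deviation of additive white noise.
#' @param phase_offset Contralateral phase lag as a fraction of the stride
#'   cycle (0.5 = perfectly alternating gait).
#' @return An object of class `gait_profile`.
#' @export
gait_profile <- function(cadence_hz = 1.0, swing_amp = 1.0,
                         swing_duration_s = 0.45, trough_amp = 0.3,
                         noise_sd = 0.05, phase_offset = 0.5) {
  stopifnot(cadence_hz > 0, swing_amp > 0, noise_sd >= 0,
            swing_duration_s > 0, swing_duration_s < 1 / cadence_hz,
            phase_offset > 0, phase_offset < 1)
  structure(list(cadence_hz = cadence_hz, swing_amp = swing_amp,
                 swing_duration_s = swing_duration_s, trough_amp = trough_amp,
                 noise_sd = noise_sd, phase_offset = phase_offset),
            class = "gait_profile")
}

#' Pre-FOG gait degradation profile
#'
#' Parameterizes the walking-pattern degradation the generator applies in a
#' window immediately preceding each FOG episode: swing amplitude shrinks,
#' steps become faster/shorter, and spectral content shifts upward in
#' frequency. Factors ramp from their normal-gait values at the start of the
#' window to the stated onset values at episode onset.
#'
#' @param window_s Length of the pre-FOG window over which degradation
#'   ramps, seconds.
#' @param amp_decay Multiplicative swing-amplitude factor reached at episode
#'   onset (in (0, 1]; 1 = no decay).
#' @param steptime_shrink Multiplicative step-period factor reached at onset
#'   (in (0, 1]; smaller = faster, shorter steps).
#' @param freq_shift Amplitude of the added high-frequency component at
#'   onset, as a fraction of `swing_amp`.
#' @param ramp_shape `"linear"` or `"quadratic"` ramp of the degradation
#'   over the window.
#' @param hf_hz Frequency of the added high-frequency component, Hz.
#' @return An object of class `degradation_profile`.
#' @export
degradation_profile <- function(window_s = 2, amp_decay = 0.5,
                                steptime_shrink = 0.7, freq_shift = 0.25,
                                ramp_shape = c("linear", "quadratic"),
                                hf_hz = 6) {
  ramp_shape <- match.arg(ramp_shape)
  stopifnot(window_s > 0, amp_decay > 0, amp_decay <= 1,
            steptime_shrink > 0, steptime_shrink <= 1, freq_shift >= 0)
  structure(list(window_s = window_s, amp_decay = amp_decay,
                 steptime_shrink = steptime_shrink, freq_shift = freq_shift,
                 ramp_shape = ramp_shape, hf_hz = hf_hz),
            class = "degradation_profile")
}

#' Specification of one FOG episode
#'
#' @param onset_s,duration_s Episode bounds (trial clock), seconds.
#' @param phenotype `"trembling"` (low-amplitude leg trembling) or
#'   `"akinetic"` (near-zero signal).
#' @param tremble_hz Trembling oscillation frequency, Hz (typical 4--7).
#' @param tremble_amp Trembling amplitude as a fraction of the swing
#'   amplitude.
#' @param at_gait_initiation Logical flag marking episodes occurring during
#'   the stand-to-walk transition (excluded from pre-FOG analysis).
#' @return An object of class `fog_episode`.
#' @export
fog_episode <- function(onset_s, duration_s,
                        phenotype = c("trembling", "akinetic"),
                        tremble_hz = 5, tremble_amp = 0.3,
                        at_gait_initiation = FALSE) {
  phenotype <- match.arg(phenotype)
  stopifnot(duration_s > 0, onset_s >= 0, tremble_hz > 0, tremble_amp >= 0)
  structure(list(onset_s = onset_s, duration_s = duration_s,
                 phenotype = phenotype, tremble_hz = tremble_hz,
                 tremble_amp = tremble_amp,
                 at_gait_initiation = isTRUE(at_gait_initiation)),
            class = "fog_episode")
}

episodes_to_df <- function(episodes) {
  if (length(episodes) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      phenotype = character(0),
                      at_gait_initiation = logical(0)))
  }
  data.frame(
    start_s = vapply(episodes, function(e) e$onset_s, 0),
    end_s = vapply(episodes, function(e) e$onset_s + e$duration_s, 0),
    phenotype = vapply(episodes, function(e) e$phenotype, ""),
    at_gait_initiation = vapply(episodes, function(e) e$at_gait_initiation, NA)
  )
}

check_episodes <- function(episodes, duration_s) {
  if (length(episodes) == 0) return(invisible(NULL))
  df <- episodes_to_df(episodes)
  o <- order(df$start_s)
  df <- df[o, ]
  if (any(df$end_s > duration_s)) {
    stop("FOG episode extends beyond trial end")
  }
  if (nrow(df) > 1 && any(df$start_s[-1] < df$end_s[-nrow(df)])) {
    stop("FOG episodes overlap")
  }
  invisible(NULL)
}

# Ramp value in [0,1]: 0 well before any episode, rising to 1 at the onset
# of the episode whose pre-FOG window contains `t`.
deg_ramp <- function(t, ep_df, degradation) {
  if (nrow(ep_df) == 0) return(0)
  for (i in seq_len(nrow(ep_df))) {
    a <- ep_df$start_s[i] - degradation$window_s
    if (t >= a && t < ep_df$start_s[i]) {
      u <- (t - a) / degradation$window_s
      return(if (degradation$ramp_shape == "quadratic") u^2 else u)
    }
  }
  0
}

raised_cosine <- function(t, center, width, amp) {
  out <- numeric(length(t))
  sel <- abs(t - center) <= width / 2
  out[sel] <- amp / 2 * (1 + cos(2 * pi * (t[sel] - center) / width))
  out
}

#' Generate one synthetic two-shin trial
#'
#' Simulates a timed-up-and-go-like recording: quiet sitting, a single
#' high-amplitude biphasic sit-to-stand transient (shared by both legs in
#' the trial clock; each device additionally starts recording at a random
#' offset, so the transient serves as the synchronization anchor), a settle
#' interval, then alternating-leg walking with optional FOG episodes and
#' pre-FOG degradation confined to a window before each episode onset.
#'
#' @param profile A [gait_profile()].
#' @param episodes List of [fog_episode()] objects (non-overlapping).
#' @param degradation A [degradation_profile()].
#' @param sample_rate_hz Sampling rate, Hz (default 60).
#' @param duration_s Trial duration, seconds.
#' @param seed Integer seed; identical seeds give bit-identical trials.
#' @param sync_offset_s Inter-device start offset of the right device,
#'   seconds; `NULL` draws uniformly from `sync_offset_range_s`. Snapped to
#'   a whole number of samples.
#' @param sync_offset_range_s Range for the random offset draw.
#' @param sit_s Time of the sit-to-stand transient.
#' @param settle_s Settling time after standing before walking starts.
#' @param subject_id,condition,trial_id Metadata carried on the trial.
#' @return A `fog_trial`: left/right `raw_trace`s (right cropped by its
#'   start offset), an `annotations` data frame, and a `truth` list holding
#'   the generator's ground-truth step times/amplitudes per leg, the
#'   stand-up time, walk start and the injected device offset.
#' @export
generate_trial <- function(profile, episodes = list(),
                           degradation = degradation_profile(),
                           sample_rate_hz = 60, duration_s = 60,
                           seed = NULL, sync_offset_s = NULL,
                           sync_offset_range_s = c(0.1, 0.7),
                           sit_s = 3, settle_s = 3.5,
                           subject_id = "S1", condition = "on",
                           trial_id = "T1") {
  check_episodes(episodes, duration_s)
  walk_start <- sit_s + settle_s
  if (duration_s <= walk_start + 1) {
    stop("duration_s too short to accommodate sitting, stand-up and walking")
  }
  with_seed(seed, {
    fs <- sample_rate_hz
    n <- round(duration_s * fs)
    t <- (0:(n - 1)) / fs
    ep_df <- episodes_to_df(episodes)
    ep_df <- ep_df[order(ep_df$start_s), , drop = FALSE]

    ## ---- step event sequence (alternating legs) ----
    stride0 <- 1 / profile$cadence_hz
    end_margin <- profile$swing_duration_s / 2 + 1 / fs
    in_forbidden <- function(tt) {
      if (nrow(ep_df) == 0) return(NA_integer_)
      hit <- which(tt >= ep_df$start_s - profile$swing_duration_s / 2 &
                     tt <= ep_df$end_s + 0.3)
      if (length(hit)) hit[1] else NA_integer_
    }
    times <- numeric(0); legs <- character(0); amps <- numeric(0)
    cur <- walk_start + 0.3 * stride0
    leg <- "left"
    while (cur <= duration_s - end_margin) {
      hit <- in_forbidden(cur)
      if (!is.na(hit)) {
        cur <- ep_df$end_s[hit] + 0.35
        next
      }
      s <- deg_ramp(cur, ep_df, degradation)
      amp_f <- 1 - (1 - degradation$amp_decay) * s
      per_f <- 1 - (1 - degradation$steptime_shrink) * s
      times <- c(times, cur)
      legs <- c(legs, leg)
      amps <- c(amps, profile$swing_amp * amp_f)
      stride_now <- stride0 * per_f
      step_gap <- if (leg == "left") profile$phase_offset else
        (1 - profile$phase_offset)
      cur <- cur + step_gap * stride_now
      leg <- if (leg == "left") "right" else "left"
    }

    ## ---- waveform synthesis per leg (trial clock) ----
    make_leg <- function(which_leg) {
      x <- numeric(n)
      # sit-to-stand biphasic transient, amplitude 2x max swing amplitude
      a_su <- 2 * profile$swing_amp
      x <- x + raised_cosine(t, sit_s, 0.3, a_su)
      x <- x - raised_cosine(t, sit_s + 0.3, 0.3, 0.8 * a_su)
      sel <- which(legs == which_leg)
      for (k in sel) {
        x <- x + raised_cosine(t, times[k], profile$swing_duration_s, amps[k])
      }
      # negative troughs between consecutive same-leg swings
      if (length(sel) > 1) {
        for (j in seq_len(length(sel) - 1)) {
          t1 <- times[sel[j]]; t2 <- times[sel[j + 1]]
          if (t2 - t1 <= 1.6 * stride0) {
            mid <- (t1 + t2) / 2
            x <- x - raised_cosine(t, mid, 0.45 * (t2 - t1),
                                   profile$trough_amp *
                                     min(amps[sel[j]], amps[sel[j + 1]]))
          }
        }
      }
      # pre-FOG high-frequency component
      if (nrow(ep_df) > 0 && degradation$freq_shift > 0) {
        for (i in seq_len(nrow(ep_df))) {
          a <- ep_df$start_s[i] - degradation$window_s
          win <- which(t >= a & t < ep_df$start_s[i])
          if (length(win)) {
            u <- (t[win] - a) / degradation$window_s
            s <- if (degradation$ramp_shape == "quadratic") u^2 else u
            x[win] <- x[win] + degradation$freq_shift * profile$swing_amp *
              s * sin(2 * pi * degradation$hf_hz * t[win])
          }
        }
      }
      # FOG episodes
      if (nrow(ep_df) > 0) {
        for (i in seq_len(nrow(ep_df))) {
          win <- which(t >= ep_df$start_s[i] & t <= ep_df$end_s[i])
          if (!length(win)) next
          if (ep_df$phenotype[i] == "trembling") {
            ep <- episodes[[order(episodes_to_df(episodes)$start_s)[i]]]
            tt <- t[win] - ep_df$start_s[i]
            dur <- ep_df$end_s[i] - ep_df$start_s[i]
            taper <- pmin(1, tt / 0.2, (dur - tt) / 0.2)
            taper[taper < 0] <- 0
            x[win] <- x[win] + ep$tremble_amp * profile$swing_amp *
              sin(2 * pi * ep$tremble_hz * tt) * taper
          } # akinetic: leave near-zero (noise only)
        }
      }
      x
    }
    left <- make_leg("left")
    right <- make_leg("right")
    if (profile$noise_sd > 0) {
      left <- left + rnorm(n, 0, profile$noise_sd)
      right <- right + rnorm(n, 0, profile$noise_sd)
    }

    ## ---- inter-device start offset (right device starts late) ----
    if (is.null(sync_offset_s)) {
      sync_offset_s <- stats::runif(1, sync_offset_range_s[1],
                                    sync_offset_range_s[2])
    }
    off_n <- round(sync_offset_s * fs)
    sync_offset_s <- off_n / fs
    right_rec <- if (off_n > 0) right[-seq_len(off_n)] else right

    structure(list(
      left = raw_trace(left, fs, "left", t0 = 0),
      right = raw_trace(right_rec, fs, "right", t0 = sync_offset_s),
      annotations = ep_df,
      truth = list(
        steps = data.frame(leg = legs, time_s = times, amplitude = amps),
        stand_time_s = sit_s, walk_start_s = walk_start,
        sync_offset_s = sync_offset_s
      ),
      subject_id = subject_id, condition = condition, trial_id = trial_id,
      sample_rate_hz = fs,
      profile = profile, degradation = degradation
    ), class = "fog_trial")
  })
}

#' Cohort configuration for the synthetic generator
#'
#' @param n_subjects Number of subjects (>= 2; leave-one-subject-out
#'   validation requires at least two).
#' @param trials_per_subject Total trials per subject; conditions alternate
#'   on/off within subject so both therapy states are represented.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param trial_duration_s Trial duration, seconds.
#' @param episodes_per_trial Number of FOG episodes placed in each trial.
#' @param degradation Baseline (on-therapy) [degradation_profile()].
#' @param condition_effect Named numeric vector scaling degradation depth
#'   per condition (e.g. `c(on = 1, off = 1.5)`: off-therapy trials get a
#'   1.5x deeper amplitude/step-time decay and stronger frequency shift).
#' @param sync_offset_range_s Range of the random inter-device start offset.
#' @param p_gait_initiation Probability that a trial carries an extra FOG
#'   episode at gait initiation (flagged, excluded from pre-FOG analysis).
#' @param noise_sd Range from which per-subject noise SD is drawn.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 10, trials_per_subject = 2,
                          sample_rate_hz = 60, trial_duration_s = 60,
                          episodes_per_trial = 3,
                          degradation = degradation_profile(),
                          condition_effect = c(on = 1, off = 1.5),
                          sync_offset_range_s = c(0.1, 0.7),
                          p_gait_initiation = 0.2,
                          noise_sd = c(0.03, 0.07)) {
  stopifnot(n_subjects >= 2, trials_per_subject >= 1, sample_rate_hz > 0,
            trial_duration_s > 0, all(condition_effect > 0))
  structure(list(n_subjects = n_subjects,
                 trials_per_subject = trials_per_subject,
                 sample_rate_hz = sample_rate_hz,
                 trial_duration_s = trial_duration_s,
                 episodes_per_trial = episodes_per_trial,
                 degradation = degradation,
                 condition_effect = condition_effect,
                 sync_offset_range_s = sync_offset_range_s,
                 p_gait_initiation = p_gait_initiation,
                 noise_sd = noise_sd),
            class = "cohort_config")
}

# Scale a degradation profile's depth by `scale` (>1 = deeper decay,
# stronger frequency shift), clamped away from zero.
scale_degradation <- function(d, scale) {
  degradation_profile(
    window_s = d$window_s,
    amp_decay = max(0.05, 1 - scale * (1 - d$amp_decay)),
    steptime_shrink = max(0.3, 1 - scale * (1 - d$steptime_shrink)),
    freq_shift = min(0.9, scale * d$freq_shift),
    ramp_shape = d$ramp_shape, hf_hz = d$hf_hz
  )
}

#' Generate a synthetic cohort
#'
#' Draws per-subject gait parameters, assigns therapy conditions by
#' alternating on/off within subject, places FOG episodes in each trial and
#' generates all trials deterministically from `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed; per-trial seeds are derived from it.
#' @return List with `trials` (list of `fog_trial`) and `manifest`
#'   (data frame: subject_id, condition, trial_id, n_episodes).
#' @export
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_subjects < 2) stop("n_subjects must be >= 2")
  trials <- list()
  rows <- list()
  conds <- rep(c("on", "off"), length.out = config$trials_per_subject)
  for (si in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", si)
    subj_seed <- derive_seed(seed, si * 1000L)
    subj <- with_seed(subj_seed, list(
      profile = gait_profile(
        cadence_hz = stats::runif(1, 0.85, 1.15),
        swing_amp = stats::runif(1, 0.8, 1.2),
        swing_duration_s = 0.45,
        trough_amp = stats::runif(1, 0.25, 0.35),
        noise_sd = stats::runif(1, config$noise_sd[1], config$noise_sd[2]),
        phase_offset = 0.5
      ),
      deg_jitter = stats::runif(1, 0.9, 1.1)
    ))
    for (ti in seq_len(config$trials_per_subject)) {
      cond <- conds[ti]
      scale <- config$condition_effect[[cond]] * subj$deg_jitter
      deg <- scale_degradation(config$degradation, scale)
      trial_seed <- derive_seed(seed, si * 1000L + ti)
      eps <- with_seed(derive_seed(trial_seed, 7L),
                       draw_episodes(config, deg))
      tid <- sprintf("%s_%s_%d", sid, cond, ti)
      tr <- generate_trial(subj$profile, eps, deg,
                           sample_rate_hz = config$sample_rate_hz,
                           duration_s = config$trial_duration_s,
                           seed = trial_seed,
                           sync_offset_range_s = config$sync_offset_range_s,
                           subject_id = sid, condition = cond,
                           trial_id = tid)
      trials[[tid]] <- tr
      rows[[tid]] <- data.frame(subject_id = sid, condition = cond,
                                trial_id = tid,
                                n_episodes = nrow(tr$annotations))
    }
  }
  list(trials = trials, manifest = do.call(rbind, c(rows,
                                                    make.row.names = FALSE)))
}

# Draw episode specs for one trial: `episodes_per_trial` episodes placed in
# disjoint blocks of the walking span, plus (with probability
# p_gait_initiation) one flagged episode at gait initiation.
draw_episodes <- function(config, degradation) {
  walk_start <- 6.5
  w <- degradation$window_s
  span_lo <- walk_start + 4 + w
  span_hi <- config$trial_duration_s - 3
  span <- span_hi - span_lo
  # short trials hold fewer episodes: each block must fit the pre-FOG
  # window plus a minimal episode
  k <- config$episodes_per_trial
  while (k > 0 && (span / k - w - 0.8) < 1.5) k <- k - 1
  eps <- list()
  if (k > 0) {
    block <- span / k
    for (i in seq_len(k)) {
      dur_hi <- min(5, block - w - 1.5)
      dur <- if (dur_hi >= 3) {
        stats::runif(1, 3, dur_hi)
      } else {
        hi <- max(1.5, block - w - 0.8)
        stats::runif(1, min(1.5, hi), hi)
      }
      lo <- span_lo + (i - 1) * block + (if (i == 1) 0 else w)
      hi <- span_lo + i * block - dur - 0.5
      onset <- stats::runif(1, lo, max(lo, hi))
      pheno <- if (stats::runif(1) < 0.85) "trembling" else "akinetic"
      eps[[length(eps) + 1]] <- fog_episode(
        onset_s = onset, duration_s = dur, phenotype = pheno,
        tremble_hz = stats::runif(1, 4, 7), tremble_amp = 0.3
      )
    }
  }
  if (stats::runif(1) < config$p_gait_initiation) {
    eps[[length(eps) + 1]] <- fog_episode(
      onset_s = walk_start + 0.6, duration_s = stats::runif(1, 2, 3),
      phenotype = "trembling", tremble_hz = stats::runif(1, 4, 7),
      tremble_amp = 0.3, at_gait_initiation = TRUE
    )
  }
  eps
}
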