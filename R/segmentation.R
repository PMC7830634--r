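#' Detect mid-swing peaks in a normalized trace
#'
#' Local maxima (strictly greater than both neighbours; plateaus keep their
#' first sample) are candidate mid-swing anchors. Candidates below
#' `min_height_frac` of the maximum candidate height are discarded, and the
#' minimum separation is enforced greedily by descending height (ties keep
#' the earlier peak), so two candidates closer than `min_separation_s`
#' retain only the higher one.
#'
#' @param trace A `normalized_trace` (or any trace object with `samples`
#'   and `sample_rate_hz`).
#' @param min_height_frac Relative amplitude threshold (default 0.2: peaks
#'   must reach 20% of the maximum peak height of the same leg and trial).
#' @param min_separation_s Minimum peak separation in seconds (default
#'   0.35).
#' @param exclude_before_s Samples earlier than this time are treated as
#'   non-gait (sitting/stand-up/settling) and excluded.
#' @return A `peak_set`: list with `peak_indices` (1-based sample indices,
#'   strictly increasing), `peak_times_s` and `peak_heights`.
#' @export
detect_peaks <- function(trace, min_height_frac = 0.2,
                         min_separation_s = 0.35, exclude_before_s = 0) {
  x <- trace$samples
  fs <- trace$sample_rate_hz
  t0 <- trace$t0 %||% 0
  if (length(x) == 0) stop("empty trace")
  first_ok <- max(1L, floor((exclude_before_s - t0) * fs) + 1L)

  # local maxima with plateau handling: compare each sample to the nearest
  # differing neighbours
  n <- length(x)
  cand <- integer(0)
  if (n >= 3) {
    d <- diff(x)
    # rising-to-falling transitions; plateau -> first plateau sample
    sign_d <- sign(d)
    nz <- which(sign_d != 0)
    if (length(nz) >= 2) {
      s <- sign_d[nz]
      turn <- which(s[-length(s)] > 0 & s[-1] < 0)
      cand <- nz[turn] + 1L
    }
  }
  cand <- cand[cand >= first_ok]
  if (length(cand) == 0) {
    return(structure(list(peak_indices = integer(0),
                          peak_times_s = numeric(0),
                          peak_heights = numeric(0)),
                     class = "peak_set"))
  }
  h <- x[cand]
  keep <- h >= min_height_frac * max(h)
  cand <- cand[keep]; h <- h[keep]

  # greedy separation enforcement by descending height, ties -> earlier
  ord <- order(-h, cand)
  min_sep <- min_separation_s * fs
  accepted <- integer(0)
  for (i in ord) {
    if (all(abs(cand[i] - accepted) >= min_sep)) {
      accepted <- c(accepted, cand[i])
    }
  }
  accepted <- sort(accepted)
  structure(list(peak_indices = accepted,
                 peak_times_s = t0 + (accepted - 1) / fs,
                 peak_heights = x[accepted]),
            class = "peak_set")
}

# Walk outward from `peak` to the nearest non-positive samples; the Type II
# slice is the run of positive samples containing the peak.
positive_lobe <- function(x, peak) {
  lo <- peak
  while (lo > 1 && x[lo - 1] > 0) lo <- lo - 1
  hi <- peak
  while (hi < length(x) && x[hi + 1] > 0) hi <- hi + 1
  c(lo, hi)
}

#' Cut a leg's trace into per-step segments
#'
#' For every detected peak with a predecessor on the same leg, a
#' `step_segment` is produced holding the Type I slice (previous peak
#' exclusive to current peak inclusive; the inter-peak stride window) and
#' the Type II slice (the positive lobe containing the current peak). The
#' latest contralateral peak strictly earlier than the current peak is
#' recorded for the step-time feature.
#'
#' @param trace The `normalized_trace` the peaks were detected on.
#' @param peaks `peak_set` for this leg.
#' @param contralateral_peaks `peak_set` for the other (time-aligned) leg,
#'   or `NULL`.
#' @return List of `step_segment` objects; each holds `leg`, `peak_index`,
#'   `peak_time_s`, `peak_height`, `type1` / `type2` sample vectors,
#'   `type2_range` (index bounds), `prev_peak_time_s`,
#'   `prev_contralateral_peak_time_s` (NA if none) and `prev_type1`
#'   (previous same-leg Type I slice, NULL for the second peak of a leg).
#' @export
segment_steps <- function(trace, peaks, contralateral_peaks = NULL) {
  x <- trace$samples
  fs <- trace$sample_rate_hz
  idx <- peaks$peak_indices
  if (is.unsorted(idx, strictly = TRUE)) stop("peaks must be sorted")
  if (length(idx) && (idx[1] < 1 || idx[length(idx)] > length(x))) {
    stop("peak index out of trace bounds")
  }
  ct <- contralateral_peaks$peak_times_s %||% numeric(0)
  segs <- list()
  prev_type1 <- NULL
  for (k in seq_along(idx)) {
    if (k == 1) {
      prev_type1 <- NULL
      next
    }
    i_prev <- idx[k - 1]; i_cur <- idx[k]
    type1 <- x[(i_prev + 1):i_cur]
    lobe <- positive_lobe(x, i_cur)
    type2 <- x[lobe[1]:lobe[2]]
    t0 <- trace$t0 %||% 0
    t_cur <- t0 + (i_cur - 1) / fs
    prev_ct <- ct[ct < t_cur]
    seg <- structure(list(
      leg = trace$leg,
      peak_index = i_cur,
      peak_time_s = t_cur,
      peak_height = x[i_cur],
      type1 = type1,
      type2 = type2,
      type2_range = lobe,
      prev_peak_time_s = t0 + (i_prev - 1) / fs,
      prev_contralateral_peak_time_s =
        if (length(prev_ct)) max(prev_ct) else NA_real_,
      prev_type1 = prev_type1
    ), class = "step_segment")
    segs[[length(segs) + 1]] <- seg
    prev_type1 <- type1
  }
  # thread prev_type1 as the previous *segment's* type1 (k-1 -> k); the
  # loop above assigns it after constructing each segment, so segment 1
  # (the second peak) has no previous stride slice
  segs
}
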