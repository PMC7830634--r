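#' Labeling configuration
#'
#' @param prefog_window_s Length of the pre-FOG window before each episode
#'   onset, seconds (the model-selection sweep uses 2, 3, 4 and 5 s).
#' @param task `"detection"` (gait vs FOG; steps inside episodes are the
#'   positive class, everything else including would-be pre-FOG steps is
#'   gait) or `"prediction"` (gait vs pre-FOG; steps inside episodes are
#'   dropped).
#' @param exclude_gait_initiation Drop episodes flagged as occurring at
#'   gait initiation (applied in the prediction task only, mirroring the
#'   clinical exclusion of stand-to-walk transition episodes).
#' @return An object of class `labeling_config`.
#' @export
labeling_config <- function(prefog_window_s = 2,
                            task = c("prediction", "detection"),
                            exclude_gait_initiation = TRUE) {
  task <- match.arg(task)
  stopifnot(prefog_window_s > 0)
  structure(list(prefog_window_s = prefog_window_s, task = task,
                 exclude_gait_initiation = exclude_gait_initiation),
            class = "labeling_config")
}

#' Remove FOG episodes that occurred at gait initiation
#'
#' @param annotations Episode data frame with an `at_gait_initiation`
#'   column.
#' @return List `annotations` (filtered) and `n_excluded`.
#' @export
exclude_gait_initiation <- function(annotations) {
  if (nrow(annotations) == 0 ||
      !"at_gait_initiation" %in% names(annotations)) {
    return(list(annotations = annotations, n_excluded = 0L))
  }
  drop <- which(annotations$at_gait_initiation %in% TRUE)
  list(annotations = if (length(drop)) annotations[-drop, , drop = FALSE]
       else annotations,
       n_excluded = length(drop))
}

# Three-way label for one trial's step peak times against its episode
# table: "fog" inside [start, end]; "prefog" inside [start - window, start)
# and not inside any episode; "gait" otherwise.
label_peak_times <- function(peak_times, episodes, window_s) {
  lab <- rep("gait", length(peak_times))
  if (nrow(episodes) == 0) return(lab)
  for (i in seq_len(nrow(episodes))) {
    lab[peak_times >= episodes$start_s[i] &
          peak_times <= episodes$end_s[i]] <- "fog"
  }
  for (i in seq_len(nrow(episodes))) {
    sel <- peak_times >= episodes$start_s[i] - window_s &
      peak_times < episodes$start_s[i] & lab == "gait"
    lab[sel] <- "prefog"
  }
  lab
}

#' Label step feature rows from episode annotations
#'
#' A step belongs to an episode iff its mid-swing peak time falls inside
#' the episode bounds; it is pre-FOG iff its peak time falls in the window
#' before an onset and inside no episode (so a window reaching back into a
#' preceding episode is effectively truncated at that episode's end). The
#' detection task merges pre-FOG into gait and codes FOG as the positive
#' class; the prediction task drops FOG steps and codes pre-FOG as
#' positive. For the prediction task, gait-initiation episodes are first
#' removed when the config requests it: their steps contribute neither
#' FOG nor pre-FOG labels.
#'
#' @param features Feature data frame from [extract_cohort_features()]
#'   (needs `trial_id` and `peak_time_s`).
#' @param annotations Named list mapping trial id to an episode data frame
#'   (`start_s`, `end_s`, `at_gait_initiation`), e.g. built with
#'   [cohort_annotations()].
#' @param config A [labeling_config()].
#' @return A labeled dataset: the feature data frame with an integer
#'   `label` column (0 = gait, 1 = FOG or pre-FOG depending on task), plus
#'   attributes `task`, `prefog_window_s`, `n_gait_initiation_excluded` and
#'   a per-subject/per-condition `class_balance` data frame.
#' @export
label_steps <- function(features, annotations, config = labeling_config()) {
  stopifnot(inherits(config, "labeling_config"))
  lab3 <- character(nrow(features))
  n_excl <- 0L
  for (tid in unique(features$trial_id)) {
    rows <- which(features$trial_id == tid)
    ep <- annotations[[tid]]
    if (is.null(ep)) {
      ep <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       at_gait_initiation = logical(0))
    }
    if (config$task == "prediction" && config$exclude_gait_initiation) {
      ex <- exclude_gait_initiation(ep)
      ep <- ex$annotations
      n_excl <- n_excl + ex$n_excluded
    }
    lab3[rows] <- label_peak_times(features$peak_time_s[rows], ep,
                                   config$prefog_window_s)
  }
  if (config$task == "detection") {
    out <- features
    out$label <- as.integer(lab3 == "fog")
  } else {
    keep <- lab3 != "fog"
    out <- features[keep, , drop = FALSE]
    out$label <- as.integer(lab3[keep] == "prefog")
    if (sum(out$label) == 0) {
      warning("prediction task produced zero pre-FOG steps")
    }
  }
  rownames(out) <- NULL
  attr(out, "task") <- config$task
  attr(out, "prefog_window_s") <- config$prefog_window_s
  attr(out, "n_gait_initiation_excluded") <- n_excl
  attr(out, "label3") <- if (config$task == "detection") lab3 else
    lab3[lab3 != "fog"]
  attr(out, "class_balance") <- stats::aggregate(
    label ~ subject_id + condition, data = out,
    FUN = function(z) c(n = length(z), positives = sum(z)))
  out
}

#' Per-trial episode tables of a cohort
#'
#' @param cohort List with `trials` (each a `fog_trial`).
#' @return Named list mapping trial id to its episode data frame, the
#'   `annotations` input expected by [label_steps()].
#' @export
cohort_annotations <- function(cohort) {
  out <- lapply(cohort$trials, function(tr) tr$annotations)
  names(out) <- vapply(cohort$trials, function(tr) tr$trial_id, "")
  out
}
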