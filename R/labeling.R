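#' Label ball dwells as voluntary, spontaneous or excluded
#'
#' Applies the trial taxonomy of the gaze-controlled selection paradigm.
#' Every ball dwell receives exactly one label:
#'
#' * `excluded`, reason `"below-threshold"`: dwell shorter than
#'   `dwell_threshold` (no selection feedback was ever issued);
#' * `excluded`, reason `"late-onset"`: the first detected fixation began
#'   more than `onset_tolerance` ms after the dwell onset;
#' * `voluntary`: dwell end (taken as the saccade time) falls within
#'   `saccade_window` ms after the feedback (issued at onset +
#'   `dwell_threshold`) and the next event is a confirmation fixation
#'   starting within `confirm_window` ms of the anchor;
#' * `excluded`, reason `"delayed-confirmation"`: a confirmation fixation
#'   follows but outside the timing windows;
#' * `spontaneous`: the next event is not a confirmation fixation.
#'
#' The confirmation window is anchored at the dwell end by default
#' (`confirm_anchor = "dwell_end"`); anchoring at the feedback time is
#' available because the two readings differ only for long dwells.
#'
#' @param events `data.frame` of time-ordered, non-overlapping gaze events
#'   with columns `kind` (`ball_dwell`, `confirm_fix`, `other_fix`),
#'   `target_id`, `onset_ms`, `offset_ms`, `initial_onset_latency_ms`.
#' @param dwell_threshold dwell-time threshold in ms (feedback latency).
#' @param saccade_window max ms between feedback and dwell end for a
#'   voluntary trial.
#' @param confirm_window max ms between anchor and confirmation onset.
#' @param onset_tolerance max initial fixation onset latency in ms.
#' @param confirm_anchor `"dwell_end"` or `"feedback"`.
#' @return `data.frame` of ball dwells with added columns `label`, `reason`
#'   and `feedback_time_ms` (NA when no feedback was issued).
#' @export
label_fixations <- function(events, dwell_threshold = 500,
                            saccade_window = 500, confirm_window = 200,
                            onset_tolerance = 50,
                            confirm_anchor = c("dwell_end", "feedback")) {
  confirm_anchor <- match.arg(confirm_anchor)
  need <- c("kind", "onset_ms", "offset_ms", "initial_onset_latency_ms")
  if (!all(need %in% names(events)))
    stop("malformed-log: missing columns ",
         paste(setdiff(need, names(events)), collapse = ", "))
  if (any(events$offset_ms <= events$onset_ms))
    stop("malformed-log: events must have offset > onset")
  n <- nrow(events)
  if (n > 1) {
    if (is.unsorted(events$onset_ms))
      stop("malformed-log: events must be time-ordered")
    if (any(events$onset_ms[-1] < events$offset_ms[-n]))
      stop("malformed-log: overlapping events")
  }
  dwell_rows <- which(events$kind == "ball_dwell")
  out <- events[dwell_rows, , drop = FALSE]
  out$label <- NA_character_
  out$reason <- ""
  out$feedback_time_ms <- NA_real_
  for (j in seq_along(dwell_rows)) {
    i <- dwell_rows[j]
    onset <- events$onset_ms[i]
    offset <- events$offset_ms[i]
    dur <- offset - onset
    if (dur < dwell_threshold) {
      out$label[j] <- "excluded"; out$reason[j] <- "below-threshold"
      next
    }
    feedback <- onset + dwell_threshold
    out$feedback_time_ms[j] <- feedback
    if (events$initial_onset_latency_ms[i] > onset_tolerance) {
      out$label[j] <- "excluded"; out$reason[j] <- "late-onset"
      next
    }
    nxt <- if (i < n) i + 1L else NA_integer_
    if (!is.na(nxt) && events$kind[nxt] == "confirm_fix") {
      anchor <- if (confirm_anchor == "dwell_end") offset else feedback
      timely <- (offset - feedback) <= saccade_window &&
        (events$onset_ms[nxt] - anchor) <= confirm_window
      if (timely) {
        out$label[j] <- "voluntary"
      } else {
        out$label[j] <- "excluded"; out$reason[j] <- "delayed-confirmation"
      }
    } else {
      out$label[j] <- "spontaneous"
    }
  }
  out
}

#' Balance the two trial classes by random subsampling
#'
#' Removes uniformly random trials from the larger class until both classes
#' have the size of the smaller one; the smaller class is left untouched.
#' Reproducible under `seed`.
#'
#' @param labels vector of per-trial labels (0/1 or
#'   "spontaneous"/"voluntary"); excluded trials must already be dropped.
#' @param seed integer seed.
#' @return list with sorted integer index vectors `voluntary` and
#'   `spontaneous`, both of length `min(class sizes)`.
#' @export
balance_classes <- function(labels, seed = 1) {
  lab <- labels
  if (is.character(lab) || is.factor(lab))
    lab <- as.integer(as.character(lab) == "voluntary")
  idx_v <- which(lab == 1)
  idx_s <- which(lab == 0)
  if (length(idx_v) == 0 || length(idx_s) == 0)
    stop("insufficient-data: both classes must be non-empty")
  m <- min(length(idx_v), length(idx_s))
  set.seed(as.integer(seed))
  if (length(idx_v) > m) idx_v <- sort(sample(idx_v, m))
  if (length(idx_s) > m) idx_s <- sort(sample(idx_s, m))
  list(voluntary = idx_v, spontaneous = idx_s)
}

#' Filter participants by voluntary trial count
#'
#' Participants with strictly fewer voluntary trials than `min_trials` are
#' dropped from the analysis.
#'
#' @param trial_counts named numeric vector of voluntary trial counts.
#' @param min_trials inclusion threshold (a count equal to the threshold is
#'   kept).
#' @return character vector of included participant names (or indices when
#'   unnamed).
#' @export
participant_filter <- function(trial_counts, min_trials = 70) {
  if (any(trial_counts < 0)) stop("trial counts must be >= 0")
  keep <- trial_counts >= min_trials
  if (is.null(names(trial_counts))) which(keep) else names(trial_counts)[keep]
}
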