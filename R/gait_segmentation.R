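#' Detector configuration
#'
#' Thresholds of the rule-based gait-event detector. The swing phase is
#' accepted when the positive peak of the sagittal angular velocity exceeds
#' `swing_peak_threshold`; a foot-off is emitted at a confirmed local
#' minimum `t_min` when the conjunction
#' `t_min - t_max >= min_tmin_tmax_gap  &&  gz(t_min) <= footoff_value_threshold
#' && t_max - t_fs >= min_tmax_tfs_gap` holds, where `t_max` is the last
#' confirmed local maximum after the foot strike `t_fs`. If no foot-off is
#' confirmed within `timeout` seconds of the swing confirmation, the pending
#' swing is discarded.
#'
#' @param swing_peak_threshold rad/s, default 1.8.
#' @param footoff_value_threshold rad/s, default 1.4.
#' @param min_tmin_tmax_gap seconds, default 0.060.
#' @param min_tmax_tfs_gap seconds, default 0.070.
#' @param timeout seconds, default 1.3.
#' @param fs sampling rate in Hz, default 100.
#' @return a `detector_config` object.
#' @export
detector_config <- function(swing_peak_threshold = 1.8,
                            footoff_value_threshold = 1.4,
                            min_tmin_tmax_gap = 0.060,
                            min_tmax_tfs_gap = 0.070,
                            timeout = 1.3,
                            fs = 100) {
  stopifnot(swing_peak_threshold > 0, footoff_value_threshold > 0,
            min_tmin_tmax_gap > 0, min_tmax_tfs_gap > 0, fs > 0,
            timeout > max(min_tmin_tmax_gap, min_tmax_tfs_gap))
  structure(list(swing_peak_threshold = swing_peak_threshold,
                 footoff_value_threshold = footoff_value_threshold,
                 min_tmin_tmax_gap = min_tmin_tmax_gap,
                 min_tmax_tfs_gap = min_tmax_tfs_gap,
                 timeout = timeout, fs = fs),
            class = "detector_config")
}

#' Fresh detector state
#'
#' The automaton's memory is a fixed set of scalars (no windows, no lookback
#' buffers): the phase, the previous sample, the pending swing maximum, the
#' last foot strike, and the current local-extremum candidates. Phases cycle
#' `SEEKING_SWING -> SEEKING_FOOT_STRIKE -> SEEKING_FOOT_OFF -> SEEKING_SWING`
#' (the last transition also via timeout).
#'
#' @return an environment of class `detector_state`.
#' @export
detector_state <- function() {
  st <- new.env(parent = emptyenv())
  st$phase <- "SEEKING_SWING"
  st$prev_val <- NA_real_     # previous sample value
  st$prev_idx <- -1L          # previous sample index (order check)
  st$have_rising <- FALSE     # inside a positive lobe (after rising crossing)
  st$run_max <- -Inf          # running max since the rising crossing
  st$run_max_idx <- NA_integer_
  st$ms_idx <- NA_integer_    # confirmation index of the accepted swing
  st$fs_idx <- NA_integer_    # foot-strike index
  st$tmax_idx <- NA_integer_  # last confirmed local max after foot strike
  st$tmax_val <- NA_real_
  st$sub <- ""                # extremum being tracked: "max" or "min"
  st$cand_idx <- NA_integer_  # current extremum candidate
  st$cand_val <- NA_real_
  class(st) <- c("detector_state", "environment")
  st
}

reset_to_swing_seek <- function(st) {
  st$phase <- "SEEKING_SWING"
  st$have_rising <- FALSE
  st$run_max <- -Inf
  st$run_max_idx <- NA_integer_
  st$ms_idx <- NA_integer_
  st$fs_idx <- NA_integer_
  st$tmax_idx <- NA_integer_
  st$tmax_val <- NA_real_
  st$sub <- ""
  st$cand_idx <- NA_integer_
  st$cand_val <- NA_real_
  invisible(st)
}

mk_event <- function(type, idx, val, fs) {
  list(event_type = type, sample_index = idx, time_s = idx / fs, value = val)
}

#' Advance the streaming detector by one sample
#'
#' Feeds one `(index, value)` pair of the sagittal angular velocity into the
#' automaton. The state environment is updated in place and the (possibly
#' empty) list of events emitted at this sample is returned. Local extrema
#' are confirmed one sample after their trend reversal; plateaus take the
#' first plateau sample and ties the earliest index, so the detector is
#' deterministic and its latency is bounded by one sample plus the foot-off
#' condition checks.
#'
#' @param state a [detector_state] (mutated in place).
#' @param index 0-based sample index; must arrive in order with no gaps.
#' @param value sagittal angular velocity `g_z` in rad/s.
#' @param config a [detector_config].
#' @return list of zero or more emitted events, each a list with
#'   `event_type`, `sample_index`, `time_s`, `value`.
#' @export
step_detector <- function(state, index, value, config) {
  if (!is.finite(value))
    stop("non-finite g_z sample at index ", index)
  if (index != state$prev_idx + 1L)
    stop("out-of-order sample index ", index, " (expected ",
         state$prev_idx + 1L, ")")
  fs <- config$fs
  emitted <- list()

  # timeout since swing confirmation
  if (state$phase != "SEEKING_SWING" &&
      (index - state$ms_idx) / fs > config$timeout) {
    reset_to_swing_seek(state)
  }

  prev <- state$prev_val
  if (state$phase == "SEEKING_SWING") {
    if (!state$have_rising) {
      if (!is.na(prev) && prev < 0 && value >= 0) {
        state$have_rising <- TRUE
        state$run_max <- value
        state$run_max_idx <- index
      }
    } else {
      if (value > state$run_max) {       # strict: earliest argmax on ties
        state$run_max <- value
        state$run_max_idx <- index
      }
      if (prev >= 0 && value < 0) {      # falling crossing closes the lobe
        if (state$run_max > config$swing_peak_threshold) {
          emitted <- c(emitted, list(mk_event("MID_SWING", state$run_max_idx,
                                              state$run_max, fs)))
          state$phase <- "SEEKING_FOOT_STRIKE"
          state$ms_idx <- index          # timeout anchored at confirmation
          state$cand_idx <- index
          state$cand_val <- value
        }
        state$have_rising <- FALSE
        state$run_max <- -Inf
        state$run_max_idx <- NA_integer_
      }
    }
  } else if (state$phase == "SEEKING_FOOT_STRIKE") {
    if (value < state$cand_val) {
      state$cand_idx <- index
      state$cand_val <- value
    }
    if (value > prev) {                  # reversal confirms the minimum
      emitted <- c(emitted, list(mk_event("FOOT_STRIKE", state$cand_idx,
                                          state$cand_val, fs)))
      state$fs_idx <- state$cand_idx
      state$phase <- "SEEKING_FOOT_OFF"
      state$sub <- "max"
      state$cand_idx <- index
      state$cand_val <- value
    }
  } else {                               # SEEKING_FOOT_OFF
    if (state$sub == "max") {
      if (value > state$cand_val) {
        state$cand_idx <- index
        state$cand_val <- value
      }
      if (value < prev) {                # confirmed local max -> t_max
        state$tmax_idx <- state$cand_idx
        state$tmax_val <- state$cand_val
        state$sub <- "min"
        state$cand_idx <- index
        state$cand_val <- value
      }
    } else {
      if (value < state$cand_val) {
        state$cand_idx <- index
        state$cand_val <- value
      }
      if (value > prev) {                # confirmed local min -> t_min
        tmin_idx <- state$cand_idx
        tmin_val <- state$cand_val
        ok <- !is.na(state$tmax_idx) &&
          (tmin_idx - state$tmax_idx) / fs >= config$min_tmin_tmax_gap - 1e-12 &&
          tmin_val <= config$footoff_value_threshold &&
          (state$tmax_idx - state$fs_idx) / fs >= config$min_tmax_tfs_gap - 1e-12
        if (ok) {
          emitted <- c(emitted, list(mk_event("FOOT_OFF", tmin_idx,
                                              tmin_val, fs)))
          reset_to_swing_seek(state)
        } else {
          state$sub <- "max"
          state$cand_idx <- index
          state$cand_val <- value
        }
      }
    }
  }
  state$prev_val <- value
  state$prev_idx <- index
  emitted
}

#' Detect gait events over a whole signal
#'
#' Batch convenience: folds [step_detector] over the samples with a fresh
#' state, so chunked streaming and whole-signal runs give identical events.
#'
#' @param gz numeric vector, sagittal angular velocity in rad/s.
#' @param config a [detector_config] (default thresholds).
#' @param state optional [detector_state] to resume from (mutated).
#' @return a data.frame with columns
#'   `event_type` (`MID_SWING`/`FOOT_STRIKE`/`FOOT_OFF`), `sample_index`
#'   (0-based), `time_s`, `value` (rad/s), ordered by time.
#' @export
detect_events <- function(gz, config = detector_config(), state = NULL) {
  if (is.null(state)) state <- detector_state()
  start <- state$prev_idx + 1L
  acc <- vector("list", 64L)
  nev <- 0L
  for (k in seq_along(gz)) {
    ev <- step_detector(state, start + k - 1L, gz[[k]], config)
    for (e in ev) {
      nev <- nev + 1L
      if (nev > length(acc)) acc <- c(acc, vector("list", length(acc)))
      acc[[nev]] <- e
    }
  }
  events_df(acc[seq_len(nev)])
}

events_df <- function(evlist) {
  if (length(evlist) == 0L)
    return(data.frame(event_type = character(0), sample_index = integer(0),
                      time_s = numeric(0), value = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(
    event_type = vapply(evlist, `[[`, character(1L), "event_type"),
    sample_index = vapply(evlist, `[[`, integer(1L), "sample_index"),
    time_s = vapply(evlist, `[[`, numeric(1L), "time_s"),
    value = vapply(evlist, `[[`, numeric(1L), "value"),
    stringsAsFactors = FALSE)
}

#' Assemble gait cycles from detected events
#'
#' One cycle per adjacent pair of FOOT_OFF events (other event types are
#' ignored for boundaries); the segment covers `[start, end)` in 0-based
#' sample indices. When the recording carries per-sample labels, each cycle
#' receives the majority label, ties broken toward the label whose run
#' starts earliest within the cycle.
#'
#' @param events data.frame from [detect_events].
#' @param recording the [imu_recording] the events were detected on.
#' @return a data.frame with columns `cycle_id, start_index, end_index,
#'   start_time_s, end_time_s, activity_label`.
#' @export
cycles_from_events <- function(events, recording) {
  stopifnot(inherits(recording, "imu_recording"))
  fo <- events[events$event_type == "FOOT_OFF", , drop = FALSE]
  if (nrow(fo) < 2L)
    return(data.frame(cycle_id = integer(0), start_index = integer(0),
                      end_index = integer(0), start_time_s = numeric(0),
                      end_time_s = numeric(0),
                      activity_label = character(0),
                      stringsAsFactors = FALSE))
  n <- nrow(fo) - 1L
  start <- fo$sample_index[seq_len(n)]
  end <- fo$sample_index[seq_len(n) + 1L]
  lab <- rep(NA_character_, n)
  if (!is.null(recording$labels)) {
    for (i in seq_len(n))
      lab[i] <- majority_label(recording$labels[(start[i] + 1L):end[i]])
  }
  data.frame(cycle_id = seq_len(n), start_index = start, end_index = end,
             start_time_s = start / recording$fs,
             end_time_s = end / recording$fs,
             activity_label = lab, stringsAsFactors = FALSE)
}

# majority vote; ties broken toward the label whose first run starts earliest
majority_label <- function(labels) {
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  top[which.min(vapply(top, function(l) match(l, labels), integer(1L)))]
}
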