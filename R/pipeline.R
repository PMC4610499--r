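#' The six pre-processing configurations
#'
#' Enumeration of the compared pre-processing settings:
#' 1. raw signal;
#' 2. inclination correction only;
#' 3. raw segmentation, then filtering applied to the segmented windows;
#' 4. inclination correction, then filtering of the segmented windows;
#' 5. whole-signal filtering (no inclination correction);
#' 6. inclination correction followed by whole-signal filtering.
#' Configurations 1 and 3 share event lists by construction (filtering in 3
#' happens after segmentation), as do 2 and 4.
#'
#' @return data.frame with columns `id, inclination, filtering, name`.
#' @export
pipeline_configurations <- function() {
  data.frame(
    id = 1:6,
    inclination = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    filtering = c("none", "none", "segments", "segments", "signal",
                  "signal"),
    name = c("raw", "inclination", "raw+segment-filter",
             "inclination+segment-filter", "filtered",
             "inclination+filtered"),
    stringsAsFactors = FALSE)
}

# pre-processing of one recording up to the segmentation input;
# segment-level filtering (configs 3-4) happens later, per cycle window
prepare_recording <- function(recording, config_row, filter_spec,
                              standing_window_s = 5) {
  rec <- recording
  if (config_row$inclination)
    rec <- correct_inclination(rec, estimate_standing_offset(
      rec, window_s = standing_window_s))
  if (config_row$filtering == "signal")
    rec <- filter_recording(rec, filter_spec)
  rec
}

# filters each cycle window of all 6 channels with zero filter history
# (windows are processed independently post hoc)
filter_cycle_windows <- function(recording, cycles, spec) {
  out <- recording
  for (i in seq_len(nrow(cycles))) {
    idx <- (cycles$start_index[i] + 1L):cycles$end_index[i]
    for (ch in imu_channels())
      out[[ch]][idx] <- apply_filter_streaming(spec, recording[[ch]][idx])
  }
  out
}

#' Cycle-detection rate against ground-truth annotations
#'
#' An annotated cycle counts as detected when both of its boundary foot-off
#' events have a detected foot-off within the matching tolerance
#' (default ±40 ms).
#'
#' @param events detected events (data.frame from [detect_events]).
#' @param annotation a `synthetic_annotation` (or its `$cycles` data.frame).
#' @param fs sampling rate, Hz.
#' @param tol_s matching tolerance in seconds (default 0.040).
#' @return list with `rate` (%), `detected`, `annotated`, and `per_activity`
#'   (data.frame of per-class detected/annotated counts and ratio %).
#' @export
detection_rate <- function(events, annotation, fs = 100, tol_s = 0.040) {
  cycles <- if (inherits(annotation, "synthetic_annotation"))
    annotation$cycles else annotation
  fo <- events$sample_index[events$event_type == "FOOT_OFF"]
  tol <- tol_s * fs + 1e-9
  matched <- function(idx)
    length(fo) > 0L && min(abs(fo - idx)) <= tol
  hit <- vapply(seq_len(nrow(cycles)), function(i)
    matched(cycles$start_index[i]) && matched(cycles$end_index[i]),
    logical(1L))
  per <- do.call(rbind, lapply(split(hit, cycles$activity), function(h)
    data.frame(detected = sum(h), annotated = length(h),
               ratio = 100 * mean(h))))
  per$activity <- rownames(per)
  list(rate = 100 * mean(hit), detected = sum(hit),
       annotated = length(hit), per_activity = per)
}

#' Run one pre-processing configuration end to end
#'
#' Applies the configuration's pre-processing, segments on the resulting
#' sagittal angular velocity, optionally filters the segmented windows
#' (configurations 3-4, all six channels, zero filter history per window),
#' extracts per-cycle features, and evaluates the classifier with
#' leave-one-subject-out. Cycles whose majority label is not a locomotion
#' activity (e.g. spanning a standing rest) are excluded from
#' classification, mirroring a labeling protocol restricted to the target
#' activities.
#'
#' @param config_id configuration id 1..6 (see [pipeline_configurations]).
#' @param sessions list of per-subject lists with `recording` and
#'   optionally `annotation` (as from [generate_cohort]).
#' @param detector a [detector_config].
#' @param svm_spec a [classifier_spec].
#' @param filter_spec a `filter_spec` (default: order-2, 10 Hz at the
#'   detector's sampling rate).
#' @param select_top_k features kept per training fold (default 20).
#' @param paper_mode single global feature selection (see [loso_evaluate]).
#' @return list with `report` (`evaluation_report`), `detection` (from
#'   [detection_rate], NULL without annotations), `config` (the row), and
#'   `events` (per-subject event data.frames).
#' @export
run_configuration <- function(config_id, sessions,
                              detector = detector_config(),
                              svm_spec = classifier_spec(),
                              filter_spec = NULL, select_top_k = 20L,
                              paper_mode = FALSE) {
  cfgs <- pipeline_configurations()
  if (!config_id %in% cfgs$id) stop("unknown configuration id ", config_id)
  cfg <- cfgs[cfgs$id == config_id, ]
  if (is.null(filter_spec))
    filter_spec <- design_lowpass(10, detector$fs, 2)
  feats <- list()
  metas <- list()
  events_all <- list()
  det_detected <- 0L
  det_annotated <- 0L
  per_act <- NULL
  for (s in seq_along(sessions)) {
    rec0 <- sessions[[s]]$recording
    rec <- prepare_recording(rec0, cfg, filter_spec)
    ev <- detect_events(rec$gz, detector)
    events_all[[s]] <- ev
    cycles <- cycles_from_events(ev, rec)
    if (!is.null(sessions[[s]]$annotation)) {
      d <- detection_rate(ev, sessions[[s]]$annotation, fs = rec$fs)
      det_detected <- det_detected + d$detected
      det_annotated <- det_annotated + d$annotated
      per_act <- if (is.null(per_act)) d$per_activity else {
        m <- merge(per_act, d$per_activity, by = "activity")
        data.frame(activity = m$activity,
                   detected = m$detected.x + m$detected.y,
                   annotated = m$annotated.x + m$annotated.y)
      }
    }
    cycles <- cycles[cycles$activity_label %in% LOCOMOTION_LABELS, ,
                     drop = FALSE]
    if (nrow(cycles) == 0L) next
    if (cfg$filtering == "segments")
      rec <- filter_cycle_windows(rec, cycles, filter_spec)
    cf <- extract_cycle_features(rec, cycles)
    feats[[length(feats) + 1L]] <- cf$features
    metas[[length(metas) + 1L]] <- cf$meta
  }
  features <- do.call(rbind, feats)
  meta <- do.call(rbind, metas)
  report <- loso_evaluate(features, meta$label, meta$subject_id,
                          spec = svm_spec, select_top_k = select_top_k,
                          paper_mode = paper_mode)
  detection <- NULL
  if (det_annotated > 0L) {
    if (!is.null(per_act)) {
      per_act$ratio <- 100 * per_act$detected / per_act$annotated
      report$step_detection <- setNames(per_act$ratio, per_act$activity)
    }
    detection <- list(rate = 100 * det_detected / det_annotated,
                      detected = det_detected, annotated = det_annotated,
                      per_activity = per_act)
  }
  list(report = report, detection = detection, config = cfg,
       events = events_all)
}

#' Compare all six pre-processing configurations on identical inputs
#'
#' Runs [run_configuration] for ids 1..6 on the same sessions and folds.
#' Identical seed-fixed inputs give an identical report.
#'
#' @inheritParams run_configuration
#' @param seed recorded in the metadata (the comparison itself is
#'   deterministic given the sessions).
#' @return a `comparison_report`: list with `configurations` (per-id list
#'   of `report` + `detection`), and `metadata`.
#' @export
run_comparison <- function(sessions, detector = detector_config(),
                           svm_spec = classifier_spec(),
                           filter_spec = NULL, select_top_k = 20L,
                           seed = NA_integer_) {
  runs <- lapply(1:6, function(id) {
    r <- run_configuration(id, sessions, detector, svm_spec, filter_spec,
                           select_top_k)
    list(id = id, name = r$config$name, report = r$report,
         detection = r$detection[c("rate", "detected", "annotated")])
  })
  names(runs) <- paste0("config_", 1:6)
  structure(list(
    configurations = runs,
    metadata = list(seed = seed, n_subjects = length(sessions),
                    detector = unclass(detector),
                    svm = unclass(svm_spec),
                    package_version =
                      as.character(utils::packageVersion("gaitseg")))),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  for (r in x$configurations)
    cat(sprintf("  %d %-28s accuracy %6.2f%%  detection %s\n",
                r$id, r$name, r$report$average_accuracy,
                if (is.null(r$detection$rate)) "n/a"
                else sprintf("%6.2f%%", r$detection$rate)))
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' Deterministic payload (no timestamps), so identical runs are
#' byte-identical.
#'
#' @param report a `comparison_report`.
#' @param path output path.
#' @export
write_comparison_json <- function(report, path) {
  payload <- list(
    configurations = lapply(report$configurations, function(r)
      list(id = r$id, name = r$name,
           report = report_to_list(r$report),
           detection = r$detection)),
    metadata = report$metadata)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
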