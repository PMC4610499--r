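#' Activity label vocabulary
#'
#' Per-sample activity tags: level walking, stair ascent, stair descent,
#' running, standing still, and anything else.
#' @export
ACTIVITY_LABELS <- c("WK", "SA", "SD", "RUN", "STAND", "OTHER")

#' Locomotion classes targeted by the classifier
#' @export
LOCOMOTION_LABELS <- c("WK", "SA", "SD", "RUN")

#' Construct a six-channel IMU recording
#'
#' A uniformly sampled inertial time series: three acceleration channels
#' (m/s^2) and three angular-velocity channels (rad/s). The z gyroscope axis
#' (`gz`) is the sagittal-plane angular velocity that carries the gait
#' signature. Sample indices are 0-based throughout the package, so
#' `time[i] = i / fs` for the (i+1)-th stored sample.
#'
#' @param ax,ay,az acceleration channels, m/s^2.
#' @param gx,gy,gz angular-velocity channels, rad/s.
#' @param fs sampling rate in Hz (default 100).
#' @param time optional time vector in seconds; defaults to `(0:(n-1))/fs`.
#' @param labels optional per-sample activity tags (see [ACTIVITY_LABELS]).
#' @param subject_id opaque subject identifier.
#' @return an object of class `imu_recording`.
#' @export
imu_recording <- function(ax, ay, az, gx, gy, gz, fs = 100, time = NULL,
                          labels = NULL, subject_id = "") {
  chans <- list(ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz)
  n <- length(ax)
  if (n < 1L) stop("recording must contain at least one sample")
  for (nm in names(chans)) {
    if (length(chans[[nm]]) != n)
      stop("channel '", nm, "' length differs from ax")
    chans[[nm]] <- as.numeric(chans[[nm]])
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(time)) time <- (seq_len(n) - 1) / fs
  if (length(time) != n) stop("time length differs from channels")
  step <- 1 / fs
  bad <- which(abs(diff(time) - step) > 1e-9)
  if (length(bad) > 0L)
    stop("non-uniform sampling: time step deviates from 1/fs at index ",
         bad[1L], " (0-based)")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("labels length differs from channels")
  }
  structure(
    c(chans, list(time = as.numeric(time), fs = fs, labels = labels,
                  subject_id = as.character(subject_id))),
    class = "imu_recording")
}

#' @export
length.imu_recording <- function(x) length(x$ax)

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples @ %g Hz (%.2f s), subject '%s'%s\n",
              length(x), x$fs, length(x) / x$fs, x$subject_id,
              if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}

#' Channel names of an IMU recording
#' @export
imu_channels <- function() c("ax", "ay", "az", "gx", "gy", "gz")

#' Construct a half-open segment of a recording
#'
#' Indices are 0-based and the segment covers samples
#' `start_index, ..., end_index - 1` (half-open `[start, end)`).
#'
#' @param recording an [imu_recording].
#' @param start_index,end_index 0-based sample indices, `start < end`.
#' @param activity_label optional activity tag for the segment.
#' @return a `gait_segment` object (keeps a reference to the recording).
#' @export
gait_segment <- function(recording, start_index, end_index,
                         activity_label = NA_character_) {
  stopifnot(inherits(recording, "imu_recording"))
  n <- length(recording)
  if (!(start_index >= 0 && start_index < end_index && end_index <= n))
    stop("segment indices must satisfy 0 <= start < end <= ", n)
  structure(list(recording = recording,
                 start_index = as.integer(start_index),
                 end_index = as.integer(end_index),
                 activity_label = activity_label),
            class = "gait_segment")
}

#' @export
length.gait_segment <- function(x) x$end_index - x$start_index

#' Extract one channel of a segment as a numeric vector
#'
#' @param segment a [gait_segment].
#' @param channel one of `"ax","ay","az","gx","gy","gz"`.
#' @export
segment_channel <- function(segment, channel) {
  stopifnot(inherits(segment, "gait_segment"))
  ch <- segment$recording[[match.arg(channel, imu_channels())]]
  ch[(segment$start_index + 1L):segment$end_index]
}

# ---------------------------------------------------------------------------
# CSV input / output

#' Read an IMU recording from CSV
#'
#' Expected header: `time_s,ax,ay,az,gx,gy,gz[,label]`. Lines starting with
#' `#` are comments; a comment of the form `# sampling_rate: 100` fixes the
#' sampling rate, otherwise it is inferred from the median time step (a
#' mismatch above 0.1% between the declared rate and the time column raises).
#'
#' @param path file path.
#' @param subject_id subject identifier to attach (default: file base name).
#' @return an [imu_recording].
#' @export
read_imu_csv <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  fs_declared <- NULL
  head_lines <- readLines(path, n = 20L, warn = FALSE)
  for (ln in grep("^#", head_lines, value = TRUE)) {
    m <- regmatches(ln, regexec("sampling_rate:\\s*([0-9.]+)", ln))[[1L]]
    if (length(m) == 2L) fs_declared <- as.numeric(m[2L])
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("time_s", imu_channels())
  for (col in required)
    if (!col %in% names(df)) stop("missing required column: ", col)
  time <- as.numeric(df$time_s)
  steps <- diff(time)
  if (length(steps) > 0L) {
    ref <- if (length(steps) >= 3L) median(steps) else steps[1L]
    fs_inferred <- 1 / ref
    bad <- which(abs(steps - ref) > 1e-6)
    if (length(bad) > 0L)
      stop("non-uniform timestamps: first offending sample index ",
           bad[1L], " (0-based)")
  } else {
    fs_inferred <- if (is.null(fs_declared)) 100 else fs_declared
  }
  fs <- if (!is.null(fs_declared)) {
    if (length(steps) > 0L &&
        abs(fs_declared - fs_inferred) / fs_inferred > 0.001)
      stop("declared sampling_rate ", fs_declared,
           " Hz disagrees with time column (", signif(fs_inferred, 6), " Hz)")
    fs_declared
  } else fs_inferred
  if (is.null(subject_id))
    subject_id <- sub("\\.csv$", "", basename(path))
  imu_recording(df$ax, df$ay, df$az, df$gx, df$gy, df$gz, fs = fs,
                time = time,
                labels = if ("label" %in% names(df)) df$label else NULL,
                subject_id = subject_id)
}

#' Write an IMU recording to CSV
#'
#' Numeric columns are written with 17 significant digits so that a
#' write-then-read round trip is lossless at double precision.
#'
#' @param recording an [imu_recording].
#' @param path output file path.
#' @export
write_imu_csv <- function(recording, path) {
  stopifnot(inherits(recording, "imu_recording"))
  df <- data.frame(time_s = fmt_num(recording$time))
  for (ch in imu_channels()) df[[ch]] <- fmt_num(recording[[ch]])
  if (!is.null(recording$labels)) df$label <- recording$labels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate: %s", fmt_num(recording$fs)), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write gait events to CSV
#'
#' Header `event_type,time_s,sample_index,value_rad_s`; one row per event,
#' `sample_index` 0-based. Events must be ordered in time.
#'
#' @param events a data.frame as returned by [detect_events].
#' @param path output file path.
#' @export
write_events_csv <- function(events, path) {
  events <- as.data.frame(events)
  req <- c("event_type", "time_s", "sample_index", "value")
  if (!all(req %in% names(events)))
    stop("events must have columns ", paste(req, collapse = ", "))
  if (nrow(events) > 1L && any(diff(events$sample_index) <= 0))
    stop("events must be strictly ordered by sample_index")
  out <- data.frame(event_type = events$event_type,
                    time_s = fmt_num(events$time_s),
                    sample_index = events$sample_index,
                    value_rad_s = fmt_num(events$value))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gait events from CSV written by [write_events_csv]
#' @param path file path.
#' @return a data.frame with columns `event_type,sample_index,time_s,value`.
#' @export
read_events_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(event_type = as.character(df$event_type),
             sample_index = as.integer(df$sample_index),
             time_s = as.numeric(df$time_s),
             value = as.numeric(df$value_rad_s),
             stringsAsFactors = FALSE)
}
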