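#' Estimate per-channel offsets from an initial standing-still window
#'
#' The recording protocol starts with the subject standing upright for a few
#' seconds; the per-channel arithmetic mean over that window captures both
#' the gravity projection on the accelerometer axes and any constant
#' mounting/inclination bias, and is later subtracted by
#' [correct_inclination].
#'
#' @param recording an [imu_recording].
#' @param window_s length of the standing window in seconds (default 5).
#' @return named numeric vector of six offsets (`ax..gz`), channel units.
#' @export
estimate_standing_offset <- function(recording, window_s = 5) {
  stopifnot(inherits(recording, "imu_recording"))
  nwin <- floor(window_s * recording$fs)
  if (length(recording) < nwin)
    stop("recording shorter than the ", window_s, " s standing window")
  vapply(imu_channels(),
         function(ch) mean(recording[[ch]][seq_len(nwin)]),
         numeric(1L))
}

#' Subtract per-channel offsets from a recording
#'
#' All six channels (gyroscope included) have their offset removed; length,
#' sampling rate and labels are unchanged.
#'
#' @param recording an [imu_recording].
#' @param offsets named numeric vector as from [estimate_standing_offset].
#' @return a corrected [imu_recording].
#' @export
correct_inclination <- function(recording, offsets) {
  stopifnot(inherits(recording, "imu_recording"))
  if (!all(is.finite(offsets))) stop("offsets must be finite")
  if (is.null(names(offsets))) names(offsets) <- imu_channels()
  out <- recording
  for (ch in imu_channels()) out[[ch]] <- recording[[ch]] - offsets[[ch]]
  out
}

#' Design the causal low-pass filter
#'
#' Order 1 is the bilinear transform of a single-pole RC prototype,
#' pre-warped so the analog corner maps exactly to `cutoff_hz`; order 2 is
#' the cascade of two identical first-order sections collapsed into one
#' recursion with two feed-forward and two feedback taps. DC gain is unity.
#' The default order-2 design at 10 Hz cutoff and 100 Hz sampling attenuates
#' by more than 15 dB at twice the corner frequency.
#'
#' @param cutoff_hz corner frequency in Hz, `0 < cutoff_hz < fs/2`.
#' @param fs sampling rate in Hz.
#' @param order 1 or 2 (default 2).
#' @return a `filter_spec` object with fields `b` (b0..bM), `a` (a1..aN,
#'   leading 1 implicit), `cutoff_hz`, `fs`.
#' @export
design_lowpass <- function(cutoff_hz = 10, fs = 100, order = 2) {
  if (!(cutoff_hz > 0 && cutoff_hz < fs / 2))
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  wa <- tan(pi * cutoff_hz / fs)  # pre-warped analog corner
  b1 <- c(wa, wa) / (1 + wa)
  a1 <- (wa - 1) / (1 + wa)
  if (order == 1) {
    b <- b1; a <- a1
  } else {
    b <- convolve(b1, rev(b1), type = "open")       # (b0 + b1 z^-1)^2
    a <- convolve(c(1, a1), rev(c(1, a1)), type = "open")[-1L]
  }
  spec <- structure(list(b = b, a = a, cutoff_hz = cutoff_hz, fs = fs),
                    class = "filter_spec")
  validate_filter_spec(spec)
  spec
}

validate_filter_spec <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  dc <- sum(spec$b) / (1 + sum(spec$a))
  if (abs(dc - 1) > 1e-9) stop("filter DC gain is not unity")
  poles <- polyroot(rev(c(1, spec$a)))
  if (any(Mod(poles) >= 1)) stop("filter is unstable")
  invisible(spec)
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> low-pass, cutoff %g Hz @ fs %g Hz, M=%d N=%d\n",
              x$cutoff_hz, x$fs, length(x$b) - 1L, length(x$a)))
  invisible(x)
}

#' Fresh all-zero filter state
#'
#' @param spec a `filter_spec`.
#' @return a `filter_state` carrying the past inputs and outputs.
#' @export
filter_state <- function(spec) {
  structure(list(x_hist = numeric(length(spec$b) - 1L),
                 y_hist = numeric(length(spec$a))),
            class = "filter_state")
}

#' Apply the filter causally, one output per input
#'
#' Computes `y[n] = sum b_k x[n-k] - sum a_k y[n-k]` with zero initial
#' history. Passing the state returned by a previous call continues the
#' recursion bit-exactly, so chunked and whole-signal application agree.
#'
#' @param spec a `filter_spec` from [design_lowpass].
#' @param x numeric input samples.
#' @param state optional `filter_state` to resume from (default: zeros).
#' @param return_state if TRUE, return `list(y, state)` instead of `y`.
#' @return filtered samples, or a list when `return_state = TRUE`.
#' @export
apply_filter_streaming <- function(spec, x, state = NULL,
                                   return_state = FALSE) {
  stopifnot(inherits(spec, "filter_spec"))
  if (is.null(state)) state <- filter_state(spec)
  res <- iir_filter_cpp(spec$b, spec$a, as.numeric(x),
                        state$x_hist, state$y_hist)
  if (return_state)
    list(y = res$y,
         state = structure(list(x_hist = res$x_hist, y_hist = res$y_hist),
                           class = "filter_state"))
  else res$y
}

#' Filter all six channels of a recording
#'
#' Each channel gets its own zero-history recursion.
#'
#' @param recording an [imu_recording].
#' @param spec a `filter_spec`.
#' @return the filtered [imu_recording].
#' @export
filter_recording <- function(recording, spec) {
  stopifnot(inherits(recording, "imu_recording"))
  out <- recording
  for (ch in imu_channels())
    out[[ch]] <- apply_filter_streaming(spec, recording[[ch]])
  out
}

#' Transfer-function magnitude in dB
#'
#' Evaluates `20*log10 |H(e^{j 2 pi f / fs})|` of the filter recursion.
#'
#' @param spec a `filter_spec`.
#' @param freq_hz frequency (or vector of frequencies), `0 <= f <= fs/2`.
#' @return gain in dB (can be `-Inf` at a transmission zero).
#' @export
frequency_response <- function(spec, freq_hz) {
  stopifnot(inherits(spec, "filter_spec"))
  if (any(freq_hz < 0 | freq_hz > spec$fs / 2))
    stop("frequency must lie in [0, fs/2]")
  vapply(freq_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / spec$fs)
    num <- sum(spec$b * z^(seq_along(spec$b) - 1L))
    den <- 1 + sum(spec$a * z^(seq_along(spec$a)))
    20 * log10(Mod(num / den))
  }, numeric(1L))
}

#' Serialize a filter design to JSON
#' @param spec a `filter_spec`.
#' @param path output path.
#' @export
write_filter_json <- function(spec, path) {
  jsonlite::write_json(list(b = spec$b, a = spec$a,
                            cutoff_hz = spec$cutoff_hz, fs = spec$fs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a filter design from JSON
#' @param path input path.
#' @export
read_filter_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- structure(list(b = as.numeric(j$b), a = as.numeric(j$a),
                         cutoff_hz = j$cutoff_hz, fs = j$fs),
                    class = "filter_spec")
  validate_filter_spec(spec)
  spec
}
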