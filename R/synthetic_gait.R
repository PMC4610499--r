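# Synthetic shank-IMU generator.
#
# The sagittal angular velocity g_z of one stride is rendered as half-cosine
# arcs between knot points, so every intended extremum sits exactly on a
# knot at a known sample: the foot-off negative dip at the cycle start, the
# positive swing lobe (maximum = mid-swing), the foot-strike negative dip,
# and a low-amplitude stance that rises to a small positive pre-swing hump
# before plunging into the next foot-off dip. Arc interpolation is smooth
# and monotone between knots, which keeps the morphology compatible with a
# streaming extremum-confirmation detector and makes annotations exact by
# construction.

#' Activity profile for the synthetic generator
#'
#' Distributional parameters of one locomotion activity. Defaults (see
#' [default_profiles]) satisfy the detectability guarantee: swing peaks
#' exceed the 1.8 rad/s threshold by at least 3 noise standard deviations
#' and the stance timing leaves >= 20 ms margins on the foot-off rules.
#'
#' @param activity one of `"WK","SA","SD","RUN"`.
#' @param cycle_duration_mean,cycle_duration_sd stride duration, seconds.
#' @param swing_peak_mean,swing_peak_sd positive swing peak, rad/s
#'   (mean must be >= 3.0).
#' @param foot_off_depth,foot_strike_depth depths of the negative lobes,
#'   rad/s (entered as positive numbers).
#' @param stance_hump amplitude of the pre-swing stance maximum, rad/s.
#' @param acc_amp length-3 acceleration waveform amplitudes (ax, ay, az),
#'   m/s^2.
#' @param acc_noise_sd,gyro_noise_sd white-noise standard deviations per
#'   channel family (m/s^2, rad/s).
#' @return an `activity_profile`.
#' @export
activity_profile <- function(activity, cycle_duration_mean,
                             cycle_duration_sd, swing_peak_mean,
                             swing_peak_sd, foot_off_depth,
                             foot_strike_depth, stance_hump, acc_amp,
                             acc_noise_sd = 0.4, gyro_noise_sd = 0.08) {
  stopifnot(activity %in% LOCOMOTION_LABELS,
            cycle_duration_mean > 0.4,
            swing_peak_mean >= 3.0,
            swing_peak_mean - 1.8 >= 3 * gyro_noise_sd,
            foot_off_depth > 0, foot_strike_depth > 0, stance_hump > 0,
            length(acc_amp) == 3L)
  structure(list(activity = activity,
                 cycle_duration_mean = cycle_duration_mean,
                 cycle_duration_sd = cycle_duration_sd,
                 swing_peak_mean = swing_peak_mean,
                 swing_peak_sd = swing_peak_sd,
                 foot_off_depth = foot_off_depth,
                 foot_strike_depth = foot_strike_depth,
                 stance_hump = stance_hump,
                 acc_amp = acc_amp,
                 acc_noise_sd = acc_noise_sd,
                 gyro_noise_sd = gyro_noise_sd),
            class = "activity_profile")
}

#' Default activity profiles
#'
#' Stated-world conventions, not measurements: swing-peak means (rad/s)
#' WK 4.5, SA 3.5, SD 4.0, RUN 7.0; cycle durations (s) WK 1.1, SA 1.4,
#' SD 1.2, RUN 0.75; gyroscope noise sd 0.08 rad/s.
#'
#' @param noise_scale multiplies both noise standard deviations
#'   (0 = noise-free templates).
#' @return named list of four [activity_profile]s.
#' @export
default_profiles <- function(noise_scale = 1) {
  g <- 0.08 * noise_scale
  a <- 0.4 * noise_scale
  list(
    WK = activity_profile("WK", 1.10, 0.05, 4.5, 0.30, 2.2, 2.6, 1.20,
                          c(3.0, 4.0, 1.5), a, g),
    SA = activity_profile("SA", 1.40, 0.07, 3.5, 0.25, 1.8, 2.6, 1.30,
                          c(1.5, 5.0, 1.2), a, g),
    SD = activity_profile("SD", 1.20, 0.06, 4.0, 0.30, 2.0, 3.2, 1.25,
                          c(2.5, 3.5, 2.8), a, g),
    RUN = activity_profile("RUN", 0.75, 0.04, 7.0, 0.40, 3.0, 4.5, 1.30,
                           c(6.0, 8.0, 3.0), a, g))
}

# Half-cosine interpolation through a knot sequence; knots at integer
# sample offsets, evaluated on [0, n) (half-open, so the final knot belongs
# to the following segment). Negative-lobe knots (below -0.45 rad/s)
# additionally receive a narrow triangular impact notch (width ±50 ms,
# depth 25% of the lobe), emulating the impulsive character of foot strike
# and toe-off; the notch apex coincides with the knot, so annotated event
# samples remain the exact extrema, while the sharpened dip bottoms keep
# the local slope well above the sensor noise.
eval_arcs <- function(knots_t, knots_v, n) {
  out <- numeric(n)
  for (k in seq_len(length(knots_t) - 1L)) {
    t1 <- knots_t[k]; t2 <- knots_t[k + 1L]
    if (t2 <= t1) next
    idx <- max(t1, 0L):min(t2 - 1L, n - 1L)
    idx <- idx[idx >= 0 & idx < n]
    if (length(idx) == 0L) next
    frac <- (idx - t1) / (t2 - t1)
    out[idx + 1L] <- knots_v[k] +
      (knots_v[k + 1L] - knots_v[k]) * (1 - cos(pi * frac)) / 2
  }
  w <- 5L
  for (k in seq_along(knots_t)) {
    if (knots_v[k] >= -0.45) next
    depth <- 0.25 * abs(knots_v[k])
    for (dt in (-w):w) {
      i <- knots_t[k] + dt
      if (i >= 0 && i < n)
        out[i + 1L] <- out[i + 1L] - depth * (1 - abs(dt) / w)
    }
  }
  out
}

# draws one stride's parameters from the profile (uses the current RNG)
draw_cycle_params <- function(profile) {
  T_s <- max(0.55, rnorm(1L, profile$cycle_duration_mean,
                         profile$cycle_duration_sd))
  peak <- max(2.2, rnorm(1L, profile$swing_peak_mean, profile$swing_peak_sd))
  list(T_s = T_s, peak = peak,
       d_fo = max(1.0, rnorm(1L, profile$foot_off_depth,
                             0.1 * profile$foot_off_depth)),
       d_fs = max(1.2, rnorm(1L, profile$foot_strike_depth,
                             0.1 * profile$foot_strike_depth)))
}

# g_z knots of one stride of n samples: entry dip (annotated foot-off) at
# sample 0, mid-swing at 0.25 n, a 300 ms swing descent into the foot
# strike (capped so at least 300 ms of stance remain), the stance rise to
# the pre-swing hump, and a 130 ms plunge into the exit dip at sample n.
# The fast terminal-swing reversal and the sharpened dips (see eval_arcs)
# keep every slope that the foot-off rules can act on well above the
# sensor noise.
cycle_knots <- function(n, entry_depth, peak, strike_depth, hump,
                        exit_depth, fs) {
  hump_lead <- round(0.13 * fs)
  k_ms <- round(0.25 * n)
  k_fs <- min(k_ms + round(0.30 * fs), n - round(0.30 * fs))
  list(t = c(0L, k_ms, k_fs, n - hump_lead, n),
       v = c(-entry_depth, peak, -strike_depth, hump, -exit_depth),
       ms = k_ms, fsk = k_fs)
}

# acceleration + secondary gyro waveforms over one stride (phase-locked)
cycle_accessory <- function(n, profile, peak, fs) {
  phi <- (seq_len(n) - 1L) / n
  A <- profile$acc_amp
  k_fs <- min(round(0.25 * n) + round(0.30 * fs), n - round(0.30 * fs))
  impact <- exp(-0.5 * ((seq_len(n) - 1L - k_fs) / (0.02 * fs))^2)
  list(ax = A[1L] * (sin(2 * pi * phi) + 0.35 * sin(4 * pi * phi + 0.8)),
       ay = 9.81 + A[2L] * (cos(2 * pi * phi) +
                              0.40 * sin(4 * pi * phi + 1.5)) +
         0.5 * A[2L] * impact,
       az = A[3L] * (sin(2 * pi * phi + 2.0) +
                       0.30 * sin(6 * pi * phi + 0.3)),
       gx = 0.20 * peak * sin(2 * pi * phi + 0.4),
       gy = 0.15 * peak * sin(2 * pi * phi + 2.1))
}

add_noise <- function(chans, profile) {
  n <- length(chans$ax)
  for (ch in c("ax", "ay", "az"))
    chans[[ch]] <- chans[[ch]] + rnorm(n, 0, profile$acc_noise_sd)
  for (ch in c("gx", "gy", "gz"))
    chans[[ch]] <- chans[[ch]] + rnorm(n, 0, profile$gyro_noise_sd)
  chans
}

#' Generate a single annotated gait cycle
#'
#' One stride sampled at `fs`: the annotated foot-off dip at sample 0, the
#' swing lobe (annotated mid-swing maximum), the foot-strike dip, and the
#' stance rise to the pre-swing hump, ending just before the next foot-off
#' dip (half-open). Annotated event samples are template extrema, exact by
#' construction.
#'
#' @param profile an [activity_profile].
#' @param seed integer seed; required, so no call depends on hidden global
#'   randomness.
#' @param fs sampling rate in Hz.
#' @return list with `channels` (named list of the 6 channel vectors),
#'   `events` (0-based samples `foot_off`, `mid_swing`, `foot_strike`),
#'   `n_samples`, `duration_s`.
#' @export
generate_cycle <- function(profile, seed, fs = 100) {
  if (missing(seed)) stop("generate_cycle requires an explicit seed")
  stopifnot(inherits(profile, "activity_profile"))
  set.seed(as.integer(seed))
  p <- draw_cycle_params(profile)
  n <- round(p$T_s * fs)
  kn <- cycle_knots(n, p$d_fo, p$peak, p$d_fs, profile$stance_hump,
                    p$d_fo, fs)
  chans <- cycle_accessory(n, profile, p$peak, fs)
  chans$gz <- eval_arcs(kn$t, kn$v, n)
  chans <- add_noise(chans[c("ax", "ay", "az", "gx", "gy", "gz")], profile)
  list(channels = chans,
       events = list(foot_off = 0L, mid_swing = kn$ms, foot_strike = kn$fsk),
       n_samples = n, duration_s = n / fs)
}

standing_segment <- function(n, acc_noise, gyro_noise) {
  list(ax = rnorm(n, 0, acc_noise), ay = 9.81 + rnorm(n, 0, acc_noise),
       az = rnorm(n, 0, acc_noise), gx = rnorm(n, 0, gyro_noise),
       gy = rnorm(n, 0, gyro_noise), gz = rnorm(n, 0, gyro_noise))
}

#' Default activity protocol
#'
#' Ordered activity bouts with cycle counts, emulating a route of walking,
#' stair ascent, stair descent and running separated by standing rests.
#'
#' @param n_cycles cycles per activity bout (default 50, i.e. about 200
#'   cycles per session).
#' @param activities bout order.
#' @return data.frame with columns `activity`, `n_cycles`.
#' @export
default_protocol <- function(n_cycles = 50L,
                             activities = c("WK", "SA", "SD", "RUN")) {
  data.frame(activity = activities, n_cycles = as.integer(n_cycles),
             stringsAsFactors = FALSE)
}

#' Generate a labeled session with ground-truth annotations
#'
#' Layout: 5 s of standing (for offset initialization), then one bout per
#' protocol row separated by standing rests. Each bout renders a
#' non-annotated gait-initiation stride (a first swing starting from
#' standing — no event-based method can close a cycle before the first
#' swing), the `n_cycles` annotated strides, and a terminal toe-off dip
#' followed by a sub-threshold recovery swing, so every annotated cycle has
#' both boundary foot-off events present in the signal. An optional constant
#' per-channel bias emulates sensor inclination.
#'
#' @param protocol data.frame `activity,n_cycles` (see [default_protocol]).
#' @param seed integer seed (required).
#' @param subject_id subject identifier.
#' @param profiles named list of [activity_profile]s.
#' @param bias named 6-vector added to all samples of each channel
#'   (default: all zero).
#' @param subject_scale multiplies the sd of the per-subject lognormal
#'   jitter on durations, peaks and acceleration amplitudes (default 1).
#' @param fs sampling rate, Hz.
#' @param lead_s,rest_s,tail_s standing durations: initial, between bouts,
#'   final (seconds).
#' @return list with `recording` ([imu_recording]) and `annotation`
#'   (`synthetic_annotation`: `$cycles` data.frame with 0-based event
#'   samples `start_index,mid_swing_index,foot_strike_index,end_index`,
#'   times in seconds, `activity`; plus `$bias`, `$seed`, `$subject_id`).
#' @export
generate_session <- function(protocol = default_protocol(), seed,
                             subject_id = "S1",
                             profiles = default_profiles(), bias = NULL,
                             subject_scale = 1, fs = 100,
                             lead_s = 5, rest_s = 3, tail_s = 2) {
  if (missing(seed)) stop("generate_session requires an explicit seed")
  stopifnot(nrow(protocol) >= 1L)
  set.seed(as.integer(seed))
  if (is.null(bias)) bias <- setNames(numeric(6L), imu_channels())
  stopifnot(length(bias) == 6L)
  # per-subject jitter factors
  jitter <- list(dur = exp(rnorm(1L, 0, 0.04 * subject_scale)),
                 peak = exp(rnorm(1L, 0, 0.05 * subject_scale)),
                 amp = exp(rnorm(3L, 0, 0.08 * subject_scale)))
  base_noise <- profiles[[protocol$activity[1L]]]
  chans <- lapply(imu_channels(), function(ch) numeric(0))
  names(chans) <- imu_channels()
  labels <- character(0)
  cyc <- list()
  append_seg <- function(seg, lab) {
    for (ch in imu_channels()) chans[[ch]] <<- c(chans[[ch]], seg[[ch]])
    labels <<- c(labels, rep(lab, length(seg$ax)))
  }
  append_seg(standing_segment(round(lead_s * fs), base_noise$acc_noise_sd,
                              base_noise$gyro_noise_sd), "STAND")
  for (b in seq_len(nrow(protocol))) {
    act <- protocol$activity[b]
    prof <- profiles[[act]]
    if (is.null(prof)) stop("no profile for activity ", act)
    prof_j <- prof
    prof_j$cycle_duration_mean <- prof$cycle_duration_mean * jitter$dur
    prof_j$swing_peak_mean <- prof$swing_peak_mean * jitter$peak
    prof_j$acc_amp <- prof$acc_amp * jitter$amp
    nc <- protocol$n_cycles[b]
    # draw all stride parameters of the bout (first entry depth belongs to
    # annotated cycle 1; the initiation stride enters from standing level)
    pars <- replicate(nc, draw_cycle_params(prof_j), simplify = FALSE)
    term_depth <- max(1.0, rnorm(1L, prof_j$foot_off_depth,
                                 0.1 * prof_j$foot_off_depth))
    # initiation stride: swing from standing, exits into cycle 1's dip
    pin <- draw_cycle_params(prof_j)
    n_in <- round(pin$T_s * fs)
    kin <- cycle_knots(n_in, 0, 0.9 * pin$peak, pin$d_fs,
                       prof_j$stance_hump, pars[[1L]]$d_fo, fs)
    # enter from standing level via a small counter-rotation dip, so the
    # swing is preceded by a negative-to-positive crossing even noise-free
    kin$t <- c(0L, round(0.06 * fs), kin$t[-1L])
    kin$v <- c(0, -0.3, kin$v[-1L])
    seg <- cycle_accessory(n_in, prof_j, pin$peak, fs)
    seg$gz <- eval_arcs(kin$t, kin$v, n_in)
    append_seg(add_noise(seg[c("ax", "ay", "az", "gx", "gy", "gz")],
                         prof_j), act)
    for (k in seq_len(nc)) {
      p <- pars[[k]]
      exit_depth <- if (k < nc) pars[[k + 1L]]$d_fo else term_depth
      n <- round(p$T_s * fs)
      start_idx <- length(chans$gz)     # 0-based global sample of the dip
      kn <- cycle_knots(n, p$d_fo, p$peak, p$d_fs, prof_j$stance_hump,
                        exit_depth, fs)
      seg <- cycle_accessory(n, prof_j, p$peak, fs)
      seg$gz <- eval_arcs(kn$t, kn$v, n)
      append_seg(add_noise(seg[c("ax", "ay", "az", "gx", "gy", "gz")],
                           prof_j), act)
      cyc[[length(cyc) + 1L]] <- data.frame(
        activity = act, bout = b,
        start_index = start_idx,
        mid_swing_index = start_idx + kn$ms,
        foot_strike_index = start_idx + kn$fsk,
        end_index = start_idx + n,
        stringsAsFactors = FALSE)
    }
    # terminal toe-off dip + sub-threshold recovery swing, then rest
    n_t <- round(0.40 * fs)
    kt <- list(t = c(0L, round(0.15 * fs), n_t),
               v = c(-term_depth, 0.9, 0))
    seg <- cycle_accessory(n_t, prof_j, 0.9, fs)
    seg$gz <- eval_arcs(kt$t, kt$v, n_t)
    append_seg(add_noise(seg[c("ax", "ay", "az", "gx", "gy", "gz")],
                         prof_j), act)
    rest <- if (b < nrow(protocol)) rest_s else tail_s
    append_seg(standing_segment(round(rest * fs), prof$acc_noise_sd,
                                prof$gyro_noise_sd), "STAND")
  }
  for (ch in imu_channels()) chans[[ch]] <- chans[[ch]] + bias[[ch]]
  rec <- imu_recording(chans$ax, chans$ay, chans$az, chans$gx, chans$gy,
                       chans$gz, fs = fs, labels = labels,
                       subject_id = subject_id)
  cycles <- do.call(rbind, cyc)
  cycles$cycle_id <- seq_len(nrow(cycles))
  cycles$t_foot_off <- cycles$start_index / fs
  cycles$t_mid_swing <- cycles$mid_swing_index / fs
  cycles$t_foot_strike <- cycles$foot_strike_index / fs
  cycles$t_end <- cycles$end_index / fs
  ann <- structure(list(cycles = cycles, bias = bias, seed = seed,
                        subject_id = subject_id),
                   class = "synthetic_annotation")
  list(recording = rec, annotation = ann)
}

#' Generate a multi-subject synthetic cohort
#'
#' Per-subject parameter jitter and noise realizations flow from distinct
#' sub-seeds derived deterministically from `seed`; subjects also receive a
#' small random constant mounting bias (inclination emulation).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param protocol activity protocol (see [default_protocol]).
#' @param seed integer seed (required).
#' @param profiles named list of [activity_profile]s.
#' @param subject_scale per-subject jitter scale (see [generate_session]).
#' @param bias_sd_acc,bias_sd_gyro sd of the per-subject constant bias
#'   (m/s^2, rad/s); gyro bias is clamped to ±0.04 rad/s so segmentation
#'   stays inside the constant-bias robustness envelope.
#' @param fs sampling rate, Hz.
#' @return list of per-subject lists, each with `recording`, `annotation`.
#' @export
generate_cohort <- function(n_subjects = 9L, protocol = default_protocol(),
                            seed, profiles = default_profiles(),
                            subject_scale = 1, bias_sd_acc = 0.3,
                            bias_sd_gyro = 0.02, fs = 100) {
  if (missing(seed)) stop("generate_cohort requires an explicit seed")
  stopifnot(n_subjects >= 1L)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  lapply(seq_len(n_subjects), function(s) {
    set.seed(sub_seeds[s])
    bias <- setNames(c(rnorm(3L, 0, bias_sd_acc),
                       pmin(0.04, pmax(-0.04, rnorm(3L, 0, bias_sd_gyro)))),
                     imu_channels())
    generate_session(protocol, seed = sub_seeds[s],
                     subject_id = sprintf("S%02d", s),
                     profiles = profiles, bias = bias,
                     subject_scale = subject_scale, fs = fs)
  })
}
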