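make_lobe <- function(peak, n = 40) {
  # single positive half-sine lobe entered from below zero
  c(-0.2, peak * sin(pi * seq_len(n) / (n + 1)), -0.2, -0.1)
}

test_that("detector config validates thresholds", {
  cfg <- detector_config()
  expect_equal(cfg$swing_peak_threshold, 1.8)
  expect_equal(cfg$footoff_value_threshold, 1.4)
  expect_equal(cfg$timeout, 1.3)
  expect_error(detector_config(timeout = 0.05), "timeout")
  expect_error(detector_config(swing_peak_threshold = -1))
})

test_that("no events on all-zero or empty signals; sub-threshold lobes ignored", {
  expect_identical(nrow(detect_events(numeric(0))), 0L)
  expect_identical(nrow(detect_events(rep(0, 1000))), 0L)
  ev <- detect_events(make_lobe(1.5))
  expect_false("MID_SWING" %in% ev$event_type)   # 1.5 < 1.8 rad/s
  ev2 <- detect_events(make_lobe(2.0))
  expect_true("MID_SWING" %in% ev2$event_type)
})

test_that("noise-free templates are recovered within +-2 samples", {
  s <- clean_session()
  ev <- detect_events(s$recording$gz)
  ann <- s$annotation$cycles
  fo <- ev$sample_index[ev$event_type == "FOOT_OFF"]
  ms <- ev$sample_index[ev$event_type == "MID_SWING"]
  fs <- ev$sample_index[ev$event_type == "FOOT_STRIKE"]
  for (i in seq_len(nrow(ann))) {
    expect_lte(min(abs(fo - ann$start_index[i])), 2)
    expect_lte(min(abs(fo - ann$end_index[i])), 2)
    expect_lte(min(abs(ms - ann$mid_swing_index[i])), 2)
    expect_lte(min(abs(fs - ann$foot_strike_index[i])), 2)
  }
})

test_that("foot-off rule rejects a 50 ms max-min gap and continues searching", {
  fs <- 100
  # swing lobe then strike, then a stance where the only max-min pair has a
  # 50 ms gap; afterwards a valid pair
  gz <- c(-0.5, 3 * sin(pi * (1:30) / 31),        # swing, peak > 1.8
          seq(-0.5, -2.5, length.out = 8),        # drop to strike
          seq(-2.5, 1.0, length.out = 12),        # recover to a max
          seq(1.0, -2.0, length.out = 5),         # min 50 ms after the max
          seq(-2.0, 1.2, length.out = 18),        # recover to a later max
          seq(1.2, -2.2, length.out = 14),        # valid plunge (130 ms)
          seq(-2.2, 0, length.out = 10))
  ev <- detect_events(gz, detector_config(fs = fs))
  fo <- ev[ev$event_type == "FOOT_OFF", ]
  expect_identical(nrow(fo), 1L)
  # the emitted foot-off is the second (valid) minimum, not the 50 ms one
  strike_idx <- ev$sample_index[ev$event_type == "FOOT_STRIKE"][1]
  expect_gt(fo$sample_index, strike_idx + 12 + 5 + 18)
})

test_that("timeout discards the pending swing and the automaton re-seeks", {
  st <- detector_state()
  cfg <- detector_config()
  gz <- c(-0.5, 3 * sin(pi * (1:30) / 31), -0.5, rep(0, 140))
  evs <- list()
  for (i in seq_along(gz))
    evs <- c(evs, step_detector(st, i - 1L, gz[i], cfg))
  types <- vapply(evs, `[[`, character(1), "event_type")
  expect_true("MID_SWING" %in% types)
  expect_false("FOOT_OFF" %in% types)
  expect_identical(st$phase, "SEEKING_SWING")    # reset by the 1.3 s timeout
})

test_that("streaming and batch detection are identical (chunks of 7)", {
  s <- noisy_session()
  gz <- s$recording$gz[1:5000]
  whole <- detect_events(gz)
  st <- detector_state()
  pieces <- split(gz, ceiling(seq_along(gz) / 7))
  pieces <- pieces[order(as.integer(names(pieces)))]
  parts <- lapply(pieces, function(p) detect_events(p, state = st))
  chunked <- do.call(rbind, parts)
  rownames(chunked) <- NULL
  expect_identical(chunked, whole)
})

test_that("event stream is ordered and cyclically typed", {
  ev <- detect_events(noisy_session()$recording$gz)
  expect_true(all(diff(ev$sample_index) > 0))
  expect_identical(ev$time_s, ev$sample_index / 100)
  # MID_SWING -> FOOT_STRIKE -> (FOOT_OFF | MID_SWING after timeout)
  typ <- ev$event_type
  for (i in seq_len(nrow(ev) - 1L)) {
    nxt <- switch(typ[i],
                  MID_SWING = "FOOT_STRIKE",
                  FOOT_STRIKE = c("FOOT_OFF", "MID_SWING"),
                  FOOT_OFF = "MID_SWING")
    expect_true(typ[i + 1L] %in% nxt)
  }
})

test_that("foot-off conditions are re-checkable from the raw signal", {
  s <- noisy_session()
  gz <- s$recording$gz
  ev <- detect_events(gz)
  fo <- ev[ev$event_type == "FOOT_OFF", ]
  fs <- ev[ev$event_type == "FOOT_STRIKE", ]
  expect_gt(nrow(fo), 20)
  for (i in seq_len(nrow(fo))) {
    expect_lte(fo$value[i], 1.4)
    expect_identical(fo$value[i], gz[fo$sample_index[i] + 1L])
    # t_min - t_fs >= 60 ms + 70 ms by the two gap conditions combined
    prev_fs <- max(fs$sample_index[fs$sample_index < fo$sample_index[i]])
    expect_gte(fo$sample_index[i] - prev_fs, 13L)
  }
})

test_that("a 20-cycle walking session is recovered within +-30 ms", {
  s <- generate_session(data.frame(activity = "WK", n_cycles = 20L),
                        seed = 51)
  ev <- detect_events(s$recording$gz)
  fo <- ev$sample_index[ev$event_type == "FOOT_OFF"]
  ann <- s$annotation$cycles
  expect_identical(nrow(ann), 20L)
  # one detected foot-off within +-30 ms of every annotated boundary
  bounds <- unique(c(ann$start_index, ann$end_index))
  expect_gte(length(fo), 20L)
  for (b in bounds) expect_lte(min(abs(fo - b)), 3)
})

test_that("a small constant bias does not move foot-off events", {
  s <- generate_session(default_protocol(8), seed = 21)   # zero bias
  gz <- s$recording$gz
  ev0 <- detect_events(gz)
  for (c0 in c(-0.04, 0.03)) {
    ev1 <- detect_events(gz + c0)
    fo0 <- ev0$sample_index[ev0$event_type == "FOOT_OFF"]
    fo1 <- ev1$sample_index[ev1$event_type == "FOOT_OFF"]
    expect_identical(length(fo0), length(fo1))
    expect_true(all(abs(fo0 - fo1) <= 1))
  }
})

test_that("detector state is constant-size and rejects bad streams", {
  st <- detector_state()
  fields <- sort(ls(st))
  cfg <- detector_config()
  set.seed(33)
  for (i in 0:499) step_detector(st, i, rnorm(1), cfg)
  expect_identical(sort(ls(st)), fields)        # no growing members
  expect_true(all(vapply(fields, function(f) length(st[[f]]) == 1L,
                         logical(1))))
  expect_error(step_detector(st, 700L, 0, cfg), "out-of-order")
  expect_error(step_detector(st, 500L, NaN, cfg), "non-finite")
})

test_that("determinism: identical input and config give identical events", {
  gz <- noisy_session()$recording$gz[1:3000]
  expect_identical(detect_events(gz), detect_events(gz))
})

test_that("cycles come from adjacent foot-off pairs with majority labels", {
  rec <- toy_recording(1000)
  ev0 <- detect_events(rep(0, 10))
  expect_identical(nrow(cycles_from_events(ev0, rec)), 0L)

  mk_fo <- function(idx) data.frame(event_type = "FOOT_OFF",
                                    sample_index = idx, time_s = idx / 100,
                                    value = -2, stringsAsFactors = FALSE)
  one <- mk_fo(100L)
  expect_identical(nrow(cycles_from_events(one, rec)), 0L)

  five <- mk_fo(c(100L, 200L, 320L, 450L, 600L))
  cyc <- cycles_from_events(five, rec)
  expect_identical(nrow(cyc), 4L)
  expect_identical(cyc$end_index[-4], cyc$start_index[-1])  # shared bounds

  # majority label 60/40 and earliest-run tie-break
  lab <- c(rep("WK", 60), rep("STAND", 40))
  rec2 <- imu_recording(rnorm(100), rnorm(100), rnorm(100), rnorm(100),
                        rnorm(100), rnorm(100), fs = 100, labels = lab)
  cyc2 <- cycles_from_events(mk_fo(c(0L, 100L)), rec2)
  expect_identical(cyc2$activity_label, "WK")
  lab3 <- c(rep("SD", 50), rep("WK", 50))
  rec3 <- imu_recording(rnorm(100), rnorm(100), rnorm(100), rnorm(100),
                        rnorm(100), rnorm(100), fs = 100, labels = lab3)
  expect_identical(cycles_from_events(mk_fo(c(0L, 100L)),
                                      rec3)$activity_label, "SD")
})
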