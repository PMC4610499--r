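test_that("profiles validate the detectability-oriented invariants", {
  expect_error(activity_profile("WK", 0.3, 0.05, 4.5, 0.3, 2, 2, 1,
                                c(1, 1, 1)))           # duration too short
  expect_error(activity_profile("WK", 1.1, 0.05, 2.0, 0.3, 2, 2, 1,
                                c(1, 1, 1)))           # peak mean < 3
  p <- default_profiles()
  for (a in names(p)) {
    expect_gte(p[[a]]$swing_peak_mean - 1.8, 3 * p[[a]]$gyro_noise_sd)
    expect_gt(p[[a]]$cycle_duration_mean, 0.4)
  }
})

test_that("generation is seed-reproducible and seed-sensitive", {
  p <- default_profiles()$WK
  c1 <- generate_cycle(p, seed = 42)
  c2 <- generate_cycle(p, seed = 42)
  expect_identical(c1, c2)
  c3 <- generate_cycle(p, seed = 43)
  expect_false(identical(c1$channels$gz, c3$channels$gz))
  expect_error(generate_cycle(p), "seed")

  s1 <- generate_session(default_protocol(3), seed = 8)
  s2 <- generate_session(default_protocol(3), seed = 8)
  expect_identical(s1$recording$gz, s2$recording$gz)
  expect_identical(s1$annotation$cycles, s2$annotation$cycles)
  expect_error(generate_session(default_protocol(3)), "seed")

  co1 <- generate_cohort(2, default_protocol(3), seed = 9)
  co2 <- generate_cohort(2, default_protocol(3), seed = 9)
  expect_identical(co1[[1]]$recording$gz, co2[[1]]$recording$gz)
  co3 <- generate_cohort(2, default_protocol(3), seed = 10)
  expect_false(identical(co1[[1]]$recording$gz, co3[[1]]$recording$gz))
  # same protocol structure regardless of seed
  expect_identical(co1[[2]]$annotation$cycles$activity,
                   co3[[2]]$annotation$cycles$activity)
})

test_that("annotations count cycles and cover the protocol exactly", {
  s <- generate_session(data.frame(activity = "WK", n_cycles = 3L),
                        seed = 12)
  expect_identical(nrow(s$annotation$cycles), 3L)
  expect_true(all(s$annotation$cycles$activity == "WK"))
  # event ordering within each cycle
  cyc <- s$annotation$cycles
  expect_true(all(cyc$start_index < cyc$mid_swing_index &
                    cyc$mid_swing_index < cyc$foot_strike_index &
                    cyc$foot_strike_index < cyc$end_index))
})

test_that("labels partition the session into contiguous blocks", {
  s <- noisy_session()
  lab <- s$recording$labels
  expect_length(lab, length(s$recording))
  expect_false(any(is.na(lab)))
  runs <- rle(lab)
  # STAND alternates with one block per protocol bout
  expect_identical(runs$values[1], "STAND")
  expect_identical(runs$values[runs$values != "STAND"],
                   default_protocol(10)$activity)
})

test_that("an injected constant bias is recovered by the standing estimate", {
  bias <- c(ax = 0.5, ay = -0.3, az = 9.6, gx = 0.01, gy = 0.02,
            gz = -0.01)
  s <- generate_session(default_protocol(3), seed = 13, bias = bias)
  off <- estimate_standing_offset(s$recording, window_s = 5)
  noise <- c(rep(0.4, 3), rep(0.08, 3))
  expected <- bias + c(0, 9.81, 0, 0, 0, 0)   # gravity rides on ay
  expect_true(all(abs(off - expected) < 4 * noise / sqrt(500)))
})

test_that("generated templates honor the detector margins", {
  s <- clean_session()
  gz <- s$recording$gz
  cyc <- s$annotation$cycles
  fs <- s$recording$fs
  for (i in seq_len(nrow(cyc))) {
    expect_gt(gz[cyc$mid_swing_index[i] + 1L], 1.8)     # swing detectable
    expect_lte(gz[cyc$start_index[i] + 1L], 1.4)        # foot-off level
    # >= 20 ms margin on both foot-off gap rules (60 ms and 70 ms)
    hump <- cyc$end_index[i] - round(0.13 * fs)
    expect_gte((cyc$end_index[i] - hump) / fs, 0.060 + 0.020)
    expect_gte((hump - cyc$foot_strike_index[i]) / fs, 0.070 + 0.020)
  }
})

test_that("sub-threshold swings are not reported", {
  # scale a clean stride so its swing peak stays below 1.8 rad/s
  cc <- clean_cycle()
  gz <- cc$channels$gz
  scaled <- gz * (1.0 / max(gz))
  ev <- detect_events(scaled)
  expect_false("MID_SWING" %in% ev$event_type)
})

test_that("noise-free strides are recovered within +-2 samples", {
  cc <- clean_cycle()
  # embed two identical strides so the closing foot-off exists
  gz <- c(rep(0, 50), cc$channels$gz, cc$channels$gz, rep(0, 50))
  ev <- detect_events(gz)
  offs <- 50 + cc$events$foot_off + c(0, cc$n_samples)
  fo <- ev$sample_index[ev$event_type == "FOOT_OFF"]
  # the first dip has no preceding swing; the second is localized exactly
  expect_lte(min(abs(fo - offs[2])), 2)
  ms <- ev$sample_index[ev$event_type == "MID_SWING"]
  expect_lte(min(abs(ms - (50 + cc$events$mid_swing))), 2)
  fstr <- ev$sample_index[ev$event_type == "FOOT_STRIKE"]
  expect_lte(min(abs(fstr - (50 + cc$events$foot_strike))), 2)
})

test_that("cohorts have the requested structure", {
  co <- generate_cohort(2, default_protocol(3), seed = 14)
  expect_length(co, 2L)
  expect_identical(co[[1]]$recording$subject_id, "S01")
  for (s in co)
    expect_setequal(unique(s$annotation$cycles$activity),
                    c("WK", "SA", "SD", "RUN"))
  norun <- generate_cohort(2, default_protocol(3, c("WK", "SA", "SD")),
                           seed = 15)
  for (s in norun) {
    expect_false("RUN" %in% s$recording$labels)
    expect_false("RUN" %in% s$annotation$cycles$activity)
  }
})

test_that("default profiles separate the activity classes in feature space", {
  co <- small_cohort()
  feats <- list(); labs <- character(0)
  for (s in co) {
    ev <- detect_events(s$recording$gz)
    cyc <- cycles_from_events(ev, s$recording)
    cyc <- cyc[cyc$activity_label %in% LOCOMOTION_LABELS, ]
    cf <- extract_cycle_features(s$recording, cyc)
    feats[[length(feats) + 1]] <- cf$features
    labs <- c(labs, cf$meta$label)
  }
  X <- do.call(rbind, feats)
  top <- select_top(rank_features_svm(X, labs), 20)
  n_sep <- 0L
  for (f in top) {
    mu <- tapply(X[, f], labs, mean)
    pooled <- sqrt(mean(tapply(X[, f], labs, var)))
    gap <- max(dist(mu)) / pooled
    if (gap >= 2) n_sep <- n_sep + 1L
  }
  expect_gte(n_sep, 5L)
})
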