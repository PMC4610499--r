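# Shared fixtures, generated in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small 3-subject cohort for pipeline-level tests
small_cohort <- function() {
  memo("small_cohort", generate_cohort(3, default_protocol(12), seed = 5))
}

# one labeled session with default noise
noisy_session <- function() {
  memo("noisy_session",
       generate_session(default_protocol(10), seed = 11))
}

# noise-free session: template-exact events
clean_session <- function() {
  memo("clean_session",
       generate_session(default_protocol(5), seed = 1,
                        profiles = default_profiles(noise_scale = 0)))
}

# single noise-free walking stride (channels + exact event samples)
clean_cycle <- function() {
  memo("clean_cycle",
       generate_cycle(default_profiles(noise_scale = 0)$WK, seed = 3))
}

# a recording wrapper for raw channel matrices used in feature tests
toy_recording <- function(n = 64, seed = 7) {
  set.seed(seed)
  imu_recording(ax = rnorm(n), ay = rnorm(n), az = rnorm(n),
                gx = rnorm(n), gy = rnorm(n), gz = rnorm(n), fs = 100)
}

expect_samefo <- function(ev1, ev2) {
  expect_identical(ev1$sample_index[ev1$event_type == "FOOT_OFF"],
                   ev2$sample_index[ev2$event_type == "FOOT_OFF"])
}
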