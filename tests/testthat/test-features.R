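# brute-force definitional oracles, independent of the implementation
oracle_stats <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  sk <- if (m2 > 0) (sum((x - m)^3) / n) / m2^(3 / 2) else 0
  ku <- if (m2 > 0) (sum((x - m)^4) / n) / m2^2 else 0
  q <- unname(quantile(x, c(0.25, 0.75), type = 7))
  c(mean = m, median = median(x), skewness = sk, kurtosis = ku,
    sd = sqrt(sum((x - m)^2) / (n - 1)), iqr = q[2] - q[1])
}
oracle_dft_mag <- function(x, k) {
  n <- length(x)
  j <- seq_len(n) - 1
  Mod(sum(x * exp(-2i * pi * k * j / n))) / n
}

test_that("magnitude is the Euclidean norm and rotation invariant", {
  expect_equal(magnitude(3, 4, 0), 5)
  expect_equal(magnitude(0, 0, 0), 0)
  expect_error(magnitude(1:3, 1:2, 1:3), "length")
  set.seed(15)
  v <- matrix(rnorm(300), ncol = 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  w <- v %*% t(R)
  expect_equal(magnitude(v[, 1], v[, 2], v[, 3]),
               magnitude(w[, 1], w[, 2], w[, 3]), tolerance = 1e-9)
})

test_that("the feature registry has exactly 152 unique names", {
  nm <- feature_names()
  expect_length(nm, 152L)
  expect_identical(anyDuplicated(nm), 0L)
  expect_length(grep("^corr_", nm), 56L)
  expect_length(grep("^(energy|fft[1-5])_", nm), 48L)
})

test_that("extract_features returns 152 finite named values on any segment", {
  rec <- toy_recording(73)
  f <- extract_features(rec, start_index = 0, end_index = 73)
  expect_length(f, 152L)
  expect_identical(names(f), feature_names())
  expect_true(all(is.finite(f)))
  expect_error(extract_features(rec, start_index = 0, end_index = 5),
               "minimum 8")
})

test_that("degenerate and analytic cases behave as defined", {
  n <- 40
  rec <- imu_recording(ax = rep(2.5, n), ay = 2 * rep(2.5, n) + 1,
                       az = rnorm(n), gx = rep(0, n), gy = rnorm(n),
                       gz = rnorm(n), fs = 100)
  f <- extract_features(rec, start_index = 0, end_index = n)
  # constant channel: mean = median = c, sd = iqr = 0, DFT bins 1..5 zero
  expect_equal(unname(f["mean_ax"]), 2.5)
  expect_equal(unname(f["median_ax"]), 2.5)
  expect_equal(unname(f["sd_ax"]), 0)
  expect_equal(unname(f["iqr_ax"]), 0)
  expect_equal(unname(f["skewness_ax"]), 0)
  expect_equal(unname(f["kurtosis_ax"]), 0)
  expect_equal(unname(f[paste0("fft", 1:5, "_ax")]),
               rep(0, 5), tolerance = 1e-12)
  # constant-vs-constant correlation is defined as 0
  expect_equal(unname(f["corr_ax_ay"]), 0)
  expect_equal(unname(f["corr_ax_gx"]), 0)

  # perfect linear dependence on non-constant channels
  set.seed(16)
  x <- rnorm(n)
  rec2 <- imu_recording(ax = x, ay = 2 * x + 1, az = rnorm(n),
                        gx = rnorm(n), gy = rnorm(n), gz = rnorm(n),
                        fs = 100)
  f2 <- extract_features(rec2, start_index = 0, end_index = n)
  expect_equal(unname(f2["corr_ax_ay"]), 1, tolerance = 1e-9)

  # Parseval: spectral energy equals the time-domain mean square
  t2 <- seq_len(n) - 1
  s <- 1.3 * sin(2 * pi * 2 * t2 / n)
  rec3 <- imu_recording(ax = s, ay = rnorm(n), az = rnorm(n), gx = rnorm(n),
                        gy = rnorm(n), gz = rnorm(n), fs = 100)
  f3 <- extract_features(rec3, start_index = 0, end_index = n)
  expect_equal(unname(f3["energy_ax"]), mean(s^2), tolerance = 1e-6)
})

test_that("every statistic matches its brute-force oracle within 1e-9", {
  set.seed(17)
  for (n in c(21, 64, 103)) {
    rec <- toy_recording(n, seed = n)
    f <- extract_features(rec, start_index = 0, end_index = n)
    chans <- lapply(imu_channels(), function(ch) rec[[ch]])
    names(chans) <- imu_channels()
    chans$amag <- sqrt(chans$ax^2 + chans$ay^2 + chans$az^2)
    chans$gmag <- sqrt(chans$gx^2 + chans$gy^2 + chans$gz^2)
    for (cn in names(chans)) {
      o <- oracle_stats(chans[[cn]])
      for (s in names(o))
        expect_equal(unname(f[paste0(s, "_", cn)]), unname(o[s]),
                     tolerance = 1e-9, label = paste(s, cn))
      for (k in 1:5)
        expect_equal(unname(f[paste0("fft", k, "_", cn)]),
                     oracle_dft_mag(chans[[cn]], k), tolerance = 1e-9)
      expect_equal(unname(f[paste0("energy_", cn)]),
                   mean(chans[[cn]]^2), tolerance = 1e-9)
    }
    # pairwise correlations, both orders
    f_ab <- f[paste0("corr_ax_", c("ay", "gz", "gmag"))]
    f_ba <- f[paste0("corr_", c("ay", "gz", "gmag"), "_ax")]
    expect_equal(unname(f_ab), unname(f_ba), tolerance = 1e-12)
    expect_equal(unname(f["corr_ax_ay"]), cor(chans$ax, chans$ay),
                 tolerance = 1e-9)
  }
})

test_that("SVM-weight ranking finds the informative feature", {
  set.seed(18)
  n <- 60
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", sprintf("%02d", 1:10))))
  y <- rep(c("A", "B"), each = n / 2)
  X[, 4] <- ifelse(y == "A", 3, -3) + rnorm(n, 0, 0.2)
  rk <- rank_features_svm(X, y)
  expect_identical(rk$name[1], "f04")
  expect_true(all(diff(rk$score) <= 1e-12))

  # duplicated feature columns get equal importance and adjacent ranks
  X2 <- cbind(X, f11 = X[, 4])
  rk2 <- rank_features_svm(X2, y)
  i4 <- which(rk2$name == "f04"); i11 <- which(rk2$name == "f11")
  expect_equal(rk2$score[i4], rk2$score[i11], tolerance = 1e-6)
  expect_equal(abs(i4 - i11), 1L)

  # constant column carries no weight
  X3 <- cbind(X, fconst = rep(1, n))
  rk3 <- rank_features_svm(X3, y)
  expect_equal(rk3$score[rk3$name == "fconst"], 0)

  expect_error(rank_features_svm(X, rep("A", n)), "two classes")
})

test_that("select_top returns the first k ranked names", {
  set.seed(19)
  X <- matrix(rnorm(40 * 152), 40, 152,
              dimnames = list(NULL, feature_names()))
  y <- rep(c("A", "B"), each = 20)
  rk <- rank_features_svm(X, y)
  expect_identical(select_top(rk, 152), rk$name)
  expect_length(select_top(rk, 20), 20L)
  expect_identical(select_top(rk, 20), rk$name[1:20])
  expect_error(select_top(rk, 0), "between")
  expect_error(select_top(rk, 153), "between")
})
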