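#' Euclidean magnitude of a tri-axial channel
#'
#' Element-wise `sqrt(x^2 + y^2 + z^2)`; orientation independent, so a fixed
#' rotation of the sensor frame leaves it unchanged.
#'
#' @param x,y,z equal-length numeric vectors.
#' @return numeric vector of magnitudes.
#' @export
magnitude <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z))
    stop("magnitude channels must have equal length")
  sqrt(x^2 + y^2 + z^2)
}

FEATURE_CHANNELS <- c("ax", "ay", "az", "amag", "gx", "gy", "gz", "gmag")
TIME_STATS <- c("mean", "median", "skewness", "kurtosis", "sd", "iqr")

#' Registry of the 152 feature names
#'
#' Fixed order: 48 time statistics (`<stat>_<channel>`: mean, median,
#' skewness, kurtosis, sd, iqr over the 8 channels ax, ay, az, amag, gx, gy,
#' gz, gmag), 56 ordered-pair Pearson correlations (`corr_<A>_<B>`, all 8x7
#' ordered pairs; the symmetric duplicates are retained so the layout stays
#' rectangular in the channels), and 48 spectral features (`energy_<ch>`
#' plus `fft1_<ch>..fft5_<ch>`).
#'
#' @return character vector of length 152.
#' @export
feature_names <- function() {
  tstats <- as.vector(outer(TIME_STATS, FEATURE_CHANNELS,
                            function(s, c) paste(s, c, sep = "_")))
  pairs <- character(0)
  for (a in FEATURE_CHANNELS)
    for (b in FEATURE_CHANNELS)
      if (a != b) pairs <- c(pairs, paste("corr", a, b, sep = "_"))
  spec <- as.vector(vapply(FEATURE_CHANNELS, function(c)
    c(paste0("energy_", c), paste0("fft", 1:5, "_", c)), character(6L)))
  c(tstats, pairs, spec)
}

# third / fourth standardized sample moments (population denominators),
# defined as 0 for constant input so the feature space stays finite
sample_skewness <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}
sample_kurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^4) / s2^2
}

# Pearson correlation with zero-variance guard
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

# spectral features of one channel: Parseval-normalized energy (equals the
# time-domain mean square) and the magnitudes of DFT bins 1..5 (DC excluded,
# scaled by 1/n so they are amplitude-like and comparable across
# variable-length cycles)
spectral_features <- function(x) {
  n <- length(x)
  X <- fft(x)
  energy <- mean(Mod(X)^2) / n
  c(energy, Mod(X[2:6]) / n)
}

#' Extract the 152-dimensional feature vector of one segment
#'
#' Over the 8 channels (ax, ay, az, amag, gx, gy, gz, gmag): 6 time
#' statistics each, Pearson correlation of every ordered channel pair, and
#' per-channel spectral energy plus the magnitudes of DFT coefficients 1-5
#' of the unpadded segment. With cycles of roughly one second at 100 Hz the
#' retained bins cover about 1-5 Hz, the band holding the main frequency
#' components of locomotion. Deterministic for fixed input; degenerate cases
#' (constant channels) map to finite values.
#'
#' @param segment a [gait_segment] of at least 8 samples, or a recording
#'   with `start_index`/`end_index` given.
#' @param start_index,end_index optional 0-based half-open bounds when
#'   `segment` is an [imu_recording].
#' @return named numeric vector of length 152 (see [feature_names]).
#' @export
extract_features <- function(segment, start_index = NULL, end_index = NULL) {
  if (inherits(segment, "imu_recording")) {
    segment <- gait_segment(segment, start_index, end_index)
  }
  stopifnot(inherits(segment, "gait_segment"))
  if (length(segment) < 8L)
    stop("segment too short for feature extraction (minimum 8 samples)")
  chans <- lapply(imu_channels(), function(ch) segment_channel(segment, ch))
  names(chans) <- imu_channels()
  chans$amag <- magnitude(chans$ax, chans$ay, chans$az)
  chans$gmag <- magnitude(chans$gx, chans$gy, chans$gz)
  chans <- chans[FEATURE_CHANNELS]

  tstats <- unlist(lapply(FEATURE_CHANNELS, function(cn) {
    x <- chans[[cn]]
    c(mean(x), median(x), sample_skewness(x), sample_kurtosis(x),
      sd(x), unname(quantile(x, 0.75) - quantile(x, 0.25)))
  }))
  corrs <- numeric(0)
  for (a in FEATURE_CHANNELS)
    for (b in FEATURE_CHANNELS)
      if (a != b) corrs <- c(corrs, safe_cor(chans[[a]], chans[[b]]))
  spec <- unlist(lapply(chans, spectral_features), use.names = FALSE)
  setNames(c(tstats, corrs, spec), feature_names())
}

#' Extract features for every cycle of a recording
#'
#' @param recording an [imu_recording].
#' @param cycles data.frame from [cycles_from_events].
#' @param min_samples cycles shorter than this many samples are dropped
#'   (default 8, the feature-extraction minimum).
#' @return a list with `features` (matrix, one row per kept cycle, 152
#'   named columns) and `meta` (data.frame `cycle_id, subject_id, label,
#'   start_index, end_index`).
#' @export
extract_cycle_features <- function(recording, cycles, min_samples = 8L) {
  keep <- which(cycles$end_index - cycles$start_index >= min_samples)
  feats <- matrix(NA_real_, nrow = length(keep), ncol = 152L,
                  dimnames = list(NULL, feature_names()))
  for (r in seq_along(keep)) {
    i <- keep[r]
    feats[r, ] <- extract_features(recording,
                                   start_index = cycles$start_index[i],
                                   end_index = cycles$end_index[i])
  }
  meta <- data.frame(cycle_id = cycles$cycle_id[keep],
                     subject_id = recording$subject_id,
                     label = cycles$activity_label[keep],
                     start_index = cycles$start_index[keep],
                     end_index = cycles$end_index[keep],
                     stringsAsFactors = FALSE)
  list(features = feats, meta = meta)
}

#' Rank features by squared one-vs-one linear-SVM weight
#'
#' Features are z-score standardized (constant columns map to zero), one
#' soft-margin linear machine is trained per unordered class pair, and the
#' importance of feature j is the sum over machines of the squared primal
#' weight `w_j^2`. The ranking is by non-increasing importance, ties broken
#' by feature name.
#'
#' @param features numeric matrix (rows = cycles, 152 named columns).
#' @param labels class label per row (at least 2 classes, 2 rows each).
#' @param cost soft-margin cost of the ranking machines (default 1).
#' @return a `feature_ranking`: data.frame `name, score` ordered by rank.
#' @export
rank_features_svm <- function(features, labels, cost = 1) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("feature ranking needs at least two classes")
  std <- fit_standardizer(features)
  X <- apply_standardizer(std, features)
  imp <- numeric(ncol(X))
  for (i in seq_len(length(classes) - 1L)) {
    for (j in (i + 1L):length(classes)) {
      sel <- labels %in% c(classes[i], classes[j])
      y <- ifelse(labels[sel] == classes[i], 1, -1)
      fit <- smo_fit(X[sel, , drop = FALSE], y, cost = cost, degree = 1L)
      w <- as.vector(crossprod(X[sel, , drop = FALSE], fit$alpha * y))
      imp <- imp + w^2
    }
  }
  nm <- colnames(features)
  ord <- order(-imp, nm)
  structure(data.frame(name = nm[ord], score = imp[ord],
                       stringsAsFactors = FALSE),
            class = c("feature_ranking", "data.frame"))
}

#' First k names of a feature ranking
#'
#' @param ranking a `feature_ranking` from [rank_features_svm].
#' @param k how many features to keep, `1 <= k <= nrow(ranking)`
#'   (default 20).
#' @return character vector of length `k`.
#' @export
select_top <- function(ranking, k = 20L) {
  if (!(k >= 1L && k <= nrow(ranking)))
    stop("k must lie between 1 and ", nrow(ranking))
  ranking$name[seq_len(k)]
}

#' Write the feature-name registry as JSON (for stability checks)
#' @param path output path.
#' @export
write_feature_registry <- function(path) {
  jsonlite::write_json(feature_names(), path)
  invisible(path)
}

#' Write a feature matrix plus metadata as CSV
#'
#' Columns `cycle_id, subject_id, label` then the 152 named features.
#' @param features matrix from [extract_cycle_features].
#' @param meta matching metadata data.frame.
#' @param path output path.
#' @export
write_features_csv <- function(features, meta, path) {
  df <- cbind(meta[, c("cycle_id", "subject_id", "label")],
              as.data.frame(features))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature CSV written by [write_features_csv]
#' @param path input path.
#' @return list with `features` matrix and `meta` data.frame.
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- df[, c("cycle_id", "subject_id", "label")]
  feats <- as.matrix(df[, setdiff(names(df),
                                  c("cycle_id", "subject_id", "label"))])
  list(features = feats, meta = meta)
}
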