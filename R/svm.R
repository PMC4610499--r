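# Soft-margin SVM on a polynomial kernel, trained by the SMO solver in
# src/smo.cpp. Decision convention: f(x) = sum_i alpha_i y_i K(x_i, x) - b.

poly_kernel <- function(A, B, degree) {
  K <- tcrossprod(A, B)
  if (degree != 1L) K <- K^degree
  K
}

smo_fit <- function(X, y, cost = 1, degree = 1L, tol = 1e-3,
                    max_epochs = 200L) {
  K <- poly_kernel(X, X, degree)
  res <- smo_train_cpp(K, y, cost, tol, max_epochs)
  sv <- which(res$alpha > 1e-8)
  list(alpha = res$alpha, b = res$b, sv = sv,
       X = X[sv, , drop = FALSE], ay = (res$alpha * y)[sv],
       degree = degree)
}

smo_decision <- function(fit, Xnew) {
  K <- poly_kernel(Xnew, fit$X, fit$degree)
  as.vector(K %*% fit$ay) - fit$b
}

# z-score standardization fitted on training data; constant columns are
# mapped to zero rather than NaN
fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sig <- apply(X, 2L, sd)
  list(mu = mu, sig = sig)
}

apply_standardizer <- function(std, X) {
  sig <- ifelse(std$sig > 0, std$sig, 1)
  Z <- sweep(sweep(X, 2L, std$mu, "-"), 2L, sig, "/")
  if (any(std$sig == 0)) Z[, std$sig == 0] <- 0
  Z
}

#' Classifier specification
#'
#' A pairwise (one-vs-one) soft-margin SVM: one binary machine per unordered
#' class pair on z-score standardized features, polynomial kernel
#' `(x . y)^degree`, majority voting with ties broken by the class with the
#' larger aggregate decision margin.
#'
#' @param degree polynomial kernel exponent (default 1, i.e. linear).
#' @param complexity soft-margin cost C (default 1).
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(degree = 1L, complexity = 1.0) {
  stopifnot(complexity > 0, degree >= 1L)
  structure(list(kernel = "polynomial", degree = as.integer(degree),
                 complexity = complexity),
            class = "classifier_spec")
}

#' Train the pairwise SVM activity classifier
#'
#' @param features numeric matrix, one row per cycle.
#' @param labels class label per row (>= 2 classes, no non-finite features).
#' @param spec a [classifier_spec].
#' @return a `gait_svm` model.
#' @export
train_classifier <- function(features, labels, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  labels <- as.character(labels)
  if (any(!is.finite(features))) stop("features must be finite")
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("training needs at least two classes")
  std <- fit_standardizer(features)
  X <- apply_standardizer(std, features)
  machines <- list()
  for (i in seq_len(length(classes) - 1L)) {
    for (j in (i + 1L):length(classes)) {
      sel <- labels %in% c(classes[i], classes[j])
      y <- ifelse(labels[sel] == classes[i], 1, -1)
      fit <- smo_fit(X[sel, , drop = FALSE], y,
                     cost = spec$complexity, degree = spec$degree)
      machines[[length(machines) + 1L]] <-
        list(pos = classes[i], neg = classes[j], fit = fit)
    }
  }
  structure(list(classes = classes, machines = machines, std = std,
                 spec = spec, feature_names = colnames(features)),
            class = "gait_svm")
}

#' @export
print.gait_svm <- function(x, ...) {
  cat(sprintf(
    "<gait_svm> %d classes (%s), %d pairwise machines, degree %d, C = %g\n",
    length(x$classes), paste(x$classes, collapse = ", "),
    length(x$machines), x$spec$degree, x$spec$complexity))
  invisible(x)
}

#' Predict activity labels with a trained pairwise SVM
#'
#' One-vs-one voting; ties go to the class with the larger aggregate signed
#' decision margin over its machines.
#'
#' @param object a `gait_svm` from [train_classifier].
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.gait_svm <- function(object, newdata, ...) {
  X <- apply_standardizer(object$std, newdata)
  n <- nrow(X)
  votes <- matrix(0L, n, length(object$classes),
                  dimnames = list(NULL, object$classes))
  margin <- matrix(0, n, length(object$classes),
                   dimnames = list(NULL, object$classes))
  for (m in object$machines) {
    d <- smo_decision(m$fit, X)
    pos <- d >= 0
    votes[, m$pos] <- votes[, m$pos] + as.integer(pos)
    votes[, m$neg] <- votes[, m$neg] + as.integer(!pos)
    margin[, m$pos] <- margin[, m$pos] + d
    margin[, m$neg] <- margin[, m$neg] - d
  }
  vapply(seq_len(n), function(i) {
    v <- votes[i, ]
    top <- which(v == max(v))
    if (length(top) > 1L) top <- top[which.max(margin[i, top])]
    object$classes[top]
  }, character(1L))
}
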