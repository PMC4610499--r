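#' Per-class specificity, sensitivity and overall accuracy
#'
#' For a square confusion matrix of per-class counts (rows = true class,
#' columns = predicted class): `sensitivity_c = TP_c / row-sum_c`,
#' `specificity_c = TN_c / (TN_c + FP_c)`, overall accuracy =
#' `trace / total`, all in percent. A class with an empty row gets `NA`
#' (undefined), not zero.
#'
#' @param m square non-negative count matrix with matching dimnames.
#' @return list with `sensitivity`, `specificity` (named vectors, %),
#'   `accuracy` (%), and `confusion_pct` (row-normalized matrix, %).
#' @export
confusion_metrics <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0)) stop("confusion matrix counts must be non-negative")
  k <- nrow(m)
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("C", seq_len(k))
  }
  total <- sum(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  tp <- diag(m)
  sens <- ifelse(rs > 0, 100 * tp / rs, NA_real_)
  fp <- cs - tp
  tn <- total - rs - fp
  spec <- ifelse(tn + fp > 0, 100 * tn / (tn + fp), NA_real_)
  conf_pct <- m
  for (i in seq_len(k))
    conf_pct[i, ] <- if (rs[i] > 0) 100 * m[i, ] / rs[i] else NA_real_
  list(sensitivity = setNames(sens, rownames(m)),
       specificity = setNames(spec, rownames(m)),
       accuracy = if (total > 0) 100 * sum(tp) / total else NA_real_,
       confusion_pct = conf_pct)
}

build_confusion <- function(truth, pred, classes) {
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (i in seq_along(truth))
    m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  m
}

make_report <- function(fold_acc, confusion, step_detection = NULL) {
  met <- confusion_metrics(confusion)
  structure(list(
    fold_accuracy = fold_acc,
    average_accuracy = mean(fold_acc),
    accuracy_sd = if (length(fold_acc) > 1L) sd(fold_acc) else 0,
    confusion_counts = confusion,
    confusion_pct = met$confusion_pct,
    sensitivity = met$sensitivity,
    specificity = met$specificity,
    step_detection = step_detection), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> average accuracy %.2f%% (sd %.2f) over %d fold(s)\n",
              x$average_accuracy, x$accuracy_sd, length(x$fold_accuracy)))
  cat("confusion (row-normalized %):\n")
  print(round(x$confusion_pct, 1))
  invisible(x)
}

#' Leave-one-subject-out evaluation of the pairwise SVM
#'
#' One fold per subject: that subject's cycles are the test set, all others
#' the training set. Standardization and (when `select_top_k` is given)
#' the SVM-weight feature ranking are refit on each training split only, so
#' no information leaks from the test fold. With `paper_mode = TRUE` the
#' top-k selection is instead done once on the full dataset before the
#' folds, reproducing a single global selection.
#'
#' @param features numeric matrix, one row per cycle.
#' @param labels class label per row.
#' @param subjects subject identifier per row (>= 2 distinct).
#' @param spec a [classifier_spec].
#' @param select_top_k number of top-ranked features to keep per fold
#'   (NULL = use all features).
#' @param paper_mode single global feature selection (default FALSE).
#' @return an `evaluation_report`: per-fold and average accuracy (%),
#'   accuracy sd across folds, pooled confusion matrix (counts and
#'   row-normalized %), per-class sensitivity and specificity.
#' @export
loso_evaluate <- function(features, labels, subjects,
                          spec = classifier_spec(), select_top_k = NULL,
                          paper_mode = FALSE) {
  labels <- as.character(labels)
  subjects <- as.character(subjects)
  subj <- unique(subjects)
  if (length(subj) < 2L) stop("LOSO needs at least two subjects")
  classes <- sort(unique(labels))
  global_sel <- NULL
  if (!is.null(select_top_k) && paper_mode) {
    global_sel <- select_top(rank_features_svm(features, labels),
                             k = select_top_k)
  }
  fold_acc <- numeric(0)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(classes, classes))
  for (s in subj) {
    test <- subjects == s
    if (!any(test)) {
      warning("subject ", s, " has no cycles; fold skipped")
      next
    }
    Xtr <- features[!test, , drop = FALSE]
    ytr <- labels[!test]
    sel <- if (!is.null(global_sel)) global_sel
           else if (!is.null(select_top_k))
             select_top(rank_features_svm(Xtr, ytr), k = select_top_k)
           else colnames(features)
    model <- train_classifier(Xtr[, sel, drop = FALSE], ytr, spec)
    pred <- predict(model, features[test, sel, drop = FALSE])
    truth <- labels[test]
    fold_acc <- c(fold_acc, 100 * mean(pred == truth))
    confusion <- confusion + build_confusion(truth, pred, classes)
  }
  make_report(fold_acc, confusion)
}

#' Train on one dataset, test on another
#'
#' Single split: the classifier (and optional per-split feature selection)
#' is fit on the full training set and evaluated on the test set. Test
#' classes absent from training are rejected up front.
#'
#' @param train_features,train_labels training cycles.
#' @param test_features,test_labels test cycles.
#' @param spec a [classifier_spec].
#' @param select_top_k optional top-k feature selection fit on training.
#' @return an `evaluation_report` with a single fold.
#' @export
cross_dataset_evaluate <- function(train_features, train_labels,
                                   test_features, test_labels,
                                   spec = classifier_spec(),
                                   select_top_k = NULL) {
  train_labels <- as.character(train_labels)
  test_labels <- as.character(test_labels)
  unseen <- setdiff(unique(test_labels), unique(train_labels))
  if (length(unseen) > 0L)
    stop("test labels absent from training: ",
         paste(unseen, collapse = ", "))
  sel <- if (!is.null(select_top_k))
    select_top(rank_features_svm(train_features, train_labels),
               k = select_top_k)
  else colnames(train_features)
  model <- train_classifier(train_features[, sel, drop = FALSE],
                            train_labels, spec)
  pred <- predict(model, test_features[, sel, drop = FALSE])
  classes <- sort(unique(test_labels))
  acc <- 100 * mean(pred == test_labels)
  make_report(acc, build_confusion(test_labels, pred, classes))
}

report_to_list <- function(report) {
  list(average_accuracy = report$average_accuracy,
       accuracy_sd = report$accuracy_sd,
       fold_accuracy = report$fold_accuracy,
       confusion_counts = apply(report$confusion_counts, 1L, as.list),
       confusion_pct = apply(report$confusion_pct, 1L, as.list),
       sensitivity = as.list(report$sensitivity),
       specificity = as.list(report$specificity),
       step_detection = report$step_detection)
}
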