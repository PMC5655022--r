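## Model evaluation ---------------------------------------------------------
##
## Repeated stratified k-fold cross-validation.  Accuracy is pooled over
## folds within a repetition (correct predictions / dataset size), giving
## one accuracy per repetition; the 95% confidence interval halfwidth is
## t_{0.975, R-1} * sd / sqrt(R) over the R repetition accuracies.
## Preprocessing (imputation, normalization, PCA) is re-fit inside every
## training fold to avoid leakage into the held-out fold.

#' t-based confidence-interval halfwidth over repetition accuracies
#'
#' Uses the t statistic with degrees of freedom equal to the number of
#' repetitions minus one and the sample standard deviation.
#'
#' @param accuracies Numeric vector, length >= 2.
#' @param level Confidence level, default 0.95.
#' @return Halfwidth on the same scale as the accuracies (0 for a constant
#'   vector).
#' @export
confidence_interval <- function(accuracies, level = 0.95) {
  n <- length(accuracies)
  if (n < 2) stop("need >= 2 values")
  stats::qt((1 + level) / 2, df = n - 1) * stats::sd(accuracies) / sqrt(n)
}

#' Per-class precision, recall and F-measure from a confusion matrix
#'
#' The positive class is `progress`.  Ratios with a zero denominator are
#' reported as NA (not-available), never silently zero.
#'
#' @param tp,fn,fp,tn Confusion counts (progress = positive).
#' @return List with elements `progress` and `no_progress`, each
#'   `c(precision, recall, f)`.
#' @export
class_metrics <- function(tp, fn, fp, tn) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  fmeas <- function(p, r) {
    if (is.na(p) || is.na(r) || p + r == 0) return(NA_real_)
    2 * p * r / (p + r)
  }
  pp <- ratio(tp, tp + fp); rp <- ratio(tp, tp + fn)
  pn <- ratio(tn, tn + fn); rn <- ratio(tn, tn + fp)
  list(progress = c(precision = pp, recall = rp, f = fmeas(pp, rp)),
       no_progress = c(precision = pn, recall = rn, f = fmeas(pn, rn)))
}

stratified_folds <- function(y, folds) {
  ## round-robin assignment within each shuffled class: every fold's class
  ## proportions differ from the global ones by at most one sample
  fold <- integer(length(y))
  for (l in levels(y)) {
    idx <- sample(which(y == l))
    fold[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  fold
}

#' Repeated stratified cross-validation
#'
#' @param spec A [model_spec()].
#' @param x Numeric matrix of feature deltas (may contain NA; the median
#'   imputation fitted on each training fold handles them).
#' @param y Two-level factor (`no_progress`, `progress`).
#' @param folds Number of folds, default 10; reduced with a warning when
#'   the minority class has fewer members than folds.
#' @param repetitions Number of repeated partitions, default 10.
#' @param seed Master seed; partitioning and per-fold model seeds are
#'   derived from it.
#' @param variant Preprocessing variant (`"raw"`, `"raw_pca"`, `"norm"`,
#'   `"norm_pca"`), fitted inside each training fold.
#' @param variance_threshold PCA explained-variance threshold.
#' @param level Confidence level for the interval.
#' @return A `cv_result`: `accuracies` (one per repetition), `mean_accuracy`,
#'   `ci_halfwidth`, `confusion` (pooled tp/fn/fp/tn over all repetitions),
#'   `metrics` (per class), `spec`, `folds`, `repetitions`, `variant`, `n`.
#' @export
repeated_stratified_cv <- function(spec, x, y, folds = 10L,
                                   repetitions = 10L, seed = 1L,
                                   variant = "raw",
                                   variance_threshold = 0.95,
                                   level = 0.95) {
  y <- factor(y, levels = c("no_progress", "progress"))
  n <- nrow(x)
  if (n < folds) stop("dataset smaller than the number of folds")
  min_class <- min(table(y))
  if (min_class < 1) stop("both classes must be present")
  if (min_class < folds) {
    folds <- max(2L, as.integer(min_class))
    warning("minority class smaller than folds; reduced to ", folds)
  }
  acc <- numeric(repetitions)
  cm <- c(tp = 0, fn = 0, fp = 0, tn = 0)
  for (r in seq_len(repetitions)) {
    set.seed(seed * 1000L + r)
    fold <- stratified_folds(y, folds)
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      prep <- fit_preprocess(x[tr, , drop = FALSE], variant,
                             variance_threshold)
      ytr <- droplevels(y[tr])
      pred <- if (nlevels(ytr) < 2) {
        ## degenerate single-class training fold: predict that class
        factor(rep(levels(ytr), sum(te)), levels = levels(y))
      } else {
        fit <- train_model(model_spec(spec$name, spec$hyper,
                                      seed = spec$seed + 7919L * r + f),
                           prep$x, ytr)
        factor(as.character(predict(fit,
                                    apply_preprocess(prep$recipe,
                                                     x[te, , drop = FALSE]))),
               levels = levels(y))
      }
      truth <- y[te]
      correct <- correct + sum(pred == truth)
      cm["tp"] <- cm["tp"] + sum(pred == "progress" & truth == "progress")
      cm["fn"] <- cm["fn"] + sum(pred == "no_progress" & truth == "progress")
      cm["fp"] <- cm["fp"] + sum(pred == "progress" & truth == "no_progress")
      cm["tn"] <- cm["tn"] +
        sum(pred == "no_progress" & truth == "no_progress")
    }
    acc[r] <- correct / n
  }
  structure(list(accuracies = acc, mean_accuracy = mean(acc),
                 ci_halfwidth = confidence_interval(acc, level),
                 confusion = cm,
                 metrics = class_metrics(cm[["tp"]], cm[["fn"]],
                                         cm[["fp"]], cm[["tn"]]),
                 spec = spec, folds = folds, repetitions = repetitions,
                 variant = variant, n = n),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s  acc %.2f%% ±%.2f%%  (%dx%d-fold, n=%d, %s)\n",
              x$spec$name, 100 * x$mean_accuracy, 100 * x$ci_halfwidth,
              x$repetitions, x$folds, x$n, x$variant))
  m <- x$metrics
  cat(sprintf("  P: prec %.3f rec %.3f F %.3f | N: prec %.3f rec %.3f F %.3f\n",
              m$progress["precision"], m$progress["recall"], m$progress["f"],
              m$no_progress["precision"], m$no_progress["recall"],
              m$no_progress["f"]))
  invisible(x)
}
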