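# Evaluation: accuracy, ROC AUC, Spearman rank correlation, stratified
# k-fold cross-validation, and repeated experiments with mean/sd summaries.

#' Classification accuracy
#'
#' @param predicted,truth Equal-length binary label vectors.
#' @return Fraction of exact matches, in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  predicted <- check_binary_labels(predicted, name = "predicted")
  truth <- check_binary_labels(truth, n = length(predicted), name = "truth")
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  mean(predicted == truth)
}

#' Area under the ROC curve
#'
#' Computed by the Mann-Whitney formulation: the probability that a random
#' positive outscores a random negative, with ties counted one half. Exact,
#' tie-aware, and invariant to any strictly increasing transform of the
#' scores.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param truth Binary labels in `{0, 1}`; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)) # 0.75
#' @export
roc_auc <- function(scores, truth) {
  truth <- check_binary_labels(truth, name = "truth")
  if (!is.numeric(scores) || length(scores) != length(truth) || anyNA(scores))
    stop("'scores' must be numeric, complete, and match 'truth'",
         call. = FALSE)
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores) # average ranks on ties
  (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Spearman rank correlation coefficient
#'
#' The Pearson correlation of average-ranked values: 1 for a perfect
#' positive, -1 for a perfect negative monotone relationship between the
#' predicted and true rankings.
#'
#' @param predicted,truth Equal-length numeric vectors of length >= 2;
#'   constant input has undefined rank correlation and is an error.
#' @return SRCC in `[-1, 1]`.
#' @export
spearman_rho <- function(predicted, truth) {
  if (!is.numeric(predicted) || !is.numeric(truth) ||
      length(predicted) != length(truth))
    stop("'predicted' and 'truth' must be equal-length numeric vectors",
         call. = FALSE)
  if (length(truth) < 2L) stop("need at least two observations", call. = FALSE)
  if (anyNA(predicted) || anyNA(truth))
    stop("missing values are not allowed", call. = FALSE)
  if (stats::sd(truth) == 0 || stats::sd(predicted) == 0)
    stop("rank correlation is undefined for constant input", call. = FALSE)
  stats::cor(predicted, truth, method = "spearman")
}

#' Stratified k-fold assignment
#'
#' Partitions samples into `k` folds preserving the class ratio within one
#' sample per fold. If some class has fewer than `k` members the folds fall
#' back to a plain (unstratified) seeded partition with a warning, which is
#' also the behaviour selected by `stratify = FALSE` (used for regression).
#'
#' @param labels Class labels (any type) or, unstratified, anything of
#'   length n.
#' @param k Number of folds (default 10).
#' @param seed Optional seed for the shuffles.
#' @param stratify Stratify on `labels`?
#' @return An integer vector of fold indices in `1..k`.
#' @export
stratified_kfold <- function(labels, k = 10, seed = NULL, stratify = TRUE) {
  k <- check_count(k, "k")
  n <- length(labels)
  if (k > n) stop("'k' cannot exceed the number of samples", call. = FALSE)
  with_seed(seed, {
    folds <- integer(n)
    if (stratify) {
      classes <- unique(labels)
      if (any(table(labels) < k)) {
        warning("a class has fewer than k members; using plain folds",
                call. = FALSE)
        stratify <- FALSE
      } else {
        for (cls in classes) {
          idx <- which(labels == cls)
          folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
        }
      }
    }
    if (!stratify) folds <- sample(rep_len(seq_len(k), n))
    folds
  })
}

#' Cross-validate a model trainer
#'
#' Trains `k` models, each on all folds but one, scores each on its
#' held-out fold, and summarises the per-fold metric values with their mean
#' and standard deviation. No model is ever evaluated on a sample it was
#' trained on.
#'
#' @param trainer `function(x, y)` returning a fitted model.
#' @param x Sample-by-feature matrix.
#' @param y Labels (classification) or numeric responses (regression).
#' @param scorer `function(model, x, y)` returning a named numeric vector
#'   of metrics for the held-out fold.
#' @param k Number of folds (default 10).
#' @param seed Optional seed for the fold assignment.
#' @param stratify Stratify folds on `y` (default TRUE; use FALSE for
#'   regression).
#' @return A `"metric_summary"`: per-fold values (k x metrics matrix),
#'   `mean`, and `sd`.
#' @export
cross_validate <- function(trainer, x, y, scorer, k = 10, seed = NULL,
                           stratify = TRUE) {
  x <- as_numeric_matrix(x)
  folds <- stratified_kfold(y, k = k, seed = seed, stratify = stratify)
  vals <- lapply(seq_len(k), function(f) {
    tr <- which(folds != f); te <- which(folds == f)
    tryCatch({
      fit <- trainer(x[tr, , drop = FALSE], y[tr])
      scorer(fit, x[te, , drop = FALSE], y[te])
    }, error = function(e) {
      stop(sprintf("fold %d: %s", f, conditionMessage(e)), call. = FALSE)
    })
  })
  metric_summary(do.call(rbind, vals))
}

#' Repeat a seeded experiment
#'
#' Runs `experiment(seed)` for seeds `base_seed, ..., base_seed + n - 1`
#' and summarises the per-repeat metric values (the repeated-runs protocol:
#' report the mean and standard deviation over repeats).
#'
#' @param experiment `function(seed)` returning a named numeric vector.
#' @param n_repeats Number of repeats (default 10).
#' @param base_seed First seed.
#' @return A `"metric_summary"` over repeats.
#' @export
repeat_experiment <- function(experiment, n_repeats = 10, base_seed = 1) {
  n_repeats <- check_count(n_repeats, "n_repeats")
  vals <- lapply(seq_len(n_repeats) - 1L,
                 function(i) experiment(base_seed + i))
  metric_summary(do.call(rbind, vals))
}

metric_summary <- function(values) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("metric", seq_len(ncol(values)))
  structure(list(values = values,
                 mean = colMeans(values),
                 sd = apply(values, 2L, stats::sd)),
            class = "metric_summary")
}

#' @export
print.metric_summary <- function(x, ...) {
  cat(sprintf("Metric summary over %d runs\n", nrow(x$values)))
  for (m in colnames(x$values))
    cat(sprintf("  %s: mean %.4f, sd %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}
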