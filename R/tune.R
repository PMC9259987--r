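# Indicator-driven hyperparameter search over autoencoder settings: the
# tuning loop trains a candidate representation model, scores a classifier
# on its codes by cross-validation, and keeps searching until the
# (accuracy, AUC) pair has failed to improve for `indicator` consecutive
# candidates.

#' Tune the representation model with the Indicator loop
#'
#' Implements the tuning automaton: starting from best performance `(0, 0)`
#' and Indicator 10, each iteration draws a candidate hyperparameter setting
#' (seeded uniform draw without replacement; the grid is reshuffled and
#' re-cycled when exhausted), trains a [dp_autoencoder()] on `x_repr` with
#' its own full budget, encodes `x_task`, and scores a [dp_classifier()] on
#' the codes by stratified k-fold cross-validation. If the candidate's
#' (mean accuracy, mean AUC) pair improves on the best pair — both
#' components at least as good and at least one strictly better — the best
#' is updated and the Indicator resets to its start value; otherwise it
#' decrements. The loop stops at Indicator 0 (or `max_evals`).
#'
#' Each setting's evaluation seed is a fixed function of `seed` and the
#' setting's grid index, so re-evaluating a setting is deterministic and
#' the whole search trajectory is reproducible from `seed`.
#'
#' @param x_repr Matrix for representation learning (the larger "second
#'   private" dataset).
#' @param x_task Matrix for the classification task, sharing the feature
#'   set of `x_repr`.
#' @param labels Binary labels for `x_task`.
#' @param grid Named list of candidate sets for the autoencoder:
#'   any of `hidden` (a list of width vectors), `learning_rate`, `epochs`,
#'   `dropout`, `corruption_sd`, `clip_norm`, `batch_size`. The full
#'   factorial of the supplied sets is searched.
#' @param epsilon_ae,epsilon_clf Stage budgets (each candidate retrains the
#'   representation model from scratch with the full `epsilon_ae`).
#' @param alpha Shared Renyi order.
#' @param k Cross-validation folds for candidate scoring (default 10).
#' @param indicator Start/reset value of the Indicator (default 10).
#' @param max_evals Optional hard cap on candidate evaluations.
#' @param seed Master seed of the search.
#' @param clf_args Fixed extra arguments for the candidate classifiers.
#' @param ae_args Fixed extra arguments for the candidate autoencoders.
#' @return A list of class `"dp_tune"`: `best_ae` and `best_classifier`
#'   (refit on the full task data with the best setting), `best_settings`,
#'   `best_performance` (accuracy, AUC), and the evaluation `trace`.
#' @export
dp_tune <- function(x_repr, x_task, labels, grid, epsilon_ae = 1,
                    epsilon_clf = 1, alpha = 2, k = 10, indicator = 10,
                    max_evals = NULL, seed = 1, clf_args = list(),
                    ae_args = list()) {
  if (!is.list(grid) || length(grid) == 0L ||
      any(!lengths(grid)) || is.null(names(grid)))
    stop("'grid' must be a non-empty named list of candidate sets",
         call. = FALSE)
  allowed <- c("hidden", "learning_rate", "epochs", "dropout",
               "corruption_sd", "clip_norm", "batch_size")
  bad <- setdiff(names(grid), allowed)
  if (length(bad))
    stop("unknown grid entries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  indicator <- check_count(indicator, "indicator")
  x_repr <- as_numeric_matrix(x_repr, "x_repr")
  x_task <- as_numeric_matrix(x_task, "x_task")
  labels <- check_binary_labels(labels, n = nrow(x_task))

  idx_grid <- expand.grid(lapply(grid, seq_along))
  settings <- lapply(seq_len(nrow(idx_grid)), function(i) {
    s <- lapply(names(grid), function(nm) grid[[nm]][[idx_grid[i, nm]]])
    names(s) <- names(grid)
    s
  })
  ns <- length(settings)
  setting_seed <- function(si) as.integer((seed + 7919 * si) %% 2147483647L)

  evaluate <- function(si) {
    s <- settings[[si]]
    cseed <- setting_seed(si)
    ae <- do.call(dp_autoencoder,
                  c(list(x = x_repr, epsilon = epsilon_ae, alpha = alpha,
                         seed = cseed),
                    s, ae_args))
    codes <- encode(ae, x_task)
    trainer <- function(x, y)
      do.call(dp_classifier,
              c(list(x = x, y = y, epsilon = epsilon_clf, alpha = alpha,
                     seed = cseed), clf_args))
    scorer <- function(fit, x, y)
      c(accuracy = accuracy(predict(fit, x, type = "class"), y),
        auc = roc_auc(predict(fit, x, type = "score"), y))
    cv <- cross_validate(trainer, codes, labels, scorer, k = k,
                         seed = cseed)
    list(perf = cv$mean, ae = ae)
  }

  cache <- vector("list", ns)
  best <- c(accuracy = 0, auc = 0)
  best_si <- NA_integer_
  ind <- indicator
  trace <- list()
  evals <- 0L
  done <- FALSE
  with_seed(seed, {
    while (!done) {
      perm <- sample.int(ns)
      for (si in perm) {
        if (is.null(cache[[si]])) cache[[si]] <- evaluate(si)
        perf <- cache[[si]]$perf
        evals <- evals + 1L
        improved <- perf[["accuracy"]] >= best[["accuracy"]] &&
          perf[["auc"]] >= best[["auc"]] &&
          (perf[["accuracy"]] > best[["accuracy"]] ||
             perf[["auc"]] > best[["auc"]])
        if (improved) {
          best <- perf
          best_si <- si
          ind <- indicator
        } else {
          ind <- ind - 1L
        }
        trace[[evals]] <- data.frame(
          eval = evals, setting = si, accuracy = perf[["accuracy"]],
          auc = perf[["auc"]], improved = improved, indicator = ind)
        if (ind == 0L || (!is.null(max_evals) && evals >= max_evals)) {
          done <- TRUE
          break
        }
      }
    }
  })

  best_ae <- cache[[best_si]]$ae
  best_clf <- do.call(
    dp_classifier,
    c(list(x = encode(best_ae, x_task), y = labels, epsilon = epsilon_clf,
           alpha = alpha, seed = setting_seed(best_si)),
      clf_args))
  structure(
    list(best_ae = best_ae, best_classifier = best_clf,
         best_settings = settings[[best_si]],
         best_performance = best,
         trace = do.call(rbind, trace),
         indicator_final = ind, n_evals = evals, seed = seed),
    class = "dp_tune")
}

#' @export
print.dp_tune <- function(x, ...) {
  cat("Indicator-driven hyperparameter search\n")
  cat(sprintf("  evaluations: %d (final indicator %d)\n",
              x$n_evals, x$indicator_final))
  cat(sprintf("  best performance: accuracy %.3f, AUC %.3f\n",
              x$best_performance[["accuracy"]],
              x$best_performance[["auc"]]))
  cat("  best settings:\n")
  for (nm in names(x$best_settings))
    cat(sprintf("    %s = %s\n", nm,
                paste(x$best_settings[[nm]], collapse = ", ")))
  invisible(x)
}
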