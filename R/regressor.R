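# The differentially private scalar regressor (dpRegM) and the per-drug
# panel wrapper.

#' Fit a differentially private scalar regressor
#'
#' Trains a linear-output regression network (dense/ReLU/dropout hidden
#' layers, a final width-1 dense layer) on low-dimensional codes under mean
#' squared error, with standard batch-wise DP-SGD. Intended for IC50-like
#' drug-sensitivity responses: samples with a missing response are dropped
#' before any computation, matching the keep-only-tested-samples rule.
#'
#' @param x Numeric matrix of inputs (rows are samples; typically codes
#'   from [encode()]).
#' @param y Numeric response vector; `NA` entries mark untested samples and
#'   are removed together with their rows before training.
#' @param hidden Hidden widths before the single output unit.
#' @param epsilon Total RDP budget (default 1.0); `Inf` = non-private.
#' @param alpha Renyi order.
#' @param clip_norm Per-example l2 clipping norm.
#' @param dropout Hidden drop rate.
#' @param learning_rate,batch_size,epochs Plain SGD hyperparameters.
#' @param shuffle Reshuffle batches each epoch.
#' @param seed Seed; `NULL` uses the session stream.
#' @param init Optional initial parameters.
#' @return An object of class `"dp_regressor"` with parameters, the spent
#'   accountant, per-epoch loss, and `n_used` (observed samples trained on).
#' @examples
#' set.seed(1)
#' codes <- matrix(rnorm(300), 100, 3)
#' y <- codes %*% c(1, -1, 0.5) + rnorm(100, sd = 0.1)
#' y[sample(100, 20)] <- NA
#' fit <- dp_regressor(codes, y, hidden = 4, epsilon = Inf,
#'                     clip_norm = Inf, epochs = 10, batch_size = 20,
#'                     seed = 1)
#' fit$n_used # 80
#' @export
dp_regressor <- function(x, y, hidden = 16, epsilon = 1, alpha = 2,
                         clip_norm = 1, dropout = 0.2, learning_rate = 0.01,
                         batch_size = 50, epochs = 40, shuffle = TRUE,
                         seed = NULL, init = NULL) {
  cl <- match.call()
  batch_size <- check_count(batch_size, "batch_size")
  epochs <- check_count(epochs, "epochs")
  x <- as_numeric_matrix(x)
  if (!is.numeric(y) || length(y) != nrow(x))
    stop("'y' must be a numeric vector with one entry per row of 'x'",
         call. = FALSE)
  keep <- which(!is.na(y))
  if (length(keep) == 0L)
    stop("all responses are missing", call. = FALSE)
  x <- x[keep, , drop = FALSE]
  yk <- as.numeric(y[keep])
  x <- check_training_matrix(x, batch_size, min_batches = 2L)
  hidden <- as.integer(hidden)
  planned <- epochs * (nrow(x) %/% batch_size)
  acct <- rdp_accountant(epsilon, alpha = alpha, clip_norm = clip_norm,
                         planned_steps = planned)
  target <- matrix(yk, ncol = 1L)
  res <- with_seed(seed, {
    params <- init %||% init_params(c(ncol(x), hidden, 1L))
    dp_train_engine(params, x, target = target, loss = "mse",
                    accountant = acct, learning_rate = learning_rate,
                    batch_size = batch_size, epochs = epochs,
                    dropout = dropout, shuffle = shuffle)
  })
  structure(
    list(params = res$params,
         spec = list(input_dim = ncol(x), hidden = hidden,
                     widths = c(hidden, 1L), dropout = dropout,
                     features = colnames(x)),
         privacy = res$accountant,
         loss = res$epoch_loss,
         n_used = length(keep),
         used_rows = keep,
         config = list(learning_rate = learning_rate,
                       batch_size = batch_size, epochs = epochs),
         seed = seed, call = cl),
    class = "dp_regressor")
}

#' Predict method for dp_regressor
#'
#' @param object A [dp_regressor()] fit.
#' @param newdata Matrix with the training feature count.
#' @param ... Unused.
#' @return A numeric vector of predicted responses.
#' @export
predict.dp_regressor <- function(object, newdata, ...) {
  newdata <- as_numeric_matrix(newdata, "newdata")
  check_feature_compat(object, newdata)
  drop(mlp_forward(object$params, newdata))
}

#' @export
print.dp_regressor <- function(x, ...) {
  cat("Differentially private regressor\n")
  cat(sprintf("  architecture: %d -> %s\n",
              x$spec$input_dim, paste(x$spec$widths, collapse = " -> ")))
  cat(sprintf("  trained on %d observed samples\n", x$n_used))
  if (length(x$loss))
    cat(sprintf("  training MSE: %.5g -> %.5g\n",
                x$loss[1L], x$loss[length(x$loss)]))
  print(x$privacy)
  invisible(x)
}

#' @export
coef.dp_regressor <- function(object, ...) object$params

#' @export
residuals.dp_regressor <- function(object, x, y, ...) {
  keep <- which(!is.na(y))
  y[keep] - predict(object, x[keep, , drop = FALSE])
}

#' Fit one private regressor per drug
#'
#' Given a drugs-by-samples response table with missing entries, fits an
#' independent [dp_regressor()] (with its own full privacy budget: the
#' models are disjoint publications) for each drug on the samples where
#' that drug was tested. Drugs with no observed response are skipped with
#' a warning.
#'
#' @param x Code matrix, samples in rows. If `responses` has column names
#'   they must match `rownames(x)` (in any order).
#' @param responses Numeric matrix, drugs in rows, samples in columns,
#'   `NA` for untested pairs.
#' @param ... Passed on to [dp_regressor()].
#' @param seed Base seed; drug `j` uses `seed + j`.
#' @return A list of `dp_regressor` fits named by drug, classed
#'   `"dp_drug_panel"`.
#' @export
dp_drug_panel <- function(x, responses, ..., seed = NULL) {
  x <- as_numeric_matrix(x)
  responses <- as_numeric_matrix(responses, "responses")
  if (!is.null(colnames(responses)) && !is.null(rownames(x))) {
    if (!all(colnames(responses) %in% rownames(x)))
      stop("'responses' has samples absent from 'x'", call. = FALSE)
    x <- x[colnames(responses), , drop = FALSE]
  } else if (ncol(responses) != nrow(x)) {
    stop("'responses' must have one column per row of 'x'", call. = FALSE)
  }
  drugs <- rownames(responses) %||% paste0("drug", seq_len(nrow(responses)))
  fits <- vector("list", nrow(responses))
  names(fits) <- drugs
  for (j in seq_len(nrow(responses))) {
    yj <- responses[j, ]
    if (all(is.na(yj))) {
      warning(sprintf("drug '%s': all responses missing, skipped", drugs[j]),
              call. = FALSE)
      next
    }
    sj <- if (is.null(seed)) NULL else seed + j
    fits[[j]] <- dp_regressor(x, yj, ..., seed = sj)
  }
  structure(fits[!vapply(fits, is.null, logical(1))],
            class = "dp_drug_panel")
}

#' @export
print.dp_drug_panel <- function(x, ...) {
  cat(sprintf("Panel of %d differentially private drug-response regressors\n",
              length(x)))
  n_used <- vapply(unclass(x), `[[`, numeric(1), "n_used")
  cat(sprintf("  observed samples per drug: %d-%d (median %g)\n",
              min(n_used), max(n_used), stats::median(n_used)))
  invisible(x)
}
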