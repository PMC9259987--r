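# The differentially private binary classifier head (dpClassM).

#' Fit a differentially private binary classifier
#'
#' Trains a softmax classifier head on low-dimensional codes (typically the
#' output of [encode()] from a [dp_autoencoder()]): a dense/ReLU/dropout
#' hidden layer followed by a width-2 dense layer whose scores are turned
#' into class probabilities by a numerically stable softmax, under
#' cross-entropy loss. Training uses DP-SGD with its own accountant: the
#' total budget `epsilon` is split uniformly over the planned
#' `epochs * floor(n_train / batch_size)` batch updates.
#'
#' After each epoch the model is evaluated on a held-out stratified
#' `validation_split` fraction; training stops early when neither validation
#' accuracy nor validation AUC has strictly improved for `patience`
#' consecutive evaluations. Budget unspent because of early stopping is
#' reported as unspent, never reallocated.
#'
#' @param x Numeric matrix of inputs (rows are samples; typically codes).
#' @param y Binary labels in `{0, 1}` (class imbalance is expected and
#'   handled by stratification); both classes must be present.
#' @param hidden Width(s) of the hidden layer(s) before the 2-unit output.
#' @param epsilon Total RDP budget for this fit (default 1.0, the second
#'   stage of the two-stage 1.0 + 1.0 convention); `Inf` = non-private.
#' @param alpha Renyi order.
#' @param clip_norm Per-example l2 clipping norm.
#' @param dropout Hidden drop rate.
#' @param learning_rate,batch_size,epochs Plain SGD hyperparameters.
#' @param patience Consecutive non-improving evaluations tolerated before
#'   stopping (default 10).
#' @param validation_split Fraction held out (stratified) for the
#'   early-stopping evaluations; 0 disables early stopping and trains on
#'   all rows for the full schedule.
#' @param shuffle Reshuffle batches each epoch.
#' @param seed Seed for the whole fit; `NULL` uses the session stream.
#' @param init Optional initial parameters.
#' @return An object of class `"dp_classifier"` with the trained
#'   parameters, accountant, and a per-epoch `history` data frame (loss,
#'   validation accuracy, validation AUC).
#' @examples
#' set.seed(1)
#' codes <- matrix(rnorm(400), 200, 2)
#' y <- as.integer(codes[, 1] > 0)
#' fit <- dp_classifier(codes, y, hidden = 4, epsilon = Inf,
#'                      clip_norm = Inf, epochs = 5, batch_size = 20,
#'                      seed = 1)
#' mean(predict(fit, codes, type = "class") == y)
#' @export
dp_classifier <- function(x, y, hidden = 16, epsilon = 1, alpha = 2,
                          clip_norm = 1, dropout = 0.2, learning_rate = 0.05,
                          batch_size = 50, epochs = 40, patience = 10,
                          validation_split = 0.1, shuffle = TRUE,
                          seed = NULL, init = NULL) {
  cl <- match.call()
  batch_size <- check_count(batch_size, "batch_size")
  epochs <- check_count(epochs, "epochs")
  check_number(validation_split, "validation_split", lower = 0)
  if (validation_split >= 0.5)
    stop("'validation_split' must be < 0.5", call. = FALSE)
  x <- as_numeric_matrix(x)
  y <- check_binary_labels(y, n = nrow(x), name = "y")
  if (length(unique(y)) < 2L)
    stop("'y' must contain both classes", call. = FALSE)
  hidden <- as.integer(hidden)

  res <- with_seed(seed, {
    n <- nrow(x)
    if (validation_split > 0) {
      val_idx <- stratified_holdout(y, validation_split)
    } else {
      val_idx <- integer(0)
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    xtr <- x[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    xval <- x[val_idx, , drop = FALSE]; yval <- y[val_idx]
    xtr <- check_training_matrix(xtr, batch_size, min_batches = 1L)
    planned <- epochs * (nrow(xtr) %/% batch_size)
    acct <- rdp_accountant(epsilon, alpha = alpha, clip_norm = clip_norm,
                           planned_steps = planned)
    params <- init %||% init_params(c(ncol(x), hidden, 2L))

    best_acc <- -Inf; best_auc <- -Inf; bad <- 0L
    history <- list()
    hook <- NULL
    if (length(val_idx) > 0L) {
      hook <- function(p, epoch, loss) {
        prob <- softmax(mlp_forward(p, xval))
        pred <- as.integer(prob[, 2L] > prob[, 1L])
        acc <- mean(pred == yval)
        auc <- if (length(unique(yval)) == 2L) roc_auc(prob[, 2L], yval)
               else NA_real_
        improved <- acc > best_acc || (!is.na(auc) && auc > best_auc)
        best_acc <<- max(best_acc, acc)
        if (!is.na(auc)) best_auc <<- max(best_auc, auc)
        bad <<- if (improved) 0L else bad + 1L
        history[[epoch]] <<- c(loss = loss, val_accuracy = acc,
                               val_auc = auc)
        bad >= patience
      }
    }
    out <- dp_train_engine(params, xtr, target = ytr, loss = "softmax_ce",
                           accountant = acct,
                           learning_rate = learning_rate,
                           batch_size = batch_size, epochs = epochs,
                           dropout = dropout, shuffle = shuffle,
                           epoch_hook = hook)
    hist_df <- if (length(history)) {
      data.frame(epoch = seq_along(history),
                 do.call(rbind, history), row.names = NULL)
    } else {
      data.frame(epoch = seq_along(out$epoch_loss), loss = out$epoch_loss,
                 val_accuracy = NA_real_, val_auc = NA_real_)
    }
    list(out = out, history = hist_df,
         best = c(accuracy = best_acc, auc = best_auc),
         n_train = nrow(xtr), n_val = length(val_idx))
  })

  structure(
    list(params = res$out$params,
         spec = list(input_dim = ncol(x), hidden = hidden,
                     widths = c(hidden, 2L), dropout = dropout,
                     features = colnames(x)),
         privacy = res$out$accountant,
         history = res$history,
         best_validation = res$best,
         stopped_early = res$out$stopped_early,
         epochs_run = res$out$epochs_run,
         config = list(learning_rate = learning_rate,
                       batch_size = batch_size, epochs = epochs,
                       patience = patience,
                       validation_split = validation_split,
                       n_train = res$n_train, n_val = res$n_val),
         seed = seed, call = cl),
    class = "dp_classifier")
}

# Stratified holdout: indices of ~fraction of each class (at least 1).
stratified_holdout <- function(y, fraction) {
  unlist(lapply(unique(y), function(cls) {
    idx <- which(y == cls)
    take <- max(1L, round(length(idx) * fraction))
    sample(idx, take)
  }), use.names = FALSE)
}

#' Predict method for dp_classifier
#'
#' @param object A [dp_classifier()] fit.
#' @param newdata Matrix with the training feature count.
#' @param type `"prob"` (n x 2 probability matrix), `"score"` (probability
#'   of class 1), or `"class"` (argmax label; ties break toward class 0).
#' @param ... Unused.
#' @return Probabilities, scores or 0/1 labels.
#' @export
predict.dp_classifier <- function(object, newdata,
                                  type = c("prob", "class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as_numeric_matrix(newdata, "newdata")
  check_feature_compat(object, newdata)
  prob <- softmax(mlp_forward(object$params, newdata))
  colnames(prob) <- c("0", "1")
  rownames(prob) <- rownames(newdata)
  switch(type,
         prob = prob,
         score = prob[, 2L],
         class = as.integer(prob[, 2L] > prob[, 1L]))
}

#' @export
print.dp_classifier <- function(x, ...) {
  cat("Differentially private binary classifier\n")
  cat(sprintf("  architecture: %d -> %s -> softmax\n",
              x$spec$input_dim, paste(x$spec$widths, collapse = " -> ")))
  cat(sprintf("  epochs run: %d%s\n", x$epochs_run,
              if (isTRUE(x$stopped_early)) " (stopped early)" else ""))
  if (is.finite(x$best_validation[["accuracy"]]))
    cat(sprintf("  best validation: accuracy %.3f, AUC %.3f\n",
                x$best_validation[["accuracy"]],
                x$best_validation[["auc"]]))
  print(x$privacy)
  invisible(x)
}

#' @export
summary.dp_classifier <- function(object, ...) {
  print(object)
  cat(sprintf("  parameters: %d\n", n_flat_params(object$params)))
  invisible(object)
}

#' @export
coef.dp_classifier <- function(object, ...) object$params

#' @export
plot.dp_classifier <- function(x, ...) {
  plot(x$history$epoch, x$history$loss, type = "b", xlab = "epoch",
       ylab = "training loss", main = "dpClassM training", ...)
  invisible(x)
}
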