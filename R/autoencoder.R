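# The differentially private denoising autoencoder (dpAE).

#' Fit a differentially private denoising autoencoder
#'
#' Trains a stacked denoising autoencoder with DP-SGD: the input is
#' corrupted with elementwise Gaussian noise, passed through a dense/ReLU/
#' dropout encoder to the bottleneck code, decoded through the mirrored
#' stack, and trained to reconstruct the clean input under mean squared
#' error. Every gradient update is clipped per example, perturbed with
#' calibrated Gaussian noise, and charged to a Renyi-DP accountant whose
#' schedule spends exactly `epsilon` over `epochs * floor(n / batch_size)`
#' steps.
#'
#' The default desk-scale width profile is `c(64, 32, 16)`; the full-scale
#' profile `c(8000, 4000, 2000)` used for genome-wide matrices runs through
#' the identical code path.
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#'   Continuous expression-like values and discrete copy-number calls in
#'   `{-1, 0, 1}` are both valid inputs. The sample (row) is the unit of
#'   privacy.
#' @param hidden Encoder widths; the last entry is the code dimension and
#'   the decoder mirrors the encoder back to `ncol(x)`.
#' @param epsilon Total RDP budget for this fit (default 1, the two-stage
#'   convention granting the representation model its own budget of 1.0);
#'   `Inf` trains non-privately (no noise).
#' @param alpha Renyi order (> 1, default 2).
#' @param clip_norm Per-example l2 clipping norm `C` (default 1; `Inf`
#'   only with `epsilon = Inf`).
#' @param corruption_sd Input corruption sd (default 0.1).
#' @param dropout Hidden-layer drop rate (default 0.2).
#' @param learning_rate,batch_size,epochs Plain SGD hyperparameters
#'   (no momentum).
#' @param shuffle Reshuffle sample order each epoch (seeded).
#' @param seed Seed fixing initialisation, shuffling, corruption, dropout
#'   and noise; `NULL` uses the session RNG stream.
#' @param init Optional initial parameter list (defaults to He-normal
#'   [init_params()]).
#' @return An object of class `"dp_autoencoder"`: parameters, architecture
#'   spec, the spent accountant, and the per-epoch reconstruction loss.
#'   The object (and its serialized bundle) contains no training data.
#' @seealso [encode()], [predict.dp_autoencoder()], [save_bundle()]
#' @examples
#' X <- gen_expression(synth_config(n_samples = 120, n_features = 30,
#'                                  latent_dim = 4, seed = 1))$X
#' fit <- dp_autoencoder(X, hidden = c(16, 8), epsilon = 1, epochs = 3,
#'                       batch_size = 20, seed = 1)
#' privacy_spent(fit)
#' @export
dp_autoencoder <- function(x, hidden = c(64, 32, 16), epsilon = 1, alpha = 2,
                           clip_norm = 1, corruption_sd = 0.1, dropout = 0.2,
                           learning_rate = 0.01, batch_size = 50, epochs = 20,
                           shuffle = TRUE, seed = NULL, init = NULL) {
  cl <- match.call()
  batch_size <- check_count(batch_size, "batch_size")
  epochs <- check_count(epochs, "epochs")
  check_number(corruption_sd, "corruption_sd", lower = 0)
  x <- check_training_matrix(x, batch_size, min_batches = 2L)
  hidden <- as.integer(hidden)
  if (length(hidden) < 1L || any(hidden < 1L))
    stop("'hidden' must be positive encoder widths", call. = FALSE)
  d <- ncol(x)
  widths <- c(hidden, rev(hidden[-length(hidden)]), d)
  planned <- epochs * (nrow(x) %/% batch_size)
  acct <- rdp_accountant(epsilon, alpha = alpha, clip_norm = clip_norm,
                         planned_steps = planned)
  res <- with_seed(seed, {
    # positive hidden biases + damped output layer: without them a deep
    # ReLU reconstruction net on zero-mean data collapses into the dead
    # all-zero solution and never recovers
    params <- init %||% init_params(c(d, widths), bias = 0.5,
                                    output_scale = 0.1)
    dp_train_engine(params, x, target = x, loss = "mse", accountant = acct,
                    learning_rate = learning_rate, batch_size = batch_size,
                    epochs = epochs, dropout = dropout,
                    corruption_sd = corruption_sd, shuffle = shuffle)
  })
  structure(
    list(params = res$params,
         spec = list(input_dim = d, widths = widths,
                     code_index = length(hidden), hidden = hidden,
                     dropout = dropout, corruption_sd = corruption_sd,
                     features = colnames(x)),
         privacy = res$accountant,
         loss = res$epoch_loss,
         config = list(learning_rate = learning_rate,
                       batch_size = batch_size, epochs = epochs,
                       shuffle = shuffle),
         seed = seed, call = cl),
    class = "dp_autoencoder")
}

#' Encode data with a trained model
#'
#' @param object A fitted model.
#' @param ... Passed to methods.
#' @export
encode <- function(object, ...) UseMethod("encode")

#' Transfer features: map data into the autoencoder's code space
#'
#' Applies the trained encoder in inference mode (clean input, dropout off)
#' and returns the bottleneck representation. This is the transfer-learning
#' step: the code of a privately trained autoencoder can be extracted for
#' any dataset sharing the feature set, and downstream private models are
#' fit on the codes instead of the raw data.
#'
#' @param object A [dp_autoencoder()] fit.
#' @param x Matrix with the same feature count (and names, if present) the
#'   model was trained on; use [intersect_features()] first otherwise.
#' @param ... Unused.
#' @return An n x code_dim matrix, deterministic in `x` and row-aligned
#'   with it.
#' @export
encode.dp_autoencoder <- function(object, x, ...) {
  x <- as_numeric_matrix(x)
  check_feature_compat(object, x)
  enc <- object$params[seq_len(object$spec$code_index)]
  cur <- x
  for (l in seq_along(enc)) {
    cur <- sweep(cur %*% enc[[l]]$W, 2L, enc[[l]]$b, "+")
    cur <- pmax(cur, 0)
  }
  rownames(cur) <- rownames(x)
  cur
}

check_feature_compat <- function(object, x) {
  if (ncol(x) != object$spec$input_dim)
    stop(sprintf(
      "feature mismatch: model expects %d features, input has %d; intersect features first",
      object$spec$input_dim, ncol(x)), call. = FALSE)
  feats <- object$spec$features
  if (!is.null(feats) && !is.null(colnames(x)) &&
      !identical(colnames(x), feats))
    stop("feature names differ from the training features; align with intersect_features()",
         call. = FALSE)
  invisible(TRUE)
}

#' Predict method for dp_autoencoder
#'
#' @param object A [dp_autoencoder()] fit.
#' @param newdata Matrix of samples to push through the network.
#' @param type `"reconstruction"` (decoder output) or `"code"` (the
#'   bottleneck representation, as [encode()]).
#' @param ... Unused.
#' @return A matrix with `ncol(x)` or code-dimension columns.
#' @export
predict.dp_autoencoder <- function(object, newdata,
                                   type = c("reconstruction", "code"), ...) {
  type <- match.arg(type)
  newdata <- as_numeric_matrix(newdata, "newdata")
  check_feature_compat(object, newdata)
  if (type == "code") return(encode(object, newdata))
  out <- mlp_forward(object$params, newdata)
  rownames(out) <- rownames(newdata)
  colnames(out) <- object$spec$features
  out
}

#' Align two matrices on their common features
#'
#' Restricts both sample-by-feature matrices to the sorted intersection of
#' their feature (column) names, identically ordered, leaving sample rows
#' untouched. This mirrors the unification step needed before a model
#' trained on one cohort can encode another.
#'
#' @param a,b Numeric matrices with feature names as column names.
#' @return A list with elements `a` and `b`, column-aligned. An empty
#'   intersection is an error.
#' @export
intersect_features <- function(a, b) {
  a <- as_numeric_matrix(a, "a"); b <- as_numeric_matrix(b, "b")
  if (is.null(colnames(a)) || is.null(colnames(b)))
    stop("both matrices need feature (column) names", call. = FALSE)
  common <- sort(intersect(colnames(a), colnames(b)))
  if (length(common) == 0L)
    stop("the matrices share no features", call. = FALSE)
  list(a = a[, common, drop = FALSE], b = b[, common, drop = FALSE])
}

#' @export
print.dp_autoencoder <- function(x, ...) {
  cat("Differentially private denoising autoencoder\n")
  cat(sprintf("  architecture: %d -> %s (code dim %d)\n",
              x$spec$input_dim, paste(x$spec$widths, collapse = " -> "),
              x$spec$hidden[length(x$spec$hidden)]))
  cat(sprintf("  corruption sd %g, dropout %g\n",
              x$spec$corruption_sd, x$spec$dropout))
  if (length(x$loss))
    cat(sprintf("  reconstruction loss: %.5g (first epoch) -> %.5g (last)\n",
                x$loss[1L], x$loss[length(x$loss)]))
  print(x$privacy)
  invisible(x)
}

#' @export
summary.dp_autoencoder <- function(object, ...) {
  print(object)
  cat(sprintf("  parameters: %d\n", n_flat_params(object$params)))
  invisible(object)
}

#' @export
coef.dp_autoencoder <- function(object, ...) object$params

#' @export
plot.dp_autoencoder <- function(x, ...) {
  plot(seq_along(x$loss), x$loss, type = "b", xlab = "epoch",
       ylab = "mean reconstruction loss",
       main = "dpAE training loss", ...)
  invisible(x)
}
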