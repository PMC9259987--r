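# Dense feed-forward networks as pure computations: activations, dropout,
# input corruption, initialisation, forward passes with caches for
# backpropagation, and the loss functionals.
#
# Parameter convention used everywhere in the package: `params` is an ordered
# list of layers, each `list(W, b)` with `W` an (in x out) matrix and `b` a
# length-out bias vector. Hidden layers are dense -> ReLU -> dropout; the
# final layer is dense with identity activation (the classifier's softmax is
# part of its loss / predict step). Flattened gradients and serialized
# weights use layer-major order, each W column-major followed by its bias.

#' Rectified linear unit
#'
#' @param x Numeric vector, matrix or array.
#' @return `max(0, x)` elementwise, preserving dimensions.
#' @export
relu <- function(x) {
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  pmax(x, 0)
}

#' Inverted dropout
#'
#' In training mode each unit is zeroed independently with probability
#' `rate` and survivors are scaled by `1/(1-rate)`, so the expected
#' activation is unchanged. In inference mode the input is returned as is.
#'
#' @param x Numeric vector or matrix of activations.
#' @param rate Drop probability in `[0, 1)`.
#' @param mode `"train"` or `"infer"`.
#' @param seed Optional seed making the mask reproducible without touching
#'   the caller's RNG stream.
#' @return The masked (train) or untouched (infer) activations.
#' @export
apply_dropout <- function(x, rate, mode = c("train", "infer"), seed = NULL) {
  mode <- match.arg(mode)
  check_number(rate, "rate", lower = 0)
  if (rate >= 1) stop("'rate' must be < 1", call. = FALSE)
  if (mode == "infer" || rate == 0) return(x)
  with_seed(seed, {
    keep <- (stats::runif(length(x)) >= rate) / (1 - rate)
    out <- x * keep
    out
  })
}

#' Corrupt input with additive Gaussian noise
#'
#' The denoising-autoencoder corruption step: elementwise
#' `Normal(0, sd^2)` noise is added to the raw original input; the training
#' target remains the clean input. A fresh draw is made on every call.
#'
#' @param x Numeric matrix (samples by features).
#' @param sd Corruption standard deviation, >= 0; 0 returns `x` unchanged.
#'   The working default across the package is 0.1 (the best-performing
#'   value of the {0.1, 0.2, 0.3} grid for expression-like data).
#' @param seed Optional seed for a reproducible draw.
#' @return `x` plus noise, same shape.
#' @export
corrupt_input <- function(x, sd, seed = NULL) {
  check_number(sd, "sd", lower = 0)
  if (sd == 0) return(x)
  with_seed(seed, x + stats::rnorm(length(x), mean = 0, sd = sd))
}

#' Row-wise softmax with max-subtraction
#'
#' @param x Numeric matrix of scores (rows are samples) or a vector.
#' @return Matrix of the same shape whose rows are probability vectors.
#' @export
softmax <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as_numeric_matrix(x)
  z <- exp(x - apply(x, 1L, max))
  z / rowSums(z)
}

#' Mean squared error
#'
#' Used both as the reconstruction loss of the autoencoder (mean over all
#' entries; lower loss means higher similarity to the clean input) and as
#' the regression loss.
#'
#' @param prediction,target Numeric vectors or matrices of identical shape.
#' @return A single non-negative number, 0 exactly at perfect prediction.
#' @export
mse_loss <- function(prediction, target) {
  if (length(prediction) != length(target) ||
      !identical(dim(prediction), dim(target)))
    stop("'prediction' and 'target' must have identical shape", call. = FALSE)
  if (length(prediction) == 0L) stop("empty input", call. = FALSE)
  mean((prediction - target)^2)
}

#' Binary cross-entropy from class probabilities
#'
#' Mean of `-log p(true class)` (natural log), with probabilities clamped
#' below at 1e-12 for numerical safety.
#'
#' @param probabilities n x 2 matrix of class probabilities (rows normalized).
#' @param labels Integer vector of true labels in `{0, 1}`.
#' @return A single non-negative number.
#' @export
cross_entropy_loss <- function(probabilities, labels) {
  probabilities <- as_numeric_matrix(probabilities, "probabilities")
  if (ncol(probabilities) != 2L)
    stop("'probabilities' must have two columns", call. = FALSE)
  labels <- check_binary_labels(labels, n = nrow(probabilities))
  p_true <- probabilities[cbind(seq_along(labels), labels + 1L)]
  mean(-log(pmax(p_true, 1e-12)))
}

check_binary_labels <- function(labels, n = NULL, name = "labels") {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!is.numeric(labels) || anyNA(labels) || !all(labels %in% c(0, 1)))
    stop(sprintf("'%s' must contain only 0 and 1", name), call. = FALSE)
  if (!is.null(n) && length(labels) != n)
    stop(sprintf("'%s' has length %d, expected %d", name, length(labels), n),
         call. = FALSE)
  as.integer(labels)
}

#' He-normal parameter initialisation
#'
#' Weights for each dense layer are drawn `Normal(0, 2/fan_in)` (suited to
#' ReLU units); biases start at zero by default. For deep ReLU stacks
#' trained on zero-mean data, a small positive hidden bias (`bias`) and a
#' damped final layer (`output_scale < 1`) guard against the dead-ReLU
#' collapse in which the network shrinks to the trivial all-zero solution;
#' [dp_autoencoder()] uses those safeguards by default.
#'
#' @param sizes Integer vector `c(input_dim, width_1, ..., width_L)` giving
#'   the layer widths of the network.
#' @param seed Optional seed for a reproducible draw.
#' @param bias Initial value of the hidden-layer biases (final layer biases
#'   are always 0).
#' @param output_scale Multiplier applied to the final layer's weights.
#' @return A parameter list (one `list(W, b)` per dense layer).
#' @export
init_params <- function(sizes, seed = NULL, bias = 0, output_scale = 1) {
  if (length(sizes) < 2L || any(sizes < 1L) || any(sizes != as.integer(sizes)))
    stop("'sizes' must be >= 2 positive integer widths", call. = FALSE)
  check_number(bias, "bias")
  check_number(output_scale, "output_scale", lower = 0)
  sizes <- as.integer(sizes)
  L <- length(sizes) - 1L
  with_seed(seed, {
    lapply(seq_len(L), function(l) {
      p <- sizes[l]; q <- sizes[l + 1L]
      W <- matrix(stats::rnorm(p * q, sd = sqrt(2 / p)), p, q)
      if (l == L) W <- W * output_scale
      list(W = W, b = rep(if (l == L) 0 else bias, q))
    })
  })
}

# Forward pass keeping the caches needed by backpropagation.
# dropout: scalar rate applied to every hidden layer.
# Returns list(out, a = inputs to each layer (a[[1]] = x), z = hidden
# pre-activations, mask = dropout masks already scaled by 1/(1-rate)).
mlp_forward_cache <- function(params, x, dropout = 0, train = FALSE) {
  x <- as_numeric_matrix(x)
  L <- length(params)
  if (ncol(x) != nrow(params[[1L]]$W))
    stop(sprintf("input has %d columns but the network expects %d",
                 ncol(x), nrow(params[[1L]]$W)), call. = FALSE)
  a <- vector("list", L)
  z <- vector("list", L)
  mask <- vector("list", L)
  cur <- x
  for (l in seq_len(L)) {
    a[[l]] <- cur
    zz <- cur %*% params[[l]]$W
    zz <- sweep(zz, 2L, params[[l]]$b, "+")
    if (l < L) {
      z[[l]] <- zz
      h <- pmax(zz, 0)
      if (train && dropout > 0) {
        m <- matrix((stats::runif(length(h)) >= dropout) / (1 - dropout),
                    nrow(h), ncol(h))
        mask[[l]] <- m
        h <- h * m
      }
      cur <- h
    } else {
      cur <- zz
    }
  }
  list(out = cur, a = a, z = z, mask = mask)
}

#' Forward pass through a dense ReLU network
#'
#' Applies each dense layer followed by ReLU (and, in training mode,
#' inverted dropout) to all but the final layer; the final dense layer uses
#' the identity activation. Inference mode is deterministic.
#'
#' @param params Parameter list from [init_params()].
#' @param x Input matrix (samples by features).
#' @param dropout Hidden-layer drop rate in `[0, 1)`; only active in
#'   training mode.
#' @param mode `"infer"` (deterministic) or `"train"`.
#' @param seed Optional seed for the dropout masks.
#' @return The output matrix of the final layer (identity activation).
#' @export
mlp_forward <- function(params, x, dropout = 0, mode = c("infer", "train"),
                        seed = NULL) {
  mode <- match.arg(mode)
  check_number(dropout, "dropout", lower = 0)
  if (dropout >= 1) stop("'dropout' must be < 1", call. = FALSE)
  with_seed(seed,
            mlp_forward_cache(params, x, dropout, train = mode == "train")$out)
}

# Per-example gradient of the loss wrt the final-layer output.
# loss = "mse": target is a matrix conformable with out; per-example loss is
#   the feature-mean squared error, so the batch mean equals mse_loss().
# loss = "softmax_ce": target is a 0/1 label vector; the gradient wrt the
#   logits is p - onehot.
loss_grad_out <- function(loss, out, target) {
  if (loss == "mse") {
    if (is.null(dim(target))) target <- matrix(target, ncol = ncol(out))
    if (!identical(dim(out), dim(target)))
      stop("target shape does not match network output", call. = FALSE)
    list(dout = 2 * (out - target) / ncol(out),
         loss = mean((out - target)^2))
  } else if (loss == "softmax_ce") {
    y <- check_binary_labels(target, n = nrow(out))
    p <- softmax(out)
    dout <- p
    idx <- cbind(seq_along(y), y + 1L)
    dout[idx] <- dout[idx] - 1
    list(dout = dout, loss = mean(-log(pmax(p[idx], 1e-12))))
  } else stop("unknown loss '", loss, "'", call. = FALSE)
}

# Backpropagate per-example deltas dL_i/dz_l through the cache.
mlp_backward_deltas <- function(params, cache, dout) {
  L <- length(params)
  deltas <- vector("list", L)
  deltas[[L]] <- dout
  if (L > 1L) for (l in (L - 1L):1L) {
    back <- deltas[[l + 1L]] %*% t(params[[l + 1L]]$W)
    if (!is.null(cache$mask[[l]])) back <- back * cache$mask[[l]]
    deltas[[l]] <- back * (cache$z[[l]] > 0)
  }
  deltas
}
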