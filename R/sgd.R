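# Differentially private SGD: per-example l2 gradient clipping, Gaussian
# noise on the clipped gradient sum, and the parameter update, with every
# noisy step charged to the accountant.
#
# Sensitivity convention: noise is added to the SUM of clipped per-example
# gradients, whose l2 sensitivity to adding/removing one sample is exactly
# the clip norm C; the noisy sum is then divided by the batch size.

#' Clip a gradient vector to a maximum l2 norm
#'
#' Returns `g * min(1, C / ||g||_2)`: direction preserved, output norm at
#' most `C`, vectors already within the bound unchanged.
#'
#' @param g Numeric vector (a flattened per-example gradient).
#' @param clip_norm Clipping norm `C > 0` (`Inf` disables clipping).
#' @return The clipped vector.
#' @examples
#' clip_gradient(c(3, 4), 1) # c(0.6, 0.8)
#' @export
clip_gradient <- function(g, clip_norm) {
  if (!is.numeric(g) || anyNA(g) || any(!is.finite(g)))
    stop("'g' must be a finite numeric vector", call. = FALSE)
  check_number(clip_norm, "clip_norm", lower = 0, strict_lower = TRUE,
               allow_inf = TRUE)
  nrm <- sqrt(sum(g^2))
  if (nrm > clip_norm) g * (clip_norm / nrm) else g
}

#' Clipped, noised gradient aggregation (the DP-SGD mechanism)
#'
#' Clips each per-example gradient to norm `C`, sums them, adds isotropic
#' Gaussian noise `Normal(0, (sigma * C)^2)` per coordinate, and divides by
#' the batch size. With `sigma = 0` this is the plain clipped mean.
#'
#' @param grads Matrix with one flattened per-example gradient per row (as
#'   produced by [per_example_gradients()]), or a list of equal-length
#'   vectors.
#' @param clip_norm Clipping norm `C > 0`.
#' @param sigma Noise multiplier (the absolute noise sd is `sigma * C`),
#'   >= 0.
#' @param seed Optional seed for a reproducible noise draw.
#' @return The noisy mean gradient (numeric vector).
#' @export
noisy_aggregate <- function(grads, clip_norm, sigma, seed = NULL) {
  if (is.list(grads)) grads <- do.call(rbind, grads)
  grads <- as_numeric_matrix(grads, "grads")
  if (nrow(grads) == 0L) stop("empty gradient batch", call. = FALSE)
  check_number(sigma, "sigma", lower = 0)
  clipped <- t(apply(grads, 1L, clip_gradient, clip_norm = clip_norm))
  if (ncol(grads) == 1L) clipped <- matrix(clipped, ncol = 1L)
  s <- colSums(clipped)
  if (sigma > 0)
    s <- s + with_seed(seed,
                       stats::rnorm(length(s), sd = sigma * clip_norm))
  s / nrow(grads)
}

#' Per-example gradients of a network loss
#'
#' Computes, for every sample in the batch, the gradient of that sample's
#' loss with respect to all network parameters, flattened layer-major (each
#' weight matrix column-major, then its bias). Per-example gradients are
#' what makes the clipping step bound any single sample's influence on an
#' update. The mean over rows equals the gradient of the batch-mean loss.
#'
#' @param params Parameter list ([init_params()]).
#' @param x Input matrix (one row per sample).
#' @param y Targets: a matrix/vector conformable with the network output for
#'   `loss = "mse"`, or 0/1 labels for `loss = "softmax_ce"`.
#' @param loss `"mse"` or `"softmax_ce"`.
#' @param dropout Hidden drop rate; masks (if any) are shared across the
#'   per-example gradients of the batch, as in a training step.
#' @param seed Optional seed for the dropout masks.
#' @return An n x P matrix, one flattened gradient per sample.
#' @export
per_example_gradients <- function(params, x, y, loss = c("mse", "softmax_ce"),
                                  dropout = 0, seed = NULL) {
  loss <- match.arg(loss)
  with_seed(seed, {
    cache <- mlp_forward_cache(params, x, dropout, train = dropout > 0)
    lg <- loss_grad_out(loss, cache$out, y)
    deltas <- mlp_backward_deltas(params, cache, lg$dout)
    flat_per_example(cache, deltas)
  })
}

# n x P matrix of flattened per-example gradients from a forward cache and
# its deltas. Column order matches flatten_params().
flat_per_example <- function(cache, deltas) {
  blocks <- lapply(seq_along(deltas), function(l) {
    a <- cache$a[[l]]; d <- deltas[[l]]
    p <- ncol(a); q <- ncol(d)
    # grad of W[i, j] for each sample = a[, i] * d[, j], column-major in j
    w <- a[, rep(seq_len(p), times = q), drop = FALSE] *
      d[, rep(seq_len(q), each = p), drop = FALSE]
    cbind(w, d)
  })
  do.call(cbind, blocks)
}

# Fast path used by the training loops: clipped gradient sums per layer
# without materialising n x P matrices. Per-example gradient norms follow
# from ||outer(a_i, d_i)||_F = ||a_i|| ||d_i|| and backprop's linearity in
# the output delta, so scaling each sample's deltas by min(1, C/||g_i||)
# scales its whole flattened gradient. Returns clipped SUMS (not means).
clipped_grad_sums <- function(params, cache, deltas, clip_norm) {
  n <- nrow(cache$a[[1L]])
  if (is.finite(clip_norm)) {
    sq <- rep(0, n)
    for (l in seq_along(params))
      sq <- sq + rowSums(deltas[[l]]^2) * (rowSums(cache$a[[l]]^2) + 1)
    nrm <- sqrt(sq)
    scale <- ifelse(nrm > clip_norm, clip_norm / nrm, 1)
  } else {
    scale <- rep(1, n)
  }
  lapply(seq_along(params), function(l) {
    d <- deltas[[l]] * scale
    list(W = crossprod(cache$a[[l]], d), b = colSums(d))
  })
}

# One forward/backward pass returning noisy mean gradients (layer list) and
# the batch loss. Draws the Gaussian noise as a single flattened vector in
# flatten_params() order, so it consumes the RNG exactly as
# noisy_aggregate() would on the same batch.
dp_gradients <- function(params, x, y, loss, clip_norm, sigma_abs,
                         dropout = 0) {
  cache <- mlp_forward_cache(params, x, dropout, train = dropout > 0)
  lg <- loss_grad_out(loss, cache$out, y)
  deltas <- mlp_backward_deltas(params, cache, lg$dout)
  sums <- clipped_grad_sums(params, cache, deltas, clip_norm)
  n <- nrow(x)
  if (sigma_abs > 0) {
    noise <- stats::rnorm(n_flat_params(params), sd = sigma_abs)
    pos <- 0L
    for (l in seq_along(sums)) {
      nw <- length(sums[[l]]$W); nb <- length(sums[[l]]$b)
      sums[[l]]$W <- sums[[l]]$W + matrix(noise[pos + seq_len(nw)],
                                          nrow(sums[[l]]$W))
      sums[[l]]$b <- sums[[l]]$b + noise[pos + nw + seq_len(nb)]
      pos <- pos + nw + nb
    }
  }
  grads <- lapply(sums, function(s) list(W = s$W / n, b = s$b / n))
  list(grads = grads, loss = lg$loss)
}

#' One differentially private SGD step
#'
#' Computes per-example gradients on the batch, clips each to the
#' accountant's `clip_norm`, aggregates with calibrated Gaussian noise, and
#' applies `params - learning_rate * noisy_mean_gradient`. The step is
#' charged to the accountant before the update; a fully spent accountant
#' aborts with a budget-exhausted error, and the step is charged whether or
#' not the update is used (e.g. at `learning_rate = 0`).
#'
#' @param params Parameter list.
#' @param x,y Batch inputs and targets (see [per_example_gradients()]).
#' @param loss `"mse"` or `"softmax_ce"`.
#' @param accountant An [rdp_accountant()] supplying `clip_norm` and the
#'   per-step noise scale `sigma`.
#' @param learning_rate Step size, >= 0.
#' @param dropout Hidden drop rate during the forward pass.
#' @param seed Optional seed (dropout masks and noise).
#' @return A list with elements `params` (updated), `accountant` (advanced
#'   by one step) and `loss` (batch loss before the update).
#' @export
dp_sgd_step <- function(params, x, y, loss = c("mse", "softmax_ce"),
                        accountant, learning_rate, dropout = 0, seed = NULL) {
  loss <- match.arg(loss)
  check_number(learning_rate, "learning_rate", lower = 0)
  accountant <- record_step(accountant)
  res <- with_seed(seed,
                   dp_gradients(params, x, y, loss,
                                clip_norm = accountant$clip_norm,
                                sigma_abs = accountant$sigma,
                                dropout = dropout))
  for (l in seq_along(params)) {
    params[[l]]$W <- params[[l]]$W - learning_rate * res$grads[[l]]$W
    params[[l]]$b <- params[[l]]$b - learning_rate * res$grads[[l]]$b
  }
  list(params = params, accountant = accountant, loss = res$loss)
}
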