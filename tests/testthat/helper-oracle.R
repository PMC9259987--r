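# Independent reference implementations used as oracles. Written naively
# (explicit per-sample loops, outer products) and on purpose without any
# package internals, so agreement with the vectorised training code is a
# genuine cross-check.

# Forward pass for one sample through a dense ReLU net (identity output).
ref_forward <- function(params, x) {
  L <- length(params)
  a <- vector("list", L + 1L)
  z <- vector("list", L)
  a[[1L]] <- x
  for (l in seq_len(L)) {
    zz <- drop(a[[l]] %*% params[[l]]$W) + params[[l]]$b
    if (l < L) {
      z[[l]] <- zz
      a[[l + 1L]] <- pmax(zz, 0)
    } else {
      a[[l + 1L]] <- zz
    }
  }
  list(a = a, z = z)
}

# Gradient of one sample's loss wrt all parameters.
# loss "mse": per-sample loss is mean over output entries of squared error.
# loss "softmax_ce": target is a 0/1 label.
ref_grad_sample <- function(params, x, target, loss) {
  f <- ref_forward(params, x)
  L <- length(params)
  out <- f$a[[L + 1L]]
  if (loss == "mse") {
    d <- 2 * (out - target) / length(out)
  } else {
    p <- exp(out - max(out))
    p <- p / sum(p)
    d <- p
    d[target + 1L] <- d[target + 1L] - 1
  }
  grads <- vector("list", L)
  for (l in L:1) {
    grads[[l]] <- list(W = outer(f$a[[l]], d), b = d)
    if (l > 1L) d <- drop(params[[l]]$W %*% d) * (f$z[[l - 1L]] > 0)
  }
  grads
}

# Mean gradient over a batch, accumulated sample by sample.
ref_batch_grad <- function(params, x, targets, loss) {
  n <- nrow(x)
  acc <- NULL
  for (i in seq_len(n)) {
    tg <- if (is.matrix(targets)) targets[i, ] else targets[i]
    g <- ref_grad_sample(params, x[i, ], tg, loss)
    if (is.null(acc)) {
      acc <- g
    } else {
      for (l in seq_along(g)) {
        acc[[l]]$W <- acc[[l]]$W + g[[l]]$W
        acc[[l]]$b <- acc[[l]]$b + g[[l]]$b
      }
    }
  }
  lapply(acc, function(g) list(W = g$W / n, b = g$b / n))
}

# Plain mini-batch SGD, sequential batches, incomplete final batch dropped.
ref_sgd_train <- function(params, x, targets, loss, lr, batch_size, epochs) {
  n <- nrow(x)
  spe <- n %/% batch_size
  for (ep in seq_len(epochs)) {
    for (s in seq_len(spe)) {
      idx <- ((s - 1L) * batch_size + 1L):(s * batch_size)
      tg <- if (is.matrix(targets)) targets[idx, , drop = FALSE]
            else targets[idx]
      g <- ref_batch_grad(params, x[idx, , drop = FALSE], tg, loss)
      for (l in seq_along(params)) {
        params[[l]]$W <- params[[l]]$W - lr * g[[l]]$W
        params[[l]]$b <- params[[l]]$b - lr * g[[l]]$b
      }
    }
  }
  params
}

# Largest absolute difference between two parameter lists.
param_gap <- function(a, b) {
  max(vapply(seq_along(a), function(l) {
    max(abs(a[[l]]$W - b[[l]]$W), abs(a[[l]]$b - b[[l]]$b))
  }, numeric(1)))
}

# AUC by brute-force enumeration of positive-negative pairs (ties = 1/2).
ref_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
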