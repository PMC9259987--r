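# Shared mini-batch DP-SGD training loop. Incomplete final batches are
# dropped so every mechanism invocation has the same batch size and per-step
# budget; one accountant step is charged per parameter update.

dp_train_engine <- function(params, x, target, loss, accountant,
                            learning_rate, batch_size, epochs, dropout = 0,
                            corruption_sd = 0, shuffle = TRUE,
                            epoch_hook = NULL) {
  n <- nrow(x)
  steps_per_epoch <- n %/% batch_size
  epoch_loss <- numeric(0)
  epochs_run <- 0L
  stopped_early <- FALSE
  for (epoch in seq_len(epochs)) {
    order <- if (shuffle) sample.int(n) else seq_len(n)
    losses <- numeric(steps_per_epoch)
    for (s in seq_len(steps_per_epoch)) {
      idx <- order[((s - 1L) * batch_size + 1L):(s * batch_size)]
      xb <- x[idx, , drop = FALSE]
      if (loss == "mse" && is.matrix(target)) {
        yb <- target[idx, , drop = FALSE]
      } else {
        yb <- target[idx]
      }
      xin <- if (corruption_sd > 0) corrupt_input(xb, corruption_sd) else xb
      accountant <- record_step(accountant)
      res <- dp_gradients(params, xin, yb, loss,
                          clip_norm = accountant$clip_norm,
                          sigma_abs = accountant$sigma,
                          dropout = dropout)
      for (l in seq_along(params)) {
        params[[l]]$W <- params[[l]]$W - learning_rate * res$grads[[l]]$W
        params[[l]]$b <- params[[l]]$b - learning_rate * res$grads[[l]]$b
      }
      losses[s] <- res$loss
    }
    epoch_loss <- c(epoch_loss, mean(losses))
    epochs_run <- epoch
    if (!is.null(epoch_hook) &&
        isTRUE(epoch_hook(params, epoch, mean(losses)))) {
      stopped_early <- TRUE
      break
    }
  }
  list(params = params, accountant = accountant, epoch_loss = epoch_loss,
       epochs_run = epochs_run, stopped_early = stopped_early)
}

check_training_matrix <- function(x, batch_size, min_batches = 2L,
                                  name = "x") {
  x <- as_numeric_matrix(x, name)
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite with no missing values", name),
         call. = FALSE)
  if (nrow(x) %/% batch_size < min_batches)
    stop(sprintf(
      "'%s' has %d rows: need at least %d full batches of size %d",
      name, nrow(x), min_batches, batch_size), call. = FALSE)
  x
}
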