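# Per-example clipping, noisy aggregation, per-example gradients and the
# DP-SGD step.

test_that("clipping rescales to the norm bound and preserves direction", {
  expect_equal(clip_gradient(c(3, 4), 1), c(0.6, 0.8))
  expect_equal(clip_gradient(c(0.3, 0.4), 1), c(0.3, 0.4))
  expect_equal(clip_gradient(c(0, 0), 5), c(0, 0))
  expect_error(clip_gradient(c(1, NaN), 1), "finite")
  set.seed(1)
  for (i in 1:50) {
    g <- rnorm(sample(1:20, 1), sd = 10^runif(1, -2, 2))
    C <- runif(1, 0.01, 5)
    cg <- clip_gradient(g, C)
    expect_lte(sqrt(sum(cg^2)), C + 1e-12)
    if (any(g != 0)) # direction preserved
      expect_gt(sum(cg * g), 0)
  }
})

test_that("noise-free aggregation is the clipped mean", {
  out <- noisy_aggregate(rbind(c(2, 0), c(0, 2)), clip_norm = 10, sigma = 0)
  expect_equal(out, c(1, 1))
  expect_error(noisy_aggregate(matrix(0, 0, 2), 1, 0), "empty")
  # determinism under a fixed seed
  g <- matrix(rnorm(20), 5, 4)
  a <- noisy_aggregate(g, 1, 2, seed = 7)
  b <- noisy_aggregate(g, 1, 2, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, noisy_aggregate(g, 1, 2, seed = 8)))
})

test_that("per-example gradients match a hand-derived linear model", {
  # f(x) = w x, loss (f - y)^2, w = 1, sample (x = 2, y = 1): d/dw = 4
  params <- list(list(W = matrix(1, 1, 1), b = 0))
  g <- per_example_gradients(params, matrix(2, 1, 1), matrix(1, 1, 1),
                             "mse")
  expect_equal(g[1, 1], 4)
  expect_equal(g[1, 2], 2) # bias gradient 2(wx + b - y)
})

test_that("per-example gradients average to the batch gradient", {
  set.seed(3)
  for (loss in c("mse", "softmax_ce")) {
    params <- init_params(c(4, 5, 2), seed = 11)
    x <- matrix(rnorm(24), 6, 4)
    y <- if (loss == "mse") matrix(rnorm(12), 6, 2) else
      c(0L, 1L, 1L, 0L, 1L, 0L)
    pe <- per_example_gradients(params, x, y, loss)
    ref <- ref_batch_grad(params, x, y, loss)
    ref_flat <- unlist(lapply(ref, function(l) c(as.numeric(l$W), l$b)))
    expect_lt(max(abs(colMeans(pe) - ref_flat)), 1e-8)
  }
})

test_that("fast clipped path agrees with the explicit per-example route", {
  set.seed(9)
  params <- init_params(c(5, 4, 3, 2), seed = 3)
  x <- matrix(rnorm(40), 8, 5)
  y <- rbinom(8, 1, 0.5)
  for (C in c(0.1, 0.7, 3, 1e9)) {
    fast <- dpnet:::dp_gradients(params, x, y, "softmax_ce",
                                 clip_norm = C, sigma_abs = 0)
    ref <- noisy_aggregate(per_example_gradients(params, x, y,
                                                 "softmax_ce"), C, 0)
    expect_lt(max(abs(dpnet:::flatten_params(fast$grads) - ref)), 1e-12)
  }
})

test_that("a DP-SGD step charges the accountant exactly once", {
  params <- init_params(c(3, 2), seed = 1)
  x <- matrix(rnorm(12), 4, 3)
  y <- matrix(rnorm(8), 4, 2)
  acct <- rdp_accountant(1, 2, 1, planned_steps = 2)

  s1 <- dp_sgd_step(params, x, y, "mse", acct, learning_rate = 0.1,
                    seed = 5)
  expect_equal(s1$accountant$steps_taken, 1L)

  # learning_rate = 0: parameters unchanged, budget still charged
  s0 <- dp_sgd_step(params, x, y, "mse", acct, learning_rate = 0, seed = 5)
  expect_identical(s0$params, params)
  expect_equal(s0$accountant$steps_taken, 1L)

  # the same seed reproduces the step bit for bit
  s1b <- dp_sgd_step(params, x, y, "mse", acct, learning_rate = 0.1,
                     seed = 5)
  expect_identical(s1$params, s1b$params)

  # exhausting the schedule aborts
  s2 <- dp_sgd_step(s1$params, x, y, "mse", s1$accountant, 0.1, seed = 6)
  expect_error(dp_sgd_step(s2$params, x, y, "mse", s2$accountant, 0.1),
               "exhausted")
})

test_that("a noise-free unclipped DP step equals the plain SGD step", {
  params <- init_params(c(4, 3, 1), seed = 2)
  x <- matrix(rnorm(20), 5, 4)
  y <- matrix(rnorm(5), 5, 1)
  acct <- rdp_accountant(Inf, 2, 1e9, planned_steps = 1)
  step <- dp_sgd_step(params, x, y, "mse", acct, learning_rate = 0.3)
  ref <- ref_batch_grad(params, x, y, "mse")
  for (l in seq_along(params)) {
    expect_lt(max(abs(step$params[[l]]$W -
                        (params[[l]]$W - 0.3 * ref[[l]]$W))), 1e-10)
    expect_lt(max(abs(step$params[[l]]$b -
                        (params[[l]]$b - 0.3 * ref[[l]]$b))), 1e-10)
  }
})
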