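# Activations, dropout, corruption, losses, initialisation and forward
# passes.

test_that("relu zeroes negatives and is idempotent", {
  expect_equal(relu(c(-1, 0, 2)), c(0, 0, 2))
  expect_equal(relu(c(-5, -0.1)), c(0, 0))
  x <- matrix(rnorm(20), 4, 5)
  expect_equal(relu(relu(x)), relu(x))
  expect_equal(dim(relu(x)), dim(x))
})

test_that("inverted dropout is identity at rate 0 / in inference, unbiased in training", {
  x <- matrix(rnorm(50), 5, 10)
  expect_identical(apply_dropout(x, 0, "train"), x)
  expect_identical(apply_dropout(x, 0.7, "infer"), x)
  expect_error(apply_dropout(x, 1, "train"), "rate")

  ones <- rep(1, 1e5)
  out <- apply_dropout(ones, 0.5, "train", seed = 1)
  # mean of x * mask/(1-rate): sd of the mean = 1/sqrt(n) at rate 0.5
  expect_lt(abs(mean(out) - 1), 3 / sqrt(1e5))
  expect_identical(out, apply_dropout(ones, 0.5, "train", seed = 1))
})

test_that("input corruption is additive Gaussian with the requested sd", {
  x <- matrix(rnorm(100), 10, 10)
  expect_identical(corrupt_input(x, 0), x)
  expect_error(corrupt_input(x, -0.1), "sd")

  big <- matrix(0, 200, 500)
  noise <- corrupt_input(big, 0.1, seed = 2) - big
  # sd of the sample sd is about sd/sqrt(2n)
  expect_lt(abs(sd(noise) - 0.1), 3 * 0.1 / sqrt(2 * 1e5))
  expect_identical(corrupt_input(big, 0.1, seed = 2),
                   corrupt_input(big, 0.1, seed = 2))
})

test_that("softmax is symmetric, normalized and overflow-safe", {
  expect_equal(softmax(c(0, 0))[1, ], c(0.5, 0.5))
  p <- softmax(c(1000, 0))
  expect_true(all(is.finite(p)))
  expect_gt(p[1, 1], 1 - 1e-10)
  m <- softmax(matrix(rnorm(40, sd = 50), 10, 4))
  expect_equal(rowSums(m), rep(1, 10), tolerance = 1e-9)
})

test_that("cross-entropy matches hand-computed values", {
  u <- matrix(0.5, 4, 2)
  expect_equal(cross_entropy_loss(u, c(0, 1, 0, 1)), log(2))
  hot <- rbind(c(1, 0), c(0, 1))
  expect_lt(cross_entropy_loss(hot, c(0, 1)), 1e-10)
  p <- rbind(c(0.2, 0.8), c(0.4, 0.6))
  expect_equal(cross_entropy_loss(p, c(1, 0)),
               -(log(0.8) + log(0.4)) / 2, tolerance = 1e-9)
  expect_error(cross_entropy_loss(p, c(1, 2)), "0 and 1")
})

test_that("mean squared error matches an elementwise oracle", {
  expect_equal(mse_loss(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(mse_loss(rbind(c(1, 2), c(3, 6)), rbind(c(1, 2), c(3, 4))), 1)
  a <- matrix(rnorm(12), 3, 4); b <- matrix(rnorm(12), 3, 4)
  expect_equal(mse_loss(a, b), sum((a - b)^2) / 12)
  expect_gte(mse_loss(a, b), 0)
  expect_error(mse_loss(a, matrix(0, 4, 3)), "shape")
})

test_that("initialisation is seeded He-normal with the documented extras", {
  p1 <- init_params(c(10, 5, 2), seed = 4)
  expect_identical(p1, init_params(c(10, 5, 2), seed = 4))
  expect_true(all(vapply(p1, function(l) all(l$b == 0), logical(1))))
  big <- init_params(c(400, 300), seed = 1)
  expect_lt(abs(var(as.numeric(big[[1]]$W)) - 2 / 400), 0.1 * 2 / 400)

  p2 <- init_params(c(10, 5, 2), seed = 4, bias = 0.5, output_scale = 0.1)
  expect_true(all(p2[[1]]$b == 0.5))
  expect_true(all(p2[[2]]$b == 0)) # final layer biases stay 0
  expect_equal(p2[[2]]$W, p1[[2]]$W * 0.1)
})

test_that("forward passes chain shapes and are deterministic in inference", {
  p <- init_params(c(7, 6, 3, 6, 7), seed = 2)
  x <- matrix(rnorm(35), 5, 7)
  out <- mlp_forward(p, x)
  expect_equal(dim(out), c(5, 7))
  expect_identical(out, mlp_forward(p, x))
  expect_error(mlp_forward(p, matrix(0, 5, 6)), "expects")

  zero <- lapply(p, function(l) list(W = l$W * 0, b = l$b * 0))
  expect_true(all(mlp_forward(zero, x) == 0))
})
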