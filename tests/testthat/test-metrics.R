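# Accuracy, AUC, Spearman, fold assignment, cross-validation, repeats.

test_that("accuracy counts exact matches and is complement-symmetric", {
  expect_equal(accuracy(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(accuracy(c(1, 0, 1, 0), c(1, 0, 1, 1)), 0.75)
  set.seed(1)
  y <- rbinom(30, 1, 0.4); p <- rbinom(30, 1, 0.5)
  expect_equal(accuracy(p, y) + accuracy(1 - p, y), 1)
  expect_error(accuracy(c(1, 0), c(1, 0, 1)), "length")
})

test_that("AUC reproduces worked examples and degenerate cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(5, 4, 3), c(1, 1, 0)), 1)
  expect_equal(roc_auc(rep(2, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC equals brute-force pair enumeration, with ties", {
  set.seed(2)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5)) # both classes present
    s <- sample(seq(0, 1, 0.25), n, replace = TRUE) # ties likely
    expect_equal(roc_auc(s, y), ref_auc_pairs(s, y))
  }
})

test_that("AUC is invariant to strictly increasing transforms and matches pROC", {
  set.seed(3)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  expect_equal(roc_auc(s, y), roc_auc(exp(s), y))
  expect_equal(roc_auc(s, y), roc_auc(rank(s), y))
  auc_ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
  expect_equal(roc_auc(s, y), auc_ref, tolerance = 1e-12)
})

test_that("Spearman matches the d^2 formula and the sign conventions", {
  expect_equal(spearman_rho(c(3, 1, 4, 2), c(3, 1, 4, 2)), 1)
  expect_equal(spearman_rho(-c(3, 1, 4, 2), c(3, 1, 4, 2)), -1)
  expect_equal(spearman_rho(c(2, 1, 4, 3, 5), 1:5), 0.8)
  set.seed(4)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    a <- sample(n); b <- sample(n) # tie-free ranks
    expect_equal(spearman_rho(a, b),
                 1 - 6 * sum((rank(a) - rank(b))^2) / (n * (n^2 - 1)))
  }
  expect_equal(spearman_rho(exp(1:6), (1:6)^3), 1) # monotone invariance
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("stratified folds partition and preserve class ratios", {
  set.seed(5)
  y <- rep(c(0, 1), c(80, 20))
  f <- stratified_kfold(y, k = 10, seed = 1)
  expect_equal(sort(unique(f)), 1:10)
  expect_equal(as.numeric(table(f)), rep(10, 10))
  for (k in 1:10) expect_equal(sum(y[f == k]), 2) # 2 positives per fold
  expect_identical(f, stratified_kfold(y, k = 10, seed = 1))
  expect_error(stratified_kfold(1:5, k = 6), "exceed")
  expect_warning(stratified_kfold(c(rep(0, 20), 1), k = 5, seed = 1),
                 "fewer than k")
})

test_that("fold sizes balance within one sample without stratification", {
  f <- stratified_kfold(rnorm(47), k = 10, seed = 2, stratify = FALSE)
  expect_lte(diff(range(table(f))), 1)
  expect_equal(length(f), 47)
})

test_that("cross-validation matches a hand-enumerated constant predictor", {
  y <- c(0, 0, 1, 1)
  x <- matrix(rnorm(8), 4, 2)
  trainer <- function(x, y) structure(list(), class = "const1")
  scorer <- function(model, x, y) c(accuracy = mean(y == 1))
  cv <- cross_validate(trainer, x, y, scorer, k = 2, seed = 3)
  # stratified 2-fold: each fold holds one 0 and one 1
  expect_equal(unname(cv$values[, "accuracy"]), c(0.5, 0.5))
  expect_equal(unname(cv$mean[["accuracy"]]), 0.5)
  expect_equal(unname(cv$sd[["accuracy"]]), 0)
})

test_that("cross-validation never evaluates a training sample", {
  y <- rep(c(0, 1), each = 20)
  x <- matrix(seq_len(40), 40, 1)
  seen <- list()
  trainer <- function(x, y) { tr <- x[, 1]; structure(list(tr = tr),
                                                      class = "spy") }
  scorer <- function(model, x, y) {
    expect_length(intersect(model$tr, x[, 1]), 0)
    c(n = nrow(x))
  }
  cv <- cross_validate(trainer, x, y, scorer, k = 5, seed = 4)
  expect_equal(sum(cv$values[, "n"]), 40)
})

test_that("repeated experiments summarise per-repeat values", {
  out <- repeat_experiment(function(seed) c(v = seed^2), n_repeats = 3,
                           base_seed = 2)
  expect_equal(unname(out$values[, "v"]), c(4, 9, 16))
  expect_equal(unname(out$mean[["v"]]), mean(c(4, 9, 16)))
  one <- repeat_experiment(function(seed) c(v = 7), n_repeats = 1)
  expect_equal(unname(one$mean[["v"]]), 7)
  const <- repeat_experiment(function(seed) c(v = 1.5), n_repeats = 5)
  expect_equal(unname(const$sd[["v"]]), 0)
})
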