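# Renyi-DP calibration, composition and the accountant.

test_that("Gaussian-mechanism budget and noise calibration invert each other", {
  expect_equal(rdp_epsilon(sigma = 1, sensitivity = 1, alpha = 2), 1)
  expect_equal(rdp_epsilon(sigma = 2, sensitivity = 1, alpha = 4), 0.5)
  expect_equal(calibrate_sigma(epsilon = 1, sensitivity = 1, alpha = 2), 1)
  expect_equal(calibrate_sigma(epsilon = 0.1, sensitivity = 1, alpha = 2),
               sqrt(10))
  expect_equal(calibrate_sigma(epsilon = 2, sensitivity = 2, alpha = 4), 2)

  set.seed(42)
  for (i in 1:100) {
    eps <- runif(1, 0.01, 20)
    delta <- runif(1, 0.1, 5)
    alpha <- runif(1, 1.01, 10)
    sigma <- calibrate_sigma(eps, delta, alpha)
    expect_lt(abs(rdp_epsilon(sigma, delta, alpha) - eps), 1e-9)
  }
})

test_that("rdp_epsilon is monotone in its arguments", {
  sigmas <- sort(runif(20, 0.1, 10))
  eps <- vapply(sigmas, rdp_epsilon, numeric(1), sensitivity = 1.5,
                alpha = 3)
  expect_true(all(diff(eps) < 0)) # strictly decreasing in sigma
  alphas <- sort(runif(20, 1.01, 10))
  expect_true(all(diff(vapply(alphas, function(a)
    rdp_epsilon(2, 1, a), numeric(1))) > 0))
})

test_that("parameter domains are enforced", {
  expect_error(rdp_epsilon(0, 1, 2), "sigma")
  expect_error(rdp_epsilon(-1, 1, 2), "sigma")
  expect_error(rdp_epsilon(1, 1, 1), "alpha")
  expect_error(calibrate_sigma(0, 1, 2), "epsilon")
  expect_error(rdp_params(1, 0.5), "alpha")
  expect_error(rdp_params(2, -1), "epsilon")
})

test_that("composition is additive at fixed order and rejects mixed orders", {
  out <- rdp_compose(list(rdp_params(2, 0.5), rdp_params(2, 0.5)))
  expect_equal(out$alpha, 2)
  expect_equal(out$epsilon, 1)

  empty <- rdp_compose(list(), alpha = 3)
  expect_equal(empty$epsilon, 0)
  expect_equal(empty$alpha, 3)

  many <- rdp_compose(rep(list(rdp_params(2, 0.1)), 10))
  expect_lt(abs(many$epsilon - 1), 1e-12)

  expect_error(rdp_compose(list(rdp_params(2, 0.1), rdp_params(3, 0.1))),
               "alpha")
  expect_error(rdp_compose(list(), alpha = NULL), "alpha")
})

test_that("the schedule splits the budget uniformly and calibrates sigma", {
  acct <- rdp_accountant(1, alpha = 2, clip_norm = 1, planned_steps = 10)
  expect_equal(acct$per_step_epsilon, 0.1)
  expect_lt(abs(acct$sigma - sqrt(10)), 1e-12)

  one <- rdp_accountant(1, alpha = 2, clip_norm = 1, planned_steps = 1)
  expect_equal(one$sigma, 1)

  # conservation for arbitrary schedules
  for (steps in c(3, 7, 100)) {
    a <- rdp_accountant(2.5, alpha = 4, clip_norm = 0.5,
                        planned_steps = steps)
    expect_lt(abs(a$per_step_epsilon * steps - 2.5), 1e-9)
    # composing the per-step budgets recovers the total
    comp <- rdp_compose(rep(list(rdp_params(4, a$per_step_epsilon)), steps))
    expect_lt(abs(comp$epsilon - 2.5), 1e-9)
  }
  expect_error(rdp_accountant(1, 2, 1, planned_steps = 0), "planned_steps")
})

test_that("the accountant tracks spend exactly and refuses to overspend", {
  acct <- rdp_accountant(1, alpha = 2, clip_norm = 1, planned_steps = 10)
  for (k in 1:10) {
    acct <- record_step(acct)
    expect_lt(abs(privacy_spent(acct) - k / 10), 1e-9)
    expect_lte(privacy_spent(acct), acct$total_epsilon + 1e-9)
  }
  expect_lt(abs(privacy_spent(acct) - 1), 1e-9)
  expect_error(record_step(acct), "exhausted")
})

test_that("a non-private accountant carries zero noise", {
  acct <- rdp_accountant(Inf, alpha = 2, clip_norm = Inf, planned_steps = 5)
  expect_identical(acct$sigma, 0)
  expect_equal(privacy_spent(acct), 0)
  acct <- record_step(acct)
  expect_identical(privacy_spent(acct), Inf)
})
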