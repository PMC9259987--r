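# The seeded synthetic-data generator.

test_that("the expression matrix has the configured latent rank", {
  cfg <- synth_config(n_samples = 60, n_features = 30, latent_dim = 5,
                      noise_sd = 0, seed = 1)
  X <- gen_expression(cfg)$X
  expect_lte(qr(X)$rank, 5)
  expect_identical(X, gen_expression(cfg)$X)
  expect_equal(rownames(X)[1], "s0001")
  expect_equal(colnames(X)[30], "g0030")
})

test_that("per-entry variance is about latent_dim + noise_sd^2", {
  cfg <- synth_config(n_samples = 500, n_features = 200, latent_dim = 10,
                      noise_sd = 1, seed = 2)
  v <- var(as.numeric(gen_expression(cfg)$X))
  expect_lt(abs(v - 11) / 11, 0.1)
})

test_that("copy-number discretisation respects coding and quantiles", {
  cfg <- synth_config(n_samples = 2000, n_features = 20, latent_dim = 3,
                      cna_loss_quantile = 0.15, cna_gain_quantile = 0.15,
                      seed = 3)
  cna <- gen_cna(cfg)
  expect_true(all(cna %in% c(-1, 0, 1)))
  p_loss <- mean(cna == -1)
  se <- sqrt(0.15 * 0.85 / length(cna))
  expect_lt(abs(p_loss - 0.15), 3 * se + 1 / 2000) # quantile granularity
  expect_lt(abs(mean(cna == 1) - 0.15), 3 * se + 1 / 2000)

  none <- gen_cna(synth_config(n_samples = 50, n_features = 10,
                               latent_dim = 2, cna_loss_quantile = 0,
                               cna_gain_quantile = 0, seed = 1))
  expect_true(all(none == 0))
})

test_that("labels hit the configured class ratio and are seed-stable", {
  cfg <- synth_config(n_samples = 10000, n_features = 10, latent_dim = 2,
                      class_effect = 0, class_ratio = 0.8, seed = 4)
  Z <- gen_expression(cfg)$Z
  y <- gen_labels(cfg, Z)
  expect_lt(abs(mean(y) - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
  expect_identical(y, gen_labels(cfg, Z))

  # the offset also compensates a strong effect
  cfg2 <- synth_config(n_samples = 10000, n_features = 10, latent_dim = 2,
                       class_effect = 3, class_ratio = 0.8, seed = 5)
  Z2 <- gen_expression(cfg2)$Z
  y2 <- gen_labels(cfg2, Z2)
  expect_lt(abs(mean(y2) - 0.8), 0.02)
})

test_that("a large class effect makes labels separable on the first factor", {
  cfg <- synth_config(n_samples = 2000, n_features = 10, latent_dim = 2,
                      class_effect = 25, seed = 6)
  Z <- gen_expression(cfg)$Z
  y <- gen_labels(cfg, Z)
  expect_gte(roc_auc(Z[, 1], y), 0.99)
})

test_that("drug responses have the configured missingness and linear truth", {
  cfg <- synth_config(n_samples = 1000, n_features = 10, latent_dim = 3,
                      n_drugs = 4, missing_rate = 0.3, drug_noise_sd = 0,
                      seed = 7)
  expr <- gen_expression(cfg)
  resp <- gen_drug_response(cfg, expr$Z)
  expect_equal(dim(resp), c(4, 1000))
  obs <- rowSums(!is.na(resp))
  se <- 3 * sqrt(0.3 * 0.7 * 1000)
  expect_true(all(abs(obs - 700) < se))
  expect_identical(resp, gen_drug_response(cfg, expr$Z))

  # noiseless responses: a linear fit on Z ranks observed entries perfectly
  y <- resp[1, ]
  keep <- which(!is.na(y))
  fit <- lm(y[keep] ~ expr$Z[keep, ])
  expect_equal(spearman_rho(fitted(fit), y[keep]), 1)
})

test_that("a bundle is coherent and reproducible end to end", {
  cfg <- synth_config(n_samples = 80, n_features = 20, latent_dim = 3,
                      n_drugs = 2, seed = 8)
  b1 <- synth_bundle(cfg)
  b2 <- synth_bundle(cfg)
  expect_identical(b1$X, b2$X)
  expect_identical(b1$labels, b2$labels)
  expect_identical(b1$responses, b2$responses)
  expect_equal(colnames(b1$responses), rownames(b1$X))
  expect_error(synth_config(n_samples = 10, n_features = 5, latent_dim = 5),
               "latent_dim")
  expect_error(synth_config(missing_rate = 1), "missing_rate")
})
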