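# Seeded synthetic-data generator. A linear-Gaussian latent-factor model
# produces expression-like matrices, discretised copy-number matrices,
# imbalanced binary labels driven by the first latent factor, and per-drug
# responses with completely-at-random missingness — the minimal structure
# under which a low-dimensional code is provably sufficient for both
# downstream tasks, so utility is testable against a known oracle.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study conditions at desk scale: 1000 samples by 200
#' features with 10 latent factors and unit noise; an imbalanced ~80/20
#' binary label (matching a 794:197 class profile) with logistic effect 3
#' on the first factor; 10 drugs with 30% missing responses, leaving ~700
#' observed samples per drug; and 15%/15% loss/gain quantiles for the
#' copy-number discretisation. Full-study scales are reachable by
#' configuration.
#'
#' @param n_samples,n_features,latent_dim Matrix shape and latent rank
#'   (`latent_dim < n_features`).
#' @param noise_sd Sd of the additive observation noise on the expression
#'   matrix.
#' @param class_effect Logistic effect size of the first latent factor on
#'   the binary label.
#' @param class_ratio Expected positive-class fraction, in (0, 1).
#' @param n_drugs Number of drug-response rows.
#' @param drug_noise_sd Sd of the response noise.
#' @param missing_rate Probability an individual response entry is missing,
#'   in `[0, 1)`.
#' @param cna_loss_quantile,cna_gain_quantile Column-wise quantiles mapped
#'   to copy-number loss (-1) and gain (+1); each in `[0, 0.5)`.
#' @param seed Master seed; every artifact is reproducible from
#'   (config, seed).
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_samples = 1000, n_features = 200, latent_dim = 10,
                         noise_sd = 1, class_effect = 3, class_ratio = 0.8,
                         n_drugs = 10, drug_noise_sd = 1, missing_rate = 0.3,
                         cna_loss_quantile = 0.15, cna_gain_quantile = 0.15,
                         seed = 1) {
  n_samples <- check_count(n_samples, "n_samples")
  n_features <- check_count(n_features, "n_features")
  latent_dim <- check_count(latent_dim, "latent_dim")
  if (latent_dim >= n_features)
    stop("'latent_dim' must be smaller than 'n_features'", call. = FALSE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(class_effect, "class_effect")
  check_number(class_ratio, "class_ratio", lower = 0, strict_lower = TRUE)
  if (class_ratio >= 1) stop("'class_ratio' must be in (0, 1)", call. = FALSE)
  n_drugs <- check_count(n_drugs, "n_drugs")
  check_number(drug_noise_sd, "drug_noise_sd", lower = 0)
  check_number(missing_rate, "missing_rate", lower = 0)
  if (missing_rate >= 1) stop("'missing_rate' must be < 1", call. = FALSE)
  for (q in c("cna_loss_quantile", "cna_gain_quantile")) {
    v <- get(q)
    check_number(v, q, lower = 0)
    if (v >= 0.5) stop(sprintf("'%s' must be < 0.5", q), call. = FALSE)
  }
  structure(as.list(environment())[c(
    "n_samples", "n_features", "latent_dim", "noise_sd", "class_effect",
    "class_ratio", "n_drugs", "drug_noise_sd", "missing_rate",
    "cna_loss_quantile", "cna_gain_quantile", "seed")],
    class = "synth_config")
}

#' Generate a latent-factor expression matrix
#'
#' Draws latent factors `Z ~ N(0, 1)` (n x k), loadings `W ~ N(0, 1)`
#' (k x d), and returns `X = Z W + N(0, noise_sd^2)` with sample identifiers
#' `s0001...` and feature identifiers `g0001...`.
#'
#' @param config A [synth_config()].
#' @return A list with elements `X` (n x d), `Z` (n x k), `W` (k x d) and
#'   `config`.
#' @export
gen_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n <- config$n_samples; d <- config$n_features; k <- config$latent_dim
    Z <- matrix(stats::rnorm(n * k), n, k)
    W <- matrix(stats::rnorm(k * d), k, d)
    X <- Z %*% W
    if (config$noise_sd > 0)
      X <- X + matrix(stats::rnorm(n * d, sd = config$noise_sd), n, d)
    sample_ids <- sprintf("s%04d", seq_len(n))
    dimnames(X) <- list(sample_ids, sprintf("g%04d", seq_len(d)))
    rownames(Z) <- sample_ids
    list(X = X, Z = Z, W = W, config = config)
  })
}

#' Generate a discrete copy-number matrix
#'
#' Thresholds a [gen_expression()] matrix column-wise into copy-number
#' calls: the lowest `cna_loss_quantile` fraction becomes -1 (loss), the
#' highest `cna_gain_quantile` fraction +1 (gain), everything else 0
#' (diploid).
#'
#' @param config A [synth_config()].
#' @return A sample-by-feature matrix with values in `{-1, 0, 1}`.
#' @export
gen_cna <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  X <- gen_expression(config)$X
  out <- apply(X, 2L, function(col) {
    lo <- stats::quantile(col, config$cna_loss_quantile, names = FALSE)
    hi <- stats::quantile(col, 1 - config$cna_gain_quantile, names = FALSE)
    as.numeric((col > hi) - (col < lo))
  })
  dimnames(out) <- dimnames(X)
  out
}

#' Generate imbalanced binary labels from the latent factors
#'
#' Labels are Bernoulli draws with
#' `p(y = 1 | z) = plogis(class_effect * z_1 + offset)`, where the offset
#' is solved (by integrating over the standard-normal factor) so that the
#' expected positive fraction equals `class_ratio`.
#'
#' @param config A [synth_config()].
#' @param Z Latent matrix from the same bundle ([gen_expression()]).
#' @return An integer 0/1 vector of length `n_samples`.
#' @export
gen_labels <- function(config, Z) {
  stopifnot(inherits(config, "synth_config"))
  Z <- as_numeric_matrix(Z, "Z")
  if (nrow(Z) != config$n_samples)
    stop("'Z' does not match the configured sample count", call. = FALSE)
  offset <- solve_label_offset(config$class_effect, config$class_ratio)
  p <- stats::plogis(config$class_effect * Z[, 1L] + offset)
  with_seed(config$seed + 1L,
            as.integer(stats::runif(nrow(Z)) < p))
}

# Offset b with E_{z ~ N(0,1)}[plogis(a z + b)] = ratio.
solve_label_offset <- function(effect, ratio) {
  if (effect == 0) return(stats::qlogis(ratio))
  f <- function(b) {
    stats::integrate(function(z) stats::plogis(effect * z + b) *
                       stats::dnorm(z),
                     lower = -12, upper = 12)$value - ratio
  }
  lim <- abs(effect) * 12 + 20
  stats::uniroot(f, lower = -lim, upper = lim, tol = 1e-10)$root
}

#' Generate a drugs-by-samples response table with missingness
#'
#' For each drug `j`, responses are `Z beta_j + N(0, drug_noise_sd^2)` with
#' `beta_j ~ N(0, 1)`; each entry is then masked missing independently with
#' probability `missing_rate` (`NA`), emulating an IC50 panel in which not
#' every drug is tested in every sample.
#'
#' @param config A [synth_config()].
#' @param Z Latent matrix from the same bundle.
#' @return A numeric matrix, drugs in rows (named `drug001...`), samples in
#'   columns, with `NA` for missing entries.
#' @export
gen_drug_response <- function(config, Z) {
  stopifnot(inherits(config, "synth_config"))
  Z <- as_numeric_matrix(Z, "Z")
  if (nrow(Z) != config$n_samples)
    stop("'Z' does not match the configured sample count", call. = FALSE)
  with_seed(config$seed + 2L, {
    k <- config$latent_dim; m <- config$n_drugs; n <- nrow(Z)
    beta <- matrix(stats::rnorm(k * m), k, m)
    Y <- t(Z %*% beta)
    if (config$drug_noise_sd > 0)
      Y <- Y + matrix(stats::rnorm(m * n, sd = config$drug_noise_sd), m, n)
    if (config$missing_rate > 0)
      Y[matrix(stats::runif(m * n) < config$missing_rate, m, n)] <- NA
    dimnames(Y) <- list(sprintf("drug%03d", seq_len(m)),
                        rownames(Z) %||% sprintf("s%04d", seq_len(n)))
    Y
  })
}

#' Generate a complete synthetic bundle
#'
#' Convenience wrapper drawing the expression matrix, labels and drug
#' responses of one coherent dataset from a single configuration.
#'
#' @param config A [synth_config()].
#' @return A list of class `"synth_bundle"` with `X`, `Z`, `W`, `labels`,
#'   `responses` and `config`.
#' @export
synth_bundle <- function(config = synth_config()) {
  expr <- gen_expression(config)
  structure(
    list(X = expr$X, Z = expr$Z, W = expr$W,
         labels = gen_labels(config, expr$Z),
         responses = gen_drug_response(config, expr$Z),
         config = config),
    class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic bundle: %d samples x %d features (latent rank %d)\n",
              cfg$n_samples, cfg$n_features, cfg$latent_dim))
  cat(sprintf("  labels: %d positive / %d negative\n",
              sum(x$labels == 1L), sum(x$labels == 0L)))
  cat(sprintf("  responses: %d drugs, %.1f%% missing\n",
              nrow(x$responses), 100 * mean(is.na(x$responses))))
  invisible(x)
}
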