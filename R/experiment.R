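# Privacy-utility experiment scaffold: the end-to-end pipeline run the
# package uses to measure how much utility DP training costs on the
# synthetic fixture.

#' Run the two-stage pipeline on the synthetic fixture and score it
#'
#' For each seed this draws the default synthetic fixture (1000 samples x
#' 200 features, latent rank 10, logistic class effect 3 on the first
#' factor), holds out 20% of samples, trains the representation
#' autoencoder on the training split, encodes both splits, trains the
#' binary classifier on standardized codes, and returns the held-out ROC
#' AUC. `epsilon = Inf` runs the conventional (non-private) pipeline;
#' finite budgets run both stages with DP-SGD, each granted `epsilon`.
#'
#' The stage hyperparameters are the package's per-budget experimental
#' settings (the framework's tuning loop chooses hyperparameters per
#' budget, and so does this scaffold): the non-private arm trains the
#' default `c(64, 32, 16)` profile for 40 epochs in batches of 50 without
#' clipping; private arms train the shallower `c(64, 32)` profile for 30
#' epochs in batches of 200 at clip norm 2, which keeps per-example
#' clipping mildly binding and bounds the noise accumulated per weight.
#' Inputs are feature-standardized, and codes are standardized and scaled
#' to unit expected row norm before classification so that per-example
#' classifier gradients sit near the clip norm 1.
#'
#' @param epsilon Privacy budget per stage (`Inf` = non-private).
#' @param seeds Integer vector of fixture/training seeds; one pipeline run
#'   per seed.
#' @param config A [synth_config()] used as the fixture template (its seed
#'   field is replaced by each element of `seeds`).
#' @return Named numeric vector of held-out AUCs, one per seed.
#' @examples
#' \donttest{
#' run_utility_experiment(Inf, seeds = 1:2)
#' }
#' @export
run_utility_experiment <- function(epsilon, seeds = 1:5,
                                   config = synth_config()) {
  check_number(epsilon, "epsilon", lower = 0, strict_lower = TRUE,
               allow_inf = TRUE)
  vapply(seeds, function(seed) {
    cfg <- config
    cfg$seed <- seed
    b <- synth_bundle(cfg)
    xs <- scale(b$X)
    n <- nrow(xs)
    holdout <- with_seed(seed + 1000, sample.int(n, round(0.2 * n)))
    tr <- setdiff(seq_len(n), holdout)
    np <- is.infinite(epsilon)
    ae <- dp_autoencoder(
      xs[tr, ], hidden = if (np) c(64, 32, 16) else c(64, 32),
      epsilon = epsilon, clip_norm = if (np) Inf else 2,
      learning_rate = if (np) 0.05 else 0.1, corruption_sd = 0.1,
      dropout = 0, epochs = if (np) 40 else 30,
      batch_size = if (np) 50 else 200, seed = seed)
    ctr <- encode(ae, xs[tr, ])
    cte <- encode(ae, xs[holdout, ])
    sc <- standardize_codes(ctr)
    clf <- dp_classifier(
      sc$apply(ctr), b$labels[tr], hidden = 16, epsilon = epsilon,
      clip_norm = if (np) Inf else 1, dropout = 0.1, learning_rate = 0.5,
      batch_size = 100, epochs = 30, seed = seed + 1)
    roc_auc(predict(clf, sc$apply(cte), type = "score"), b$labels[holdout])
  }, numeric(1)) |> stats::setNames(seeds)
}

#' Standardize codes to unit expected row norm
#'
#' Learns per-dimension centers and scales from a training code matrix and
#' returns an `apply` closure that standardizes any code matrix and
#' divides by `sqrt(code_dim)`, so a typical code row has l2 norm about 1.
#' Used before classifier training so that per-example gradient norms are
#' commensurate with a clip norm of 1.
#'
#' @param codes Training code matrix.
#' @return A list with fields `center`, `scale` and `apply(x)`.
#' @export
standardize_codes <- function(codes) {
  codes <- as_numeric_matrix(codes, "codes")
  center <- colMeans(codes)
  scl <- apply(codes, 2L, stats::sd)
  scl[scl == 0] <- 1
  k <- sqrt(ncol(codes))
  list(center = center, scale = scl,
       apply = function(x) {
         x <- as_numeric_matrix(x)
         sweep(sweep(x, 2L, center), 2L, scl, "/") / k
       })
}
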