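# Renyi differential privacy: Gaussian-mechanism calibration, additive
# composition at fixed order, and the per-step budget accountant.

#' Renyi-DP guarantee of the Gaussian mechanism
#'
#' For a query with l2 sensitivity \eqn{\Delta_2} answered with additive
#' Gaussian noise of standard deviation \eqn{\sigma}, the mechanism satisfies
#' \eqn{(\alpha, \epsilon)}-Renyi differential privacy with
#' \eqn{\epsilon = \alpha \Delta_2^2 / (2 \sigma^2)}.
#'
#' @param sigma Noise standard deviation, strictly positive.
#' @param sensitivity l2 sensitivity \eqn{\Delta_2} of the query,
#'   non-negative. In DP-SGD this is the clipping norm `C`.
#' @param alpha Renyi order, strictly greater than 1.
#' @return The RDP budget \eqn{\epsilon} at order `alpha` (a single number).
#' @seealso [calibrate_sigma()] for the inverse map, [rdp_accountant()] for
#'   budget tracking over many steps.
#' @examples
#' rdp_epsilon(sigma = 1, sensitivity = 1, alpha = 2) # 1
#' @export
rdp_epsilon <- function(sigma, sensitivity, alpha) {
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  check_number(sensitivity, "sensitivity", lower = 0)
  check_number(alpha, "alpha", lower = 1, strict_lower = TRUE)
  alpha * sensitivity^2 / (2 * sigma^2)
}

#' Noise scale achieving a target Renyi-DP budget
#'
#' Inverts the Gaussian-mechanism bound: the noise standard deviation
#' \eqn{\sigma = \sqrt{\alpha \Delta_2^2 / (2 \epsilon)}} makes a query of l2
#' sensitivity \eqn{\Delta_2} satisfy \eqn{(\alpha, \epsilon)}-RDP.
#'
#' @param epsilon Target RDP budget, strictly positive. `Inf` is accepted and
#'   returns `sigma = 0` (a non-private, noise-free mechanism).
#' @inheritParams rdp_epsilon
#' @return The calibrated noise standard deviation.
#' @examples
#' calibrate_sigma(epsilon = 1, sensitivity = 1, alpha = 2) # 1
#' calibrate_sigma(epsilon = 0.1, sensitivity = 1, alpha = 2) # sqrt(10)
#' @export
calibrate_sigma <- function(epsilon, sensitivity, alpha) {
  check_number(epsilon, "epsilon", lower = 0, strict_lower = TRUE,
               allow_inf = TRUE)
  check_number(sensitivity, "sensitivity", lower = 0, strict_lower = TRUE)
  check_number(alpha, "alpha", lower = 1, strict_lower = TRUE)
  if (is.infinite(epsilon)) return(0)
  sqrt(alpha * sensitivity^2 / (2 * epsilon))
}

#' An (alpha, epsilon) Renyi-DP budget
#'
#' @param alpha Renyi order, > 1.
#' @param epsilon Budget at order `alpha`, >= 0 (may be `Inf` for a
#'   non-private mechanism).
#' @return An object of class `"rdp_params"`.
#' @export
rdp_params <- function(alpha, epsilon) {
  check_number(alpha, "alpha", lower = 1, strict_lower = TRUE)
  check_number(epsilon, "epsilon", lower = 0, allow_inf = TRUE)
  structure(list(alpha = alpha, epsilon = epsilon), class = "rdp_params")
}

#' @export
print.rdp_params <- function(x, ...) {
  cat(sprintf("(alpha = %g, epsilon = %g)-RDP\n", x$alpha, x$epsilon))
  invisible(x)
}

#' Additive composition of Renyi-DP budgets
#'
#' Mechanisms satisfying \eqn{(\alpha, \epsilon_1)}- and
#' \eqn{(\alpha, \epsilon_2)}-RDP jointly satisfy
#' \eqn{(\alpha, \epsilon_1 + \epsilon_2)}-RDP. Composition is only defined at
#' a shared order; mixed orders are rejected.
#'
#' @param budgets A list of [rdp_params()] objects sharing one `alpha`.
#' @param alpha Order used for the empty composition (ignored when `budgets`
#'   is non-empty).
#' @return An [rdp_params()] with the summed budget.
#' @examples
#' rdp_compose(list(rdp_params(2, 0.5), rdp_params(2, 0.5))) # epsilon 1
#' @export
rdp_compose <- function(budgets, alpha = NULL) {
  if (!is.list(budgets))
    stop("'budgets' must be a list of rdp_params objects", call. = FALSE)
  if (length(budgets) == 0L) {
    if (is.null(alpha))
      stop("empty composition needs an explicit 'alpha'", call. = FALSE)
    return(rdp_params(alpha, 0))
  }
  ok <- vapply(budgets, inherits, logical(1), what = "rdp_params")
  if (!all(ok))
    stop("'budgets' must be a list of rdp_params objects", call. = FALSE)
  alphas <- vapply(budgets, `[[`, numeric(1), "alpha")
  if (any(alphas != alphas[1L]))
    stop("cannot compose RDP budgets across different orders alpha",
         call. = FALSE)
  rdp_params(alphas[1L], sum(vapply(budgets, `[[`, numeric(1), "epsilon")))
}

#' Renyi-DP accountant with a uniform per-step schedule
#'
#' Plans a training run of `planned_steps` noisy gradient updates so that
#' their composition spends exactly `total_epsilon`: each step is granted
#' `total_epsilon / planned_steps` and its Gaussian noise scale is calibrated
#' for sensitivity `clip_norm` at that per-step budget. [record_step()]
#' advances the ledger and refuses to step past the plan, so the published
#' model can never exceed its privacy claim.
#'
#' @param total_epsilon Total RDP budget for the run, > 0; `Inf` plans a
#'   non-private run (noise scale 0).
#' @param alpha Renyi order, > 1. The value is never fixed by the framework;
#'   2 is the default order used throughout.
#' @param clip_norm Per-example l2 clipping norm `C`, i.e. the sensitivity of
#'   each summed-gradient query; > 0, `Inf` allowed for non-private runs.
#' @param planned_steps Number of gradient updates the schedule must cover.
#' @return An object of class `"rdp_accountant"`: a list with fields `alpha`,
#'   `total_epsilon`, `per_step_epsilon`, `planned_steps`, `steps_taken`,
#'   `sigma` (absolute noise sd per step) and `clip_norm`.
#' @examples
#' acct <- rdp_accountant(1, alpha = 2, clip_norm = 1, planned_steps = 10)
#' acct$sigma # sqrt(10)
#' @export
rdp_accountant <- function(total_epsilon, alpha = 2, clip_norm = 1,
                           planned_steps) {
  check_number(total_epsilon, "total_epsilon", lower = 0, strict_lower = TRUE,
               allow_inf = TRUE)
  check_number(alpha, "alpha", lower = 1, strict_lower = TRUE)
  check_number(clip_norm, "clip_norm", lower = 0, strict_lower = TRUE,
               allow_inf = TRUE)
  planned_steps <- check_count(planned_steps, "planned_steps", lower = 1L)
  per_step <- total_epsilon / planned_steps
  sigma <- if (is.finite(total_epsilon)) {
    if (!is.finite(clip_norm))
      stop("a finite 'total_epsilon' requires a finite 'clip_norm'",
           call. = FALSE)
    calibrate_sigma(per_step, clip_norm, alpha)
  } else 0
  structure(
    list(alpha = alpha, total_epsilon = total_epsilon,
         per_step_epsilon = per_step, planned_steps = planned_steps,
         steps_taken = 0L, sigma = sigma, clip_norm = clip_norm),
    class = "rdp_accountant")
}

#' Charge one noisy step to the accountant
#'
#' @param state An [rdp_accountant()].
#' @return The updated accountant. Attempting to step beyond
#'   `planned_steps` raises a budget-exhausted error: overspending the
#'   declared budget is never allowed.
#' @export
record_step <- function(state) {
  stopifnot(inherits(state, "rdp_accountant"))
  if (state$steps_taken >= state$planned_steps)
    stop(sprintf(
      "privacy budget exhausted: %d planned steps already taken (epsilon = %g spent)",
      state$planned_steps, privacy_spent(state)), call. = FALSE)
  state$steps_taken <- state$steps_taken + 1L
  state
}

#' Privacy budget spent so far
#'
#' @param state An [rdp_accountant()], or a fitted `dpnet` model whose
#'   accountant should be inspected.
#' @return `steps_taken * per_step_epsilon`, never exceeding `total_epsilon`.
#' @export
privacy_spent <- function(state) {
  if (!inherits(state, "rdp_accountant") && !is.null(state$privacy))
    state <- state$privacy
  stopifnot(inherits(state, "rdp_accountant"))
  if (!is.finite(state$per_step_epsilon))
    return(if (state$steps_taken > 0L) Inf else 0)
  state$steps_taken * state$per_step_epsilon
}

# Plain-list privacy record embedded in bundle manifests.
privacy_record <- function(state) {
  stopifnot(inherits(state, "rdp_accountant"))
  list(alpha = state$alpha,
       total_epsilon = state$total_epsilon,
       per_step_epsilon = state$per_step_epsilon,
       planned_steps = state$planned_steps,
       steps_taken = state$steps_taken,
       spent_epsilon = privacy_spent(state),
       sigma = state$sigma,
       clip_norm = state$clip_norm)
}

#' @export
print.rdp_accountant <- function(x, ...) {
  if (is.finite(x$total_epsilon)) {
    cat(sprintf("RDP accountant (alpha = %g)\n", x$alpha))
    cat(sprintf("  budget: %g total, %g per step over %d planned steps\n",
                x$total_epsilon, x$per_step_epsilon, x$planned_steps))
    cat(sprintf("  spent:  %g (%d steps taken)\n",
                privacy_spent(x), x$steps_taken))
    cat(sprintf("  noise:  sigma = %g at clip norm C = %g\n",
                x$sigma, x$clip_norm))
  } else {
    cat(sprintf("RDP accountant: non-private run (epsilon = Inf, sigma = 0), %d/%d steps\n",
                x$steps_taken, x$planned_steps))
  }
  invisible(x)
}
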