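#' ABC rejection sampler
#'
#' The baseline likelihood-free sampler: draw parameters from the prior,
#' simulate, accept when the distance to the observed data is within
#' tolerance. With a fixed number of trials the acceptance fraction
#' `n_accepted / n_trials` estimates the ABC marginal likelihood, which
#' makes the sampler directly comparable with [run_pa()].
#'
#' Simulation is carried out in internal batches; results for a fixed seed
#' are identical regardless of the batch size because all prior draws are
#' made before any simulation.
#'
#' @param model Model object for [simulate_values()].
#' @param prior A [log_uniform_prior()].
#' @param obs Observed [time_series()].
#' @param eps Acceptance tolerance (`>= 0`).
#' @param n_trials Number of prior draws.
#' @param seed Optional integer seed.
#' @param batch_size Internal simulation batch size.
#' @return An object of class `rejection_result`: accepted `particles`
#'   (matrix) and their `distances`, `ml_estimate`, `n_accepted`,
#'   `n_trials`, `eps` and `seed`. Zero acceptances is a valid outcome
#'   with `ml_estimate = 0`.
#' @examples
#' toy <- function_model(
#'   function(theta, times) matrix(theta[, 1L], nrow(theta), length(times)),
#'   parameter_names = "theta")
#' run_rejection(toy, log_uniform_prior(0.1, 10, "theta"),
#'               time_series(1, 0.5), eps = 0.01, n_trials = 5000, seed = 1)
#' @export
run_rejection <- function(model, prior, obs, eps, n_trials, seed = NULL,
                          batch_size = 20000L) {
  stopifnot(inherits(prior, "log_uniform_prior"),
            inherits(obs, "time_series"))
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  if (is.na(eps) || eps < 0) stop("`eps` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  theta <- sample_prior(prior, n_trials)
  d <- numeric(n_trials)
  for (start in seq(1L, n_trials, by = batch_size)) {
    rows <- start:min(start + batch_size - 1L, n_trials)
    sim <- simulate_values(model, theta[rows, , drop = FALSE], obs$time)
    d[rows] <- sse_rows(obs$value, sim)
  }
  keep <- d <= eps
  n_acc <- sum(keep)
  structure(list(particles = theta[keep, , drop = FALSE],
                 distances = d[keep],
                 ml_estimate = n_acc / n_trials,
                 n_accepted = as.integer(n_acc),
                 n_trials = as.integer(n_trials),
                 eps = eps,
                 seed = seed,
                 model_name = model$name),
            class = "rejection_result")
}

#' @export
print.rejection_result <- function(x, ...) {
  cat("<rejection_result>", x$model_name %||% "", "\n")
  cat(sprintf("  eps = %g, accepted %d of %d trials\n", x$eps,
              x$n_accepted, x$n_trials))
  cat(sprintf("  ABC marginal likelihood: %.6g\n", x$ml_estimate))
  invisible(x)
}
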