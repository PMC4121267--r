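#' Annealing schedule of ABC tolerances
#'
#' The strictly decreasing tolerance sequence `eps_0 > eps_1 > ... > eps_N`
#' defining the intermediate distributions (prior restricted to the
#' acceptance region at each tolerance). The first entry is the tolerance
#' of the initial distribution and is normally `Inf`, i.e. the prior.
#'
#' @param tolerances Numeric vector, strictly decreasing, all `>= 0`; the
#'   first entry may be `Inf`.
#' @return An object of class `annealing_schedule`.
#' @examples
#' annealing_schedule(c(Inf, 1, 0.5, 0.25, 0.2, 0.15))
#' @export
annealing_schedule <- function(tolerances) {
  tolerances <- as.numeric(tolerances)
  if (length(tolerances) < 1L || anyNA(tolerances)) {
    stop("`tolerances` must be a nonempty numeric vector", call. = FALSE)
  }
  if (any(tolerances < 0)) {
    stop("tolerances must be >= 0", call. = FALSE)
  }
  if (length(tolerances) > 1L && any(diff(tolerances) >= 0)) {
    stop("tolerances must be strictly decreasing", call. = FALSE)
  }
  structure(list(tolerances = tolerances), class = "annealing_schedule")
}

#' @export
print.annealing_schedule <- function(x, ...) {
  cat("<annealing_schedule> (",
      paste(format(x$tolerances), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' The three tolerance schedules of the FFL study
#'
#' `AS1 = (Inf, 2, 1, 0.75, 0.5, 0.25)`,
#' `AS2 = (Inf, 1, 0.5, 0.25, 0.2, 0.15)` (the default schedule) and
#' `AS3 = (Inf, 1, 0.5, 0.25, 0.15, 0.11)`.
#' @return Named list of three [annealing_schedule()] objects.
#' @export
ffl_schedules <- function() {
  list(AS1 = annealing_schedule(c(Inf, 2, 1, 0.75, 0.5, 0.25)),
       AS2 = annealing_schedule(c(Inf, 1, 0.5, 0.25, 0.2, 0.15)),
       AS3 = annealing_schedule(c(Inf, 1, 0.5, 0.25, 0.15, 0.11)))
}

#' Weighted particle ensemble
#'
#' @param theta Numeric matrix, one particle per row.
#' @param distances Cached distances to the observed data, one per particle
#'   (`Inf` for diverged simulations).
#' @param weights Normalized weights (default uniform `1/K`).
#' @return An object of class `particle_ensemble`.
#' @export
particle_ensemble <- function(theta, distances,
                              weights = rep(1 / nrow(theta), nrow(theta))) {
  if (is.null(dim(theta))) theta <- matrix(theta, ncol = 1L)
  K <- nrow(theta)
  if (length(distances) != K || length(weights) != K) {
    stop("`distances` and `weights` must have one entry per particle",
         call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  s <- sum(weights)
  if (s > 0 && abs(s - 1) > 1e-8) weights <- weights / s
  structure(list(theta = theta, distances = distances, weights = weights,
                 K = K),
            class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf("<particle_ensemble> K = %d, %d nonzero-weight, ESS = %.1f\n",
              x$K, sum(x$weights > 0), ess(x$weights)))
  invisible(x)
}

#' Effective sample size of a weight vector
#'
#' `ESS = 1 / sum(w^2)` for normalized weights; it measures weight
#' degeneracy and equals the number of surviving particles when the weights
#' come from the 0/1 indicator kernel.
#'
#' @param weights Normalized nonnegative weights.
#' @return Value in `[1, K]`; 0 signals an extinct (all-zero) ensemble.
#' @examples
#' ess(rep(0.25, 4)) # 4
#' ess(c(0.5, 0.3, 0.2)) # 1/0.38
#' @export
ess <- function(weights) {
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  s2 <- sum(weights^2)
  if (s2 == 0) return(0)
  1 / s2
}

#' Reweight an ensemble at a tighter tolerance
#'
#' With the indicator kernel and nested acceptance regions the incremental
#' weight of a particle is just `indicator(d, eps)`, so survivors keep a
#' common (renormalized) weight and the rest drop to zero.
#'
#' @param ensemble A [particle_ensemble()] with cached distances.
#' @param eps New tolerance (no larger than the previous one).
#' @return The reweighted [particle_ensemble()].
#' @seealso [run_pa()]
#' @export
update_weights <- function(ensemble, eps) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  w <- ensemble$weights * indicator(ensemble$distances, eps)
  total <- sum(w)
  if (total == 0) {
    stop(extinction_condition("all particle weights are zero at eps = ",
                              eps))
  }
  particle_ensemble(ensemble$theta, ensemble$distances, w / total)
}

extinction_condition <- function(...) {
  structure(class = c("abcpa_extinction", "error", "condition"),
            list(message = paste0(...), call = NULL))
}

#' Multinomial resampling
#'
#' Draws K particles with replacement proportionally to the weights,
#' resets all weights to `1/K` and reports `k_resample`, the number of
#' nonzero-weight particles immediately before resampling (the survival
#' count that feeds the marginal-likelihood estimate).
#'
#' @param ensemble A [particle_ensemble()] with at least one nonzero
#'   weight.
#' @return List with the resampled `ensemble` and the integer `k_resample`.
#' @export
resample <- function(ensemble) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  if (all(ensemble$weights == 0)) {
    stop(extinction_condition("cannot resample an extinct ensemble"))
  }
  K <- ensemble$K
  k_resample <- sum(ensemble$weights > 0)
  pick <- sample.int(K, K, replace = TRUE, prob = ensemble$weights)
  list(ensemble = particle_ensemble(ensemble$theta[pick, , drop = FALSE],
                                    ensemble$distances[pick],
                                    rep(1 / K, K)),
       k_resample = as.integer(k_resample))
}

#' Population annealing in the ABC framework
#'
#' Evolves K weighted particles from the prior (tolerance `eps_0`,
#' normally `Inf`) to the ABC posterior at the final tolerance. At each
#' level `n = 1..N`: weights are updated by the indicator at `eps_n`; every
#' nonzero-weight particle is rejuvenated by `mcmc_steps` ABC-MCMC moves
#' whose stationary distribution is the current intermediate distribution;
#' then, if the effective sample size has fallen below `ess_threshold`,
#' the survivor count `k_resample` is recorded and the ensemble is
#' multinomially resampled. The product of survival fractions
#' `prod(k_resample / K) * (final survivors / K)` estimates the ABC
#' marginal likelihood, the prior-predictive probability that simulated
#' data fall within the final tolerance of the observed data.
#'
#' If every particle dies at some level the run is flagged extinct and
#' returns `ml_estimate = 0` with the last viable ensemble (no error), so
#' Bayes-factor callers can handle the degenerate case.
#'
#' @param model Model object for [simulate_values()].
#' @param prior A [log_uniform_prior()].
#' @param obs Observed [time_series()].
#' @param schedule An [annealing_schedule()].
#' @param K Number of particles.
#' @param mcmc_steps ABC-MCMC moves per particle per level (default 7, the
#'   number of free FFL parameters).
#' @param ess_threshold Resampling trigger (default `K/2`).
#' @param kernel A [proposal_kernel()].
#' @param seed Optional integer seed; the run is deterministic given it.
#' @param verbose Log per-level survivor counts, ESS and resampling events.
#' @return An object of class `pa_result`: the final `ensemble`,
#'   `ml_estimate`, `resample_log` (data frame of level and `k_resample`),
#'   `ess_trace`, `extinct` flag, `schedule` and `seed`.
#' @examples
#' toy <- function_model(
#'   function(theta, times) matrix(theta[, 1L], nrow(theta), length(times)),
#'   parameter_names = "theta")
#' pr <- log_uniform_prior(0.1, 10, "theta")
#' fit <- run_pa(toy, pr, time_series(1, 0.5),
#'               annealing_schedule(c(Inf, 1, 0.1, 0.01)),
#'               K = 2000, mcmc_steps = 2, seed = 1)
#' fit$ml_estimate # ~ log10(0.6/0.4)/2 = 0.088
#' @export
run_pa <- function(model, prior, obs, schedule, K, mcmc_steps = 7L,
                   ess_threshold = K / 2, kernel = proposal_kernel(),
                   seed = NULL, verbose = FALSE) {
  stopifnot(inherits(prior, "log_uniform_prior"),
            inherits(obs, "time_series"),
            inherits(schedule, "annealing_schedule"))
  if (K < 2) stop("`K` must be at least 2", call. = FALSE)
  if (mcmc_steps < 0) stop("`mcmc_steps` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  eps_seq <- schedule$tolerances
  theta <- sample_prior(prior, K)
  sim <- simulate_values(model, theta, obs$time)
  d <- sse_rows(obs$value, sim)
  w <- rep(1 / K, K)

  ml_factor <- 1
  resample_log <- list()
  ess_trace <- numeric(0)
  extinct <- FALSE

  levels <- if (length(eps_seq) > 1L) seq(2L, length(eps_seq)) else integer(0)
  for (n in levels) {
    eps_n <- eps_seq[n]
    alive <- d <= eps_n & w > 0
    if (!any(alive)) {
      extinct <- TRUE
      if (verbose) message(sprintf("level %d (eps = %g): extinction",
                                   n - 1L, eps_n))
      break
    }
    w <- w * as.numeric(alive)
    w <- w / sum(w)

    if (mcmc_steps > 0L) {
      moved <- mcmc_sweep(theta, d, which(w > 0), eps_n, prior, kernel,
                          model, obs$time, obs$value, mcmc_steps)
      theta <- moved$theta
      d <- moved$d
    }

    e <- ess(w)
    ess_trace <- c(ess_trace, e)
    if (verbose) {
      message(sprintf("level %d (eps = %g): survivors = %d, ESS = %.1f",
                      n - 1L, eps_n, sum(w > 0), e))
    }
    if (e < ess_threshold) {
      k_res <- sum(w > 0)
      ml_factor <- ml_factor * k_res / K
      resample_log[[length(resample_log) + 1L]] <-
        data.frame(level = n - 1L, k_resample = as.integer(k_res))
      pick <- sample.int(K, K, replace = TRUE, prob = w)
      theta <- theta[pick, , drop = FALSE]
      d <- d[pick]
      w <- rep(1 / K, K)
      if (verbose) message(sprintf("  resampled (k_resample = %d)", k_res))
    }
  }

  ml <- if (extinct) 0 else ml_factor * sum(w > 0) / K
  resample_log <- if (length(resample_log)) {
    do.call(rbind, resample_log)
  } else {
    data.frame(level = integer(0), k_resample = integer(0))
  }
  colnames(theta) <- prior$names
  structure(list(ensemble = particle_ensemble(theta, d, w),
                 ml_estimate = ml,
                 resample_log = resample_log,
                 ess_trace = ess_trace,
                 extinct = extinct,
                 schedule = schedule,
                 K = as.integer(K),
                 mcmc_steps = as.integer(mcmc_steps),
                 ess_threshold = ess_threshold,
                 seed = seed,
                 model_name = model$name),
            class = "pa_result")
}

#' @export
print.pa_result <- function(x, ...) {
  cat("<pa_result>", x$model_name %||% "", "\n")
  cat("  schedule: (", paste(format(x$schedule$tolerances), collapse = ", "),
      ")\n", sep = "")
  cat(sprintf("  K = %d, mcmc_steps = %d%s\n", x$K, x$mcmc_steps,
              if (x$extinct) " [EXTINCT]" else ""))
  cat(sprintf("  ABC marginal likelihood: %.6g\n", x$ml_estimate))
  if (nrow(x$resample_log)) {
    cat("  resampling events (level: k_resample): ",
        paste(sprintf("%d: %d", x$resample_log$level,
                      x$resample_log$k_resample), collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
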