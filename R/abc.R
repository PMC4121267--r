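#' Simulate model output at observation times for a batch of parameters
#'
#' The single entry point the samplers use to turn parameter vectors into
#' simulated data. Methods exist for [ffl_model()] (compiled RK4) and for
#' [function_model()] (arbitrary deterministic maps, used for toy problems
#' and oracles).
#'
#' @param model A model object.
#' @param theta Numeric matrix, one parameter vector per row (a bare vector
#'   is taken as one row).
#' @param times Observation times.
#' @param ... Method-specific arguments.
#' @return Numeric matrix, `nrow(theta)` rows by `length(times)` columns;
#'   rows of a divergent simulation are `NA`.
#' @export
simulate_values <- function(model, theta, times, ...) {
  UseMethod("simulate_values")
}

#' @export
simulate_values.ffl_model <- function(model, theta, times, ...) {
  ffl_observe_batch(model, theta, times)
}

#' Wrap a deterministic function as a model
#'
#' @param fun Function `fun(theta, times)` mapping a parameter matrix (one
#'   row per parameter vector) to a matrix of simulated values.
#' @param parameter_names Character vector naming the parameters.
#' @param name Optional model name.
#' @return An object of class `function_model`.
#' @examples
#' # a model whose output at every time is the parameter itself
#' identity_model <- function_model(
#'   function(theta, times) matrix(theta[, 1L], nrow(theta), length(times)),
#'   parameter_names = "theta")
#' @export
function_model <- function(fun, parameter_names, name = "function_model") {
  stopifnot(is.function(fun), is.character(parameter_names))
  structure(list(fun = fun, parameter_names = parameter_names, name = name),
            class = c("function_model", "abc_model"))
}

#' @export
simulate_values.function_model <- function(model, theta, times, ...) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1L)
  out <- model$fun(theta, times)
  matrix(out, nrow(theta), length(times))
}

#' Log-uniform prior over positive parameters
#'
#' Each parameter is independently uniform on the common (base-10)
#' logarithmic scale between its bounds, the standard prior for kinetic
#' rates spanning orders of magnitude.
#'
#' @param lower,upper Positive numeric vectors of per-parameter bounds on
#'   the linear scale, `0 < lower < upper`.
#' @param names Optional parameter names.
#' @return An object of class `log_uniform_prior`.
#' @examples
#' ffl_default_prior()
#' @export
log_uniform_prior <- function(lower, upper, names = NULL) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper)) {
    stop("`lower` and `upper` must have the same length", call. = FALSE)
  }
  if (any(lower <= 0) || any(lower >= upper)) {
    stop("prior bounds require 0 < lower < upper", call. = FALSE)
  }
  if (is.null(names)) names <- paste0("theta_", seq_along(lower))
  structure(list(lower = lower, upper = upper, names = names,
                 log_lower = log10(lower), log_upper = log10(upper)),
            class = "log_uniform_prior")
}

#' @export
print.log_uniform_prior <- function(x, ...) {
  cat("<log_uniform_prior>\n")
  print(data.frame(parameter = x$names, lower = x$lower, upper = x$upper))
  invisible(x)
}

#' Default prior of the FFL study
#'
#' Bounds are one decade below and above each answer value:
#' rates on `[0.1, 10]`, `K_XY`/`K_XZ` on `[0.01, 1]`, `K_YZ` on
#' `[0.05, 5]`, each log10-uniform.
#' @return A [log_uniform_prior()] over the 7 free FFL parameters.
#' @export
ffl_default_prior <- function() {
  ans <- ffl_answer_theta()
  log_uniform_prior(ans / 10, ans * 10, names = names(ans))
}

#' Draw parameter vectors from a log-uniform prior
#'
#' @param prior A [log_uniform_prior()].
#' @param n Number of draws.
#' @return Numeric matrix `n` by `length(prior$lower)` with named columns.
#' @export
sample_prior <- function(prior, n = 1L) {
  stopifnot(inherits(prior, "log_uniform_prior"))
  p <- length(prior$lower)
  lg <- matrix(runif(n * p, rep(prior$log_lower, each = n),
                     rep(prior$log_upper, each = n)), n, p)
  theta <- 10^lg
  colnames(theta) <- prior$names
  theta
}

# Rows of theta inside the prior box (bounds inclusive).
prior_contains <- function(prior, theta) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1L)
  inside <- theta >= rep(prior$lower, each = nrow(theta)) &
    theta <= rep(prior$upper, each = nrow(theta))
  rowSums(inside) == ncol(theta)
}

#' Single-coordinate log-scale proposal kernel
#'
#' At each MCMC step one parameter is chosen uniformly at random and a
#' uniform perturbation on the base-10 logarithmic scale is added to it.
#'
#' @param half_width Bound of the uniform log10 perturbation (default 0.25).
#' @return An object of class `proposal_kernel`.
#' @export
proposal_kernel <- function(half_width = 0.25) {
  if (half_width <= 0) stop("`half_width` must be > 0", call. = FALSE)
  structure(list(half_width = half_width), class = "proposal_kernel")
}

#' Propose a new parameter vector
#'
#' Exactly one coordinate (chosen uniformly) is multiplied by
#' `10^u`, `u ~ U(-half_width, half_width)`. The kernel is symmetric.
#'
#' @param theta Numeric parameter vector.
#' @param kernel A [proposal_kernel()].
#' @return A parameter vector of the same length.
#' @export
propose <- function(theta, kernel = proposal_kernel()) {
  j <- sample.int(length(theta), 1L)
  theta[j] <- theta[j] * 10^runif(1L, -kernel$half_width, kernel$half_width)
  theta
}

# Vectorized proposal for a batch: each row perturbs one random coordinate.
propose_batch <- function(theta, kernel) {
  n <- nrow(theta)
  p <- ncol(theta)
  j <- sample.int(p, n, replace = TRUE)
  u <- runif(n, -kernel$half_width, kernel$half_width)
  cell <- cbind(seq_len(n), j)
  theta[cell] <- theta[cell] * 10^u
  list(theta = theta, coordinate = j)
}

#' Sum-of-squared-errors distance between time series
#'
#' \eqn{d = \sum_t (obs_t - sim_t)^2} over the shared observation times.
#' A simulation containing nonfinite values gets distance `Inf`, so a
#' diverged particle can never be accepted.
#'
#' @param obs,sim [time_series()] objects on identical time grids.
#' @return Nonnegative scalar distance (possibly `Inf`).
#' @examples
#' sse_distance(time_series(1:3, c(1, 2, 3)), time_series(1:3, c(0, 0, 0)))
#' @export
sse_distance <- function(obs, sim) {
  stopifnot(inherits(obs, "time_series"), inherits(sim, "time_series"))
  if (nrow(obs) != nrow(sim) ||
      any(abs(obs$time - sim$time) > 1e-9)) {
    stop("observed and simulated time grids do not match", call. = FALSE)
  }
  sse_rows(obs$value, matrix(sim$value, nrow = 1L))[1L]
}

# Distances of many simulated rows to one observed vector; NA/Inf -> Inf.
sse_rows <- function(obs_values, sim_matrix) {
  d <- rowSums((sim_matrix - rep(obs_values, each = nrow(sim_matrix)))^2)
  d[!is.finite(d)] <- Inf
  d
}

#' ABC indicator weighting function
#'
#' Equals 1 when the distance is within tolerance (`d <= eps`, boundary
#' accepted) and 0 otherwise. With `eps = Inf` every finite distance is
#' accepted, which makes the first intermediate distribution the prior.
#'
#' @param d Nonnegative distance(s).
#' @param eps Tolerance, `>= 0` or `Inf`.
#' @return 0/1 numeric vector.
#' @export
indicator <- function(d, eps) {
  if (length(eps) != 1L || is.na(eps) || eps < 0) {
    stop("`eps` must be a single nonnegative tolerance", call. = FALSE)
  }
  as.numeric(d <= eps)
}

#' One ABC-MCMC transition targeting prior x indicator
#'
#' Proposes with the symmetric single-coordinate log-scale kernel and
#' accepts iff the proposal lies inside the prior bounds and its simulated
#' data fall within tolerance (for a flat log-scale prior and symmetric
#' kernel the Metropolis-Hastings ratio reduces to exactly this product of
#' indicators). On rejection the input state is returned unchanged, so the
#' returned distance is always within tolerance.
#'
#' @param theta Current parameter vector, inside the prior support with
#'   `d_current <= eps`.
#' @param d_current Cached distance of `theta`.
#' @param eps Current tolerance.
#' @param prior A [log_uniform_prior()].
#' @param kernel A [proposal_kernel()].
#' @param model Model passed to [simulate_values()].
#' @param obs Observed [time_series()].
#' @return List with `theta`, `distance` and logical `accepted`.
#' @export
abc_mcmc_step <- function(theta, d_current, eps, prior, kernel, model, obs) {
  if (!(d_current <= eps)) {
    stop("abc_mcmc_step requires a particle inside the current support ",
         "(d_current <= eps)", call. = FALSE)
  }
  prop <- propose(theta, kernel)
  if (!prior_contains(prior, prop)) {
    return(list(theta = theta, distance = d_current, accepted = FALSE))
  }
  sim <- simulate_values(model, matrix(prop, nrow = 1L), obs$time)
  d_new <- sse_rows(obs$value, sim)[1L]
  if (d_new <= eps) {
    list(theta = prop, distance = d_new, accepted = TRUE)
  } else {
    list(theta = theta, distance = d_current, accepted = FALSE)
  }
}

# Batch MCMC sweep: `steps` ABC-MCMC moves applied to the rows in `idx`
# (the nonzero-weight particles). Only in-bounds proposals are simulated;
# distances are cached throughout.
mcmc_sweep <- function(theta, d, idx, eps, prior, kernel, model, obs_time,
                       obs_values, steps) {
  n_acc <- 0L
  for (s in seq_len(steps)) {
    if (length(idx) == 0L) break
    cur <- theta[idx, , drop = FALSE]
    prop <- propose_batch(cur, kernel)$theta
    inb <- prior_contains(prior, prop)
    acc <- logical(length(idx))
    if (any(inb)) {
      sim <- simulate_values(model, prop[inb, , drop = FALSE], obs_time)
      d_new <- sse_rows(obs_values, sim)
      ok <- d_new <= eps
      acc[inb] <- ok
      rows <- idx[inb][ok]
      theta[rows, ] <- prop[inb, , drop = FALSE][ok, , drop = FALSE]
      d[rows] <- d_new[ok]
    }
    n_acc <- n_acc + sum(acc)
  }
  list(theta = theta, d = d, n_accepted = n_acc,
       n_proposed = length(idx) * steps)
}
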