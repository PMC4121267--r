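#' Weighted empirical quantile
#'
#' Inverse of the weighted empirical CDF with lower interpolation: the
#' smallest value whose cumulative weight reaches `q`. `q = 0` returns the
#' minimum over nonzero-weight values and `q = 1` the maximum.
#'
#' @param values Finite sample values.
#' @param weights Normalized nonnegative weights.
#' @param q Quantile levels in `[0, 1]` (vectorized).
#' @return Numeric vector of quantiles, one per level.
#' @examples
#' weighted_quantile(c(1, 2, 3), c(0.5, 0.25, 0.25), 0.5) # 1
#' @export
weighted_quantile <- function(values, weights, q) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (length(values) != length(weights)) {
    stop("`values` and `weights` must have the same length", call. = FALSE)
  }
  if (any(q < 0 | q > 1)) stop("`q` must be in [0, 1]", call. = FALSE)
  keep <- weights > 0
  if (!any(keep)) stop("all weights are zero", call. = FALSE)
  v <- values[keep]
  w <- weights[keep] / sum(weights[keep])
  o <- order(v)
  v <- v[o]
  cw <- cumsum(w[o])
  vapply(q, function(qi) {
    if (qi == 0) return(v[1L])
    v[which(cw >= qi - 1e-12)[1L]]
  }, numeric(1L))
}

#' Simulate the posterior parameter ensemble
#'
#' Runs the model once for every distinct nonzero-weight particle (exact
#' duplicates created by resampling are simulated once and counted with
#' their multiplicity), under an input that may differ from the inference
#' input (prediction mode), and summarizes the resulting bundle of Z
#' trajectories by pointwise weighted quantiles. The 0/100-percentile band
#' is the pointwise min-max envelope of the ensemble. Divergent
#' trajectories are excluded with a logged count.
#'
#' @param ensemble A [particle_ensemble()] (e.g. `fit$ensemble` from
#'   [run_pa()]) with at least one nonzero-weight particle.
#' @param model An [ffl_model()] (or any model with a
#'   [simulate_values()] method).
#' @param input Input signal for the simulations; defaults to the model's.
#' @param t_end,dt Simulation horizon and step.
#' @param quantile_levels Band levels (default
#'   `c(0, 0.025, 0.25, 0.5, 0.75, 0.975, 1)`).
#' @return An object of class `trajectory_density`: `times`, a data frame
#'   `quantiles` (columns `time, q0, q2.5, ...`), `n_particles` and
#'   `n_divergent`.
#' @export
simulate_ensemble <- function(ensemble, model, input = model$input,
                              t_end = 10, dt = model$dt,
                              quantile_levels = c(0, 0.025, 0.25, 0.5,
                                                  0.75, 0.975, 1)) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  keep <- ensemble$weights > 0
  if (!any(keep)) stop("no nonzero-weight particles", call. = FALSE)
  theta <- ensemble$theta[keep, , drop = FALSE]
  w <- ensemble$weights[keep]

  # collapse exact duplicates, accumulating their weight
  key <- do.call(paste, c(lapply(seq_len(ncol(theta)),
                                 function(j) theta[, j]), sep = "\r"))
  first <- !duplicated(key)
  wsum <- tapply(w, factor(key, levels = key[first]), sum)
  theta_u <- theta[first, , drop = FALSE]
  w_u <- as.numeric(wsum)

  times <- seq(0, t_end, by = dt)
  m <- model
  m$dt <- dt
  Z <- simulate_batch_grid(m, theta_u, times, input)

  bad <- apply(Z, 1L, anyNA)
  n_div <- sum(bad)
  if (n_div > 0L) {
    message(sprintf("simulate_ensemble: excluded %d divergent trajectories",
                    n_div))
    Z <- Z[!bad, , drop = FALSE]
    w_u <- w_u[!bad]
    if (nrow(Z) == 0L) stop("all ensemble trajectories diverged",
                            call. = FALSE)
  }
  w_u <- w_u / sum(w_u)

  qm <- apply(Z, 2L, weighted_quantile, weights = w_u, q = quantile_levels)
  qm <- matrix(qm, nrow = length(quantile_levels))
  quantiles <- data.frame(time = times, t(qm))
  names(quantiles) <- c("time", paste0("q", quantile_levels * 100))
  structure(list(times = times, quantiles = quantiles,
                 levels = quantile_levels,
                 n_particles = nrow(theta_u) - n_div,
                 n_divergent = n_div,
                 input = input),
            class = "trajectory_density")
}

# Full-grid Z trajectories for a batch (dispatch keeps toy models usable).
simulate_batch_grid <- function(model, theta, times, input) {
  if (inherits(model, "ffl_model")) {
    ffl_observe_batch(model, theta, times, input = input)
  } else {
    simulate_values(model, theta, times)
  }
}

#' @export
print.trajectory_density <- function(x, ...) {
  cat(sprintf(
    "<trajectory_density> %d particles, t in [%g, %g], levels: %s\n",
    x$n_particles, x$times[1L], x$times[length(x$times)],
    paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Plot an ensemble trajectory density
#'
#' Shaded quantile band (outermost available pair by default) with the
#' median trajectory, and optional observed points.
#'
#' @param x A `trajectory_density`.
#' @param obs Optional observed [time_series()] drawn as points.
#' @param band Quantile pair to shade (default the min-max envelope).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.trajectory_density <- function(x, obs = NULL, band = c(0, 1), ...) {
  q <- x$quantiles
  lo <- q[[paste0("q", band[1L] * 100)]]
  hi <- q[[paste0("q", band[2L] * 100)]]
  ylim <- range(lo, hi, if (!is.null(obs)) obs$value)
  graphics::plot(x$times, hi, type = "n", ylim = ylim, xlab = "time",
                 ylab = "Z", ...)
  graphics::polygon(c(x$times, rev(x$times)), c(hi, rev(lo)),
                    col = grDevices::adjustcolor("steelblue", 0.4),
                    border = NA)
  if ("q50" %in% names(q)) {
    graphics::lines(x$times, q$q50, col = "steelblue4")
  }
  if (!is.null(obs)) {
    graphics::points(obs$time, obs$value, col = "red", pch = 19)
  }
  invisible(x)
}

#' Fraction of observed points inside a quantile band
#'
#' Quantifies "the band captures the data": the fraction of observed
#' points lying inside the closed band `[lower, upper]` at their
#' observation times.
#'
#' @param density A `trajectory_density` from [simulate_ensemble()].
#' @param obs Observed [time_series()]; its times must lie on the density
#'   grid.
#' @param band Pair of quantile levels present in the density (default the
#'   min-max envelope `c(0, 1)`).
#' @return Fraction in `[0, 1]`.
#' @export
coverage <- function(density, obs, band = c(0, 1)) {
  stopifnot(inherits(density, "trajectory_density"),
            inherits(obs, "time_series"))
  cols <- paste0("q", band * 100)
  if (!all(cols %in% names(density$quantiles))) {
    stop("requested band levels not present in the density", call. = FALSE)
  }
  dt <- density$times[2L] - density$times[1L]
  idx <- grid_index(obs$time, dt)
  if (any(idx > length(density$times))) {
    stop("observation times beyond the density grid", call. = FALSE)
  }
  lo <- density$quantiles[[cols[1L]]][idx]
  hi <- density$quantiles[[cols[2L]]][idx]
  mean(obs$value >= lo & obs$value <= hi)
}
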