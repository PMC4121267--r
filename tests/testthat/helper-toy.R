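# 1-parameter deterministic toy used throughout: the model's output at any
# time is the parameter itself, so with obs = 0.5 the SSE distance is
# (theta - 0.5)^2 per observation point. With a log10-uniform prior on
# [0.1, 10] and one observation, the acceptance region at tolerance eps is
# |theta - 0.5| <= sqrt(eps) and its exact prior mass has a closed form.
toy_model <- function() {
  function_model(
    function(theta, times) matrix(theta[, 1L], nrow(theta), length(times)),
    parameter_names = "theta", name = "identity_toy")
}

toy_prior <- function(lower = 0.1, upper = 10) {
  log_uniform_prior(lower, upper, names = "theta")
}

toy_obs <- function(value = 0.5) time_series(1, value)

# Exact prior mass of |theta - center| <= half under the log-uniform prior.
toy_mass <- function(eps, center = 0.5, lower = 0.1, upper = 10) {
  half <- sqrt(eps)
  a <- max(lower, center - half)
  b <- min(upper, center + half)
  if (b <= a) return(0)
  (log10(b) - log10(a)) / (log10(upper) - log10(lower))
}

ffl_fixture_obs <- function() load_fixture("step_obs")
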