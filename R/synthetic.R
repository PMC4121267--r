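#' Gaussian observation-noise model
#'
#' Additive i.i.d. Gaussian noise on the observed readout; the FFL study
#' uses mean 0 and variance 0.01.
#'
#' @param variance Noise variance (`>= 0`).
#' @param mean Noise mean (default 0).
#' @return An object of class `noise_model`.
#' @export
gaussian_noise <- function(variance = 0.01, mean = 0) {
  if (variance < 0) stop("`variance` must be >= 0", call. = FALSE)
  structure(list(distribution = "gaussian", mean = mean,
                 variance = variance),
            class = "noise_model")
}

#' Generate artificial observed data
#'
#' Simulates the noiseless trajectory at `theta_true` with the fixed-step
#' RK4 integrator, extracts Z at the observation times, and adds i.i.d.
#' Gaussian observation noise. Noisy values are not truncated at zero.
#' Deterministic given `seed`.
#'
#' @param model An [ffl_model()].
#' @param theta_true True parameter values (default the study's answer
#'   values, [ffl_answer_theta()]).
#' @param input Input signal; defaults to the model's.
#' @param times Observation times (default `1:10`).
#' @param noise A [gaussian_noise()] model (default variance 0.01).
#' @param seed Optional integer seed.
#' @return A [time_series()] of noisy observations.
#' @examples
#' m <- ffl_model("coherent_ffl")
#' generate_observed(m, seed = 1)
#' @export
generate_observed <- function(model, theta_true = ffl_answer_theta(),
                              input = model$input, times = 1:10,
                              noise = gaussian_noise(0.01), seed = NULL) {
  stopifnot(inherits(model, "ffl_model"), inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  traj <- rk4_simulate(model, theta_true, input = input,
                       t_end = max(times), dt = model$dt)
  clean <- observe(traj, times)
  noisy <- clean$value + rnorm(length(times), mean = noise$mean,
                               sd = sqrt(noise$variance))
  time_series(times, noisy)
}

#' Load a bundled observed dataset
#'
#' The package ships two observed datasets for the FFL case study,
#' produced by its own generator (coherent FFL at the answer parameters,
#' additive N(0, 0.01) observation noise at times 1..10): the step-response
#' set used for inference and model selection, and the pulse-response set
#' held out for prediction checks. They are fixed realizations committed
#' as CSV under `inst/extdata/` and labelled synthetic in their filenames:
#' they are generator output, not laboratory measurements, and every
#' number downstream of them is specific to their noise realization.
#'
#' @param name `"step_obs"` or `"pulse_obs"`.
#' @return A [time_series()] of 10 points at times 1..10.
#' @export
load_fixture <- function(name = c("step_obs", "pulse_obs")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_synthetic.csv"),
                      package = "abcpa")
  if (path == "" || !file.exists(path)) {
    stop("bundled dataset '", name, "' not found; regenerate it with ",
         "generate_observed()", call. = FALSE)
  }
  read_time_series(path)
}
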