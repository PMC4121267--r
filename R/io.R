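#' Parse and validate a run configuration file
#'
#' Configurations are YAML (JSON is accepted too) with one schema. Missing
#' entries fall back to the FFL study defaults: `K = 100000`,
#' `mcmc_steps = 7`, `ess_threshold = K/2`, `dt = 0.01`, `t_end = 10`,
#' the default schedule `(Inf, 1, 0.5, 0.25, 0.2, 0.15)`, the default
#' prior ([ffl_default_prior()]), proposal half-width 0.25 and a unit step
#' input. Infinity in schedules is written as the string `"inf"`.
#'
#' @param path Path to the configuration file.
#' @return A validated list of class `abcpa_config`.
#' @export
parse_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a mapping", call. = FALSE)

  defaults <- list(K = 100000L, mcmc_steps = 7L, dt = 0.01, t_end = 10,
                   schedule = c("inf", 1, 0.5, 0.25, 0.2, 0.15),
                   proposal_half_width = 0.25, input = "step", off_time = 5,
                   amplitude = 1, seed = NULL, data = NULL,
                   estimator = "pa", n_repeats = 10L)
  cfg <- modifyList(defaults, raw)

  parse_tol <- function(x) {
    vapply(x, function(v) {
      if (is.character(v) && tolower(v) %in% c("inf", "infinity", ".inf")) {
        Inf
      } else {
        suppressWarnings(as.numeric(v))
      }
    }, numeric(1L))
  }
  tol <- parse_tol(cfg$schedule)
  if (anyNA(tol)) stop("config: unreadable schedule entry", call. = FALSE)
  cfg$schedule <- annealing_schedule(tol)$tolerances

  models <- c("coherent_ffl", "incoherent_ffl")
  for (f in intersect(c("model", "model_1", "model_2"), names(cfg))) {
    if (!cfg[[f]] %in% models) {
      stop("config: unknown model name '", cfg[[f]], "'", call. = FALSE)
    }
  }
  if (!is.null(cfg$schedule_1) || !is.null(cfg$schedule_2)) {
    s1 <- parse_tol(cfg$schedule_1 %||% cfg$schedule)
    s2 <- parse_tol(cfg$schedule_2 %||% cfg$schedule)
    if (!identical(s1, s2)) {
      stop("config: the two models must share one annealing schedule",
           call. = FALSE)
    }
    cfg$schedule <- annealing_schedule(s1)$tolerances
  }
  cfg$K <- as.integer(cfg$K)
  if (is.na(cfg$K) || cfg$K < 2L) stop("config: K must be >= 2",
                                       call. = FALSE)
  if (is.null(cfg$ess_threshold)) cfg$ess_threshold <- cfg$K / 2
  if (cfg$mcmc_steps < 0) stop("config: mcmc_steps must be >= 0",
                               call. = FALSE)
  if (cfg$dt <= 0) stop("config: dt must be > 0", call. = FALSE)
  if (!cfg$input %in% c("step", "pulse")) {
    stop("config: input must be 'step' or 'pulse'", call. = FALSE)
  }
  if (!cfg$estimator %in% c("pa", "rejection")) {
    stop("config: estimator must be 'pa' or 'rejection'", call. = FALSE)
  }

  if (!is.null(cfg$prior)) {
    lo <- as.numeric(cfg$prior$lower)
    up <- as.numeric(cfg$prior$upper)
    cfg$prior <- log_uniform_prior(lo, up,
                                   names = cfg$prior$names %||%
                                     ffl_parameter_names())
  } else {
    cfg$prior <- ffl_default_prior()
  }
  if (cfg$proposal_half_width <= 0) {
    stop("config: proposal_half_width must be > 0", call. = FALSE)
  }
  structure(cfg, class = "abcpa_config")
}

# Build the model/schedule/kernel objects a config describes.
config_objects <- function(cfg, which_model = "model") {
  name <- cfg[[which_model]]
  if (is.null(name)) {
    stop("config: field '", which_model, "' is required", call. = FALSE)
  }
  input <- input_signal(cfg$input, amplitude = cfg$amplitude,
                        off_time = cfg$off_time)
  list(model = ffl_model(name, input = input, dt = cfg$dt),
       prior = cfg$prior,
       schedule = annealing_schedule(cfg$schedule),
       kernel = proposal_kernel(cfg$proposal_half_width))
}

#' Write a particle table to CSV
#'
#' Columns are `weight`, the parameter names, and `distance`; one row per
#' particle. Accepts a [run_pa()] result, a [run_rejection()] result or a
#' bare [particle_ensemble()] (rejection particles get constant weight
#' `1/n_accepted`).
#'
#' @param x The object holding particles.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_particles <- function(x, path) {
  if (inherits(x, "pa_result")) x <- x$ensemble
  if (inherits(x, "rejection_result")) {
    n <- max(1L, x$n_accepted)
    x <- particle_ensemble(x$particles, x$distances,
                           rep(1 / n, nrow(x$particles)))
  }
  stopifnot(inherits(x, "particle_ensemble"))
  d <- data.frame(weight = x$weights, x$theta, distance = x$distances,
                  check.names = FALSE)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory density to CSV
#'
#' One row per time point, columns `time, q0, q2.5, ...` for the quantile
#' levels the density was built with.
#'
#' @param density A `trajectory_density` from [simulate_ensemble()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_density <- function(density, path) {
  stopifnot(inherits(density, "trajectory_density"))
  write.csv(density$quantiles, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run summary
#'
#' Serializes the audit quantities of a run: for population annealing the
#' marginal-likelihood estimate, resampling log, ESS trace, schedule
#' (`Inf` as the string `"inf"`), seed and settings; for the rejection
#' sampler the acceptance count and estimate; for a Bayes-factor result
#' the per-repeat values, mean, sd and degenerate count.
#'
#' @param x A `pa_result`, `rejection_result` or `bf_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(x, path) {
  fmt_sched <- function(s) {
    lapply(s$tolerances, function(v) if (is.infinite(v)) "inf" else v)
  }
  out <- if (inherits(x, "pa_result")) {
    list(kind = "pa", model = x$model_name, ml_estimate = x$ml_estimate,
         resample_log = x$resample_log, ess_trace = x$ess_trace,
         extinct = x$extinct, schedule = fmt_sched(x$schedule), K = x$K,
         mcmc_steps = x$mcmc_steps, ess_threshold = x$ess_threshold,
         seed = x$seed)
  } else if (inherits(x, "rejection_result")) {
    list(kind = "rejection", model = x$model_name,
         ml_estimate = x$ml_estimate, n_accepted = x$n_accepted,
         n_trials = x$n_trials, eps = x$eps, seed = x$seed)
  } else if (inherits(x, "bf_result")) {
    list(kind = "bayes_factor", model_1 = x$model_1, model_2 = x$model_2,
         estimator = x$estimator, schedule = fmt_sched(x$schedule),
         K = x$K, repeats = x$n_repeats,
         per_repeat = data.frame(ml_1 = x$ml_1, ml_2 = x$ml_2,
                                 bf = x$bf_values),
         mean = x$mean, sd = x$sd, degenerate_count = x$degenerate_count,
         root_seed = x$root_seed)
  } else {
    stop("unsupported result type", call. = FALSE)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
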