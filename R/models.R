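#' Input signal for the feed-forward-loop models
#'
#' The transcription-factor input X is an idealized on/off signal: a step
#' (on at a constant level for the whole simulation) or a pulse (on until
#' `off_time`, then off). The pulse boundary itself counts as "on":
#' X(off_time) = amplitude and X(t) = 0 for t > off_time.
#'
#' @param kind `"step"` or `"pulse"`.
#' @param amplitude Signal level while on (dimensionless; default 1).
#' @param off_time Switch-off time for a pulse (default 5; ignored for a
#'   step).
#' @return An object of class `input_signal`.
#' @examples
#' input_signal("pulse", off_time = 5)
#' @export
input_signal <- function(kind = c("step", "pulse"), amplitude = 1,
                         off_time = 5) {
  kind <- match.arg(kind)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (kind == "pulse" && off_time <= 0) {
    stop("`off_time` must be > 0 for a pulse", call. = FALSE)
  }
  structure(list(kind = kind, amplitude = amplitude, off_time = off_time),
            class = "input_signal")
}

#' Evaluate an input signal at given times
#'
#' @param input An [input_signal()].
#' @param t Numeric vector of times.
#' @return Numeric vector of signal levels.
#' @export
input_value <- function(input, t) {
  stopifnot(inherits(input, "input_signal"))
  if (input$kind == "step") {
    rep(input$amplitude, length(t))
  } else {
    ifelse(t <= input$off_time + 1e-12, input$amplitude, 0)
  }
}

#' Names of the free kinetic parameters of the FFL models
#' @return Character vector of length 7.
#' @export
ffl_parameter_names <- function() {
  c("alpha_Y", "alpha_Z", "beta_Y", "beta_Z", "K_XY", "K_XZ", "K_YZ")
}

#' The "answer" parameter values of the FFL study
#'
#' The artificial observed data are generated from the coherent FFL model at
#' these values; inference tries to recover them (the Hill coefficient h = 2
#' is fixed, not inferred).
#' @return Named numeric vector of length 7.
#' @export
ffl_answer_theta <- function() {
  c(alpha_Y = 1, alpha_Z = 1, beta_Y = 1, beta_Z = 1,
    K_XY = 0.1, K_XZ = 0.1, K_YZ = 0.5)
}

#' Feed-forward-loop ODE model specification
#'
#' Coherent or incoherent type-1 FFL with AND-gate regulation of Z and no
#' basal production:
#' \deqn{dY/dt = \beta_Y \, a(X, K_{XY}) - \alpha_Y Y}
#' \deqn{dZ/dt = \beta_Z \, a(X, K_{XZ}) \, g(Y, K_{YZ}) - \alpha_Z Z}
#' where \eqn{a} is the Hill activation function, and the Y-to-Z gate
#' \eqn{g} is activation (coherent) or repression (incoherent). The seven
#' free kinetic parameters are
#' `alpha_Y, alpha_Z, beta_Y, beta_Z, K_XY, K_XZ, K_YZ`; the Hill
#' coefficient is fixed.
#'
#' @param name `"coherent_ffl"` or `"incoherent_ffl"`.
#' @param input An [input_signal()] driving X (default: unit step).
#' @param hill Fixed Hill coefficient h (default 2).
#' @param initial_state Named numeric `c(Y = , Z = )` at t = 0 (default
#'   both 0).
#' @param dt Integrator time step (default 0.01).
#' @return An object of class `ffl_model`.
#' @examples
#' m <- ffl_model("coherent_ffl")
#' rk4_simulate(m, ffl_answer_theta(), t_end = 10)
#' @export
ffl_model <- function(name = c("coherent_ffl", "incoherent_ffl"),
                      input = input_signal("step"), hill = 2,
                      initial_state = c(Y = 0, Z = 0), dt = 0.01) {
  name <- match.arg(name)
  stopifnot(inherits(input, "input_signal"))
  if (hill <= 0) stop("`hill` must be > 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (length(initial_state) != 2L || any(!is.finite(initial_state))) {
    stop("`initial_state` must be finite values for Y and Z", call. = FALSE)
  }
  structure(list(name = name, input = input, hill = hill,
                 initial_state = c(Y = unname(initial_state[1L]),
                                   Z = unname(initial_state[2L])),
                 dt = dt,
                 parameter_names = ffl_parameter_names()),
            class = c("ffl_model", "abc_model"))
}

#' @export
print.ffl_model <- function(x, ...) {
  cat(sprintf("<ffl_model> %s, h = %g, %s input, dt = %g\n",
              x$name, x$hill, x$input$kind, x$dt))
  invisible(x)
}

#' Hill regulation functions
#'
#' `hill_activation()` is \eqn{(u/K)^h / (1 + (u/K)^h)} and
#' `hill_repression()` is \eqn{1 / (1 + (u/K)^h)}; they sum to 1 at equal
#' arguments. Both are clamped for `u <= 0` (activation 0, repression 1).
#'
#' @param u Nonnegative regulator level (vectorized).
#' @param K Half-saturation threshold, > 0.
#' @param h Hill exponent, > 0.
#' @return Values in `[0, 1]`.
#' @examples
#' hill_activation(0.5, 0.5, 2) # half saturation: 0.5
#' @export
hill_activation <- function(u, K, h) {
  if (K <= 0 || h <= 0) stop("`K` and `h` must be > 0", call. = FALSE)
  r <- ifelse(u <= 0, 0, (u / K)^h)
  r / (1 + r)
}

#' @rdname hill_activation
#' @export
hill_repression <- function(u, K, h) {
  if (K <= 0 || h <= 0) stop("`K` and `h` must be > 0", call. = FALSE)
  r <- ifelse(u <= 0, 0, (u / K)^h)
  1 / (1 + r)
}

#' Right-hand side of the FFL ODEs
#'
#' @param model An [ffl_model()].
#' @param t Time (scalar).
#' @param state Numeric `c(Y, Z)`.
#' @param theta Named or ordered numeric vector of the 7 free parameters.
#' @param input An [input_signal()]; defaults to the model's own.
#' @return Numeric `c(dY, dZ)`.
#' @export
ffl_rhs <- function(model, t, state, theta, input = model$input) {
  stopifnot(inherits(model, "ffl_model"))
  if (any(!is.finite(state))) {
    stop("nonfinite state in ffl_rhs", call. = FALSE)
  }
  theta <- as_ffl_theta(theta)
  x <- input_value(input, t)
  h <- model$hill
  y <- state[1L]
  z <- state[2L]
  gate <- if (model$name == "coherent_ffl") {
    hill_activation(y, theta[["K_YZ"]], h)
  } else {
    hill_repression(y, theta[["K_YZ"]], h)
  }
  dy <- theta[["beta_Y"]] * hill_activation(x, theta[["K_XY"]], h) -
    theta[["alpha_Y"]] * y
  dz <- theta[["beta_Z"]] * hill_activation(x, theta[["K_XZ"]], h) * gate -
    theta[["alpha_Z"]] * z
  c(dY = unname(dy), dZ = unname(dz))
}

# Coerce a parameter vector (or 1-row matrix) to the canonical order.
as_ffl_theta <- function(theta) {
  theta <- as.numeric_named(theta)
  nm <- ffl_parameter_names()
  if (!is.null(names(theta)) && all(nm %in% names(theta))) {
    theta <- theta[nm]
  } else if (length(theta) == length(nm)) {
    names(theta) <- nm
  } else {
    stop("expected 7 FFL parameters", call. = FALSE)
  }
  if (any(theta <= 0)) stop("FFL parameters must be > 0", call. = FALSE)
  theta
}

as.numeric_named <- function(x) {
  out <- as.numeric(x)
  names(out) <- names(x)
  out
}

# Batch FFL simulation at the observation times: one row per parameter
# vector. Divergent particles come back as NA rows.
ffl_observe_batch <- function(model, theta, times, input = model$input,
                              return_y = FALSE) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1L)
  dt <- model$dt
  idx <- grid_index(times, dt)
  n_steps <- max(idx) - 1L
  res <- .ffl_rk4_batch(theta, model$name == "coherent_ffl", model$hill,
                        if (input$kind == "pulse") 1L else 0L,
                        input$amplitude, input$off_time,
                        model$initial_state[["Y"]],
                        model$initial_state[["Z"]],
                        n_steps, dt, idx, return_y)
  if (return_y) res else res$Z
}

# Map requested times to 1-based indices on the grid t = 0, dt, 2*dt, ...
# Times must sit on the grid (within dt/2 rounding slack).
grid_index <- function(times, dt) {
  idx <- as.integer(round(times / dt)) + 1L
  if (any(times < -1e-12)) stop("negative observation time", call. = FALSE)
  if (any(abs((idx - 1L) * dt - times) > dt * 1e-6)) {
    stop("observation times must lie on the integration grid", call. = FALSE)
  }
  idx
}

#' Classical fixed-step fourth-order Runge-Kutta integration
#'
#' A generic scalar/vector RK4 stepper used for integrator self-tests and as
#' a plain-R cross-check of the compiled FFL integrator.
#'
#' @param deriv Function `deriv(t, y, ...)` returning dy/dt.
#' @param y0 Initial state (numeric vector).
#' @param t_end End time (> 0, a multiple of `dt`).
#' @param dt Step size.
#' @param ... Passed on to `deriv`.
#' @return List with `times` (length n+1) and `states` (matrix, one row per
#'   time point).
#' @examples
#' out <- rk4_integrate(function(t, y) -y, 1, t_end = 1, dt = 0.01)
#' out$states[nrow(out$states), ] - exp(-1) # ~1e-10
#' @export
rk4_integrate <- function(deriv, y0, t_end, dt, ...) {
  if (dt <= 0 || t_end <= 0) stop("`dt` and `t_end` must be > 0",
                                  call. = FALSE)
  n <- as.integer(round(t_end / dt))
  if (abs(n * dt - t_end) > 1e-9) {
    stop("`t_end` must be a multiple of `dt`", call. = FALSE)
  }
  states <- matrix(NA_real_, n + 1L, length(y0))
  states[1L, ] <- y0
  y <- y0
  for (i in seq_len(n)) {
    t <- (i - 1L) * dt
    k1 <- deriv(t, y, ...)
    k2 <- deriv(t + dt / 2, y + dt / 2 * k1, ...)
    k3 <- deriv(t + dt / 2, y + dt / 2 * k2, ...)
    k4 <- deriv(t + dt, y + dt * k3, ...)
    y <- y + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    states[i + 1L, ] <- y
  }
  list(times = seq(0, t_end, by = dt), states = states)
}

#' Simulate one FFL trajectory
#'
#' Integrates the model with the compiled fixed-step RK4 integrator on the
#' grid `t = 0, dt, ..., t_end` and returns the full trajectory of Y and Z.
#'
#' @param model An [ffl_model()].
#' @param theta Parameter vector (7 values).
#' @param input Input signal; defaults to the model's own.
#' @param t_end End time.
#' @param dt Step size; defaults to the model's.
#' @return A data frame of class `ffl_trajectory` with columns
#'   `time`, `Y`, `Z`.
#' @examples
#' tr <- rk4_simulate(ffl_model("coherent_ffl"), ffl_answer_theta(), t_end = 10)
#' tail(tr, 1)
#' @export
rk4_simulate <- function(model, theta, input = model$input, t_end = 10,
                         dt = model$dt) {
  stopifnot(inherits(model, "ffl_model"))
  theta <- as_ffl_theta(theta)
  m <- model
  m$dt <- dt
  times <- seq(0, t_end, by = dt)
  res <- ffl_observe_batch(m, matrix(theta, nrow = 1L), times, input,
                           return_y = TRUE)
  if (anyNA(res$Z)) {
    stop("FFL integration diverged (nonfinite state) for this parameter set",
         call. = FALSE)
  }
  structure(data.frame(time = times, Y = res$Y[1L, ], Z = res$Z[1L, ]),
            class = c("ffl_trajectory", "data.frame"))
}

#' Extract observations from a trajectory
#'
#' Picks the Z values at the requested times by grid index; no
#' interpolation. Requested times must be grid points of the stored
#' trajectory and within its horizon.
#'
#' @param traj An `ffl_trajectory` from [rk4_simulate()].
#' @param times Observation times.
#' @return A [time_series()] of Z at `times`.
#' @export
observe <- function(traj, times) {
  stopifnot(inherits(traj, "ffl_trajectory"))
  dt <- traj$time[2L] - traj$time[1L]
  idx <- grid_index(times, dt)
  if (any(idx > nrow(traj))) {
    stop("requested time beyond the simulated horizon", call. = FALSE)
  }
  time_series(times, traj$Z[idx])
}
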