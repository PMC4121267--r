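test_that("Hill activation and repression take their closed-form values", {
  expect_equal(hill_activation(0.3, 0.3, 2), 0.5) # half saturation
  expect_equal(hill_activation(0, 0.1, 2), 0)
  expect_equal(hill_activation(1, 0.1, 2), 100 / 101)
  expect_equal(hill_repression(0, 0.5, 2), 1)
  expect_equal(hill_repression(0.5, 0.5, 2), 0.5)
  expect_equal(hill_repression(1, 0.5, 2), 0.2)
  expect_error(hill_activation(1, 0, 2), "> 0")
  expect_error(hill_repression(1, 0.5, -1), "> 0")
})

test_that("Hill functions are monotone, bounded and complementary", {
  u <- seq(0, 5, by = 0.05)
  a <- hill_activation(u, 0.4, 2)
  r <- hill_repression(u, 0.4, 2)
  expect_true(all(a >= 0 & a <= 1))
  expect_true(all(diff(a) >= 0))
  expect_true(all(diff(r) <= 0))
  expect_equal(a + r, rep(1, length(u)))
})

test_that("FFL right-hand sides match direct substitution", {
  theta <- ffl_answer_theta()
  co <- ffl_model("coherent_ffl")
  inc <- ffl_model("incoherent_ffl")
  off <- input_signal("pulse", off_time = 5)

  # no input, zero state: nothing moves
  expect_equal(ffl_rhs(co, t = 6, c(0, 0), theta, input = off),
               c(dY = 0, dZ = 0))
  # X = 1, zero state: Y is produced at beta_Y * act(1, K_XY); the AND gate
  # on Z sees Y = 0, so the coherent model makes no Z yet while the
  # incoherent model produces at full rate
  expect_equal(ffl_rhs(co, 0, c(0, 0), theta),
               c(dY = 100 / 101, dZ = 0))
  expect_equal(ffl_rhs(inc, 0, c(0, 0), theta),
               c(dY = 100 / 101, dZ = 100 / 101))
  expect_error(ffl_rhs(co, 0, c(NaN, 0), theta), "nonfinite")
})

test_that("the generic RK4 stepper solves dy/dt = -y to 1e-8", {
  out <- rk4_integrate(function(t, y) -y, 1, t_end = 1, dt = 0.01)
  expect_equal(length(out$times), 101L)
  expect_lt(abs(out$states[101L, 1L] - exp(-1)), 1e-8)
})

test_that("compiled FFL integrator agrees with plain-R RK4 and deSolve", {
  set.seed(4)
  prior <- ffl_default_prior()
  for (name in c("coherent_ffl", "incoherent_ffl")) {
    m <- ffl_model(name)
    for (theta in list(ffl_answer_theta(), sample_prior(prior, 1)[1L, ])) {
      tr <- rk4_simulate(m, theta, t_end = 2)
      ref <- rk4_integrate(function(t, y, ...) ffl_rhs(m, t, y, theta),
                           c(0, 0), t_end = 2, dt = 0.01)
      expect_lt(max(abs(tr$Y - ref$states[, 1L])), 1e-12)
      expect_lt(max(abs(tr$Z - ref$states[, 2L])), 1e-12)
    }
  }
  skip_if_not_installed("deSolve")
  m <- ffl_model("coherent_ffl")
  theta <- ffl_answer_theta()
  ode <- deSolve::ode(c(Y = 0, Z = 0), seq(0, 10, 0.01),
                      function(t, y, p) list(ffl_rhs(m, t, y, theta)),
                      parms = NULL, method = "rk4")
  tr <- rk4_simulate(m, theta, t_end = 10)
  expect_lt(max(abs(tr$Z - ode[, "Z"])), 1e-10)
})

test_that("step-input trajectories reach the closed-form fixed points", {
  set.seed(11)
  prior <- ffl_default_prior()
  h <- 2
  for (name in c("coherent_ffl", "incoherent_ffl")) {
    m <- ffl_model(name)
    for (i in 1:5) {
      theta <- sample_prior(prior, 1)[1L, ]
      t_end <- ceiling(10 / min(theta[c("alpha_Y", "alpha_Z")]))
      tr <- rk4_simulate(m, theta, t_end = t_end)
      ystar <- theta[["beta_Y"]] * hill_activation(1, theta[["K_XY"]], h) /
        theta[["alpha_Y"]]
      gate <- if (name == "coherent_ffl") {
        hill_activation(ystar, theta[["K_YZ"]], h)
      } else {
        hill_repression(ystar, theta[["K_YZ"]], h)
      }
      zstar <- theta[["beta_Z"]] * hill_activation(1, theta[["K_XZ"]], h) *
        gate / theta[["alpha_Z"]]
      expect_lt(abs(tr$Y[nrow(tr)] - ystar), 1e-3)
      expect_lt(abs(tr$Z[nrow(tr)] - zstar), 1e-3)
      expect_true(all(tr$Y > -1e-9 & tr$Z > -1e-9))
    }
  }
})

test_that("zero production freezes the system and halving dt barely moves Z", {
  m <- ffl_model("coherent_ffl")
  theta0 <- c(alpha_Y = 1, alpha_Z = 1,
              beta_Y = .Machine$double.xmin, beta_Z = .Machine$double.xmin,
              K_XY = 0.1, K_XZ = 0.1, K_YZ = 0.5)
  tr0 <- rk4_simulate(m, theta0, t_end = 5)
  expect_lt(max(abs(tr0$Y)), 1e-12)
  expect_lt(max(abs(tr0$Z)), 1e-12)

  theta <- ffl_answer_theta()
  z1 <- observe(rk4_simulate(m, theta, t_end = 10, dt = 0.01), 1:10)
  z2 <- observe(rk4_simulate(m, theta, t_end = 10, dt = 0.005), 1:10)
  expect_lt(max(abs(z1$value - z2$value)), 1e-6)
})

test_that("coherent and incoherent step responses are visibly distinct", {
  theta <- ffl_answer_theta()
  zc <- rk4_simulate(ffl_model("coherent_ffl"), theta, t_end = 10)$Z
  zi <- rk4_simulate(ffl_model("incoherent_ffl"), theta, t_end = 10)$Z
  expect_gt(max(abs(zc - zi)), 0.1)
})

test_that("observe() extracts by grid index and rejects off-range times", {
  m <- ffl_model("coherent_ffl")
  tr <- rk4_simulate(m, ffl_answer_theta(), t_end = 10)
  # a synthetic ramp trajectory: Z(t) = t exactly on the grid
  ramp <- tr
  ramp$Z <- ramp$time
  got <- observe(ramp, c(1, 2, 3))
  expect_equal(got$value, c(1, 2, 3))
  expect_error(observe(tr, 11), "beyond")
  expect_error(observe(tr, 1.2345), "grid")
  zeros <- tr
  zeros$Z <- 0 * zeros$Z
  expect_equal(observe(zeros, 1:10)$value, rep(0, 10))
})

test_that("pulse input is right-continuous at the switch-off boundary", {
  inp <- input_signal("pulse", off_time = 5)
  expect_equal(input_value(inp, c(4.99, 5, 5.01)), c(1, 1, 0))
  expect_equal(input_value(input_signal("step"), c(0, 100)), c(1, 1))
})
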