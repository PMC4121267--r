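test_that("ESS identities hold for uniform, degenerate and mixed weights", {
  expect_equal(ess(rep(1 / 100, 100)), 100)
  expect_equal(ess(c(1, rep(0, 9))), 1)
  expect_equal(ess(c(0.5, 0.3, 0.2)), 1 / 0.38)
  expect_equal(ess(rep(0, 5)), 0) # extinction signal
})

test_that("reweighting keeps survivors at equal weight and flags extinction", {
  ens <- particle_ensemble(matrix(1:10, ncol = 1L),
                           distances = c(rep(0.1, 5), rep(2, 5)))
  up <- update_weights(ens, 3)
  expect_equal(up$weights, rep(0.1, 10)) # everyone survives: unchanged
  up <- update_weights(ens, 1)
  expect_equal(up$weights, c(rep(0.2, 5), rep(0, 5))) # half survive: 2/K
  up_inf <- update_weights(ens, Inf)
  expect_equal(up_inf$weights, ens$weights)
  expect_error(update_weights(ens, 0.01), class = "abcpa_extinction")
})

test_that("multinomial resampling restores uniform weights and counts survivors", {
  set.seed(5)
  K <- 1000L
  d <- c(rep(0.05, 400), rep(5, 600))
  ens <- particle_ensemble(matrix(seq_len(K), ncol = 1L), d)
  ens <- update_weights(ens, 1) # 400 survivors
  rs <- resample(ens)
  expect_equal(rs$k_resample, 400L)
  expect_equal(rs$ensemble$weights, rep(1 / K, K))
  expect_equal(ess(rs$ensemble$weights), K)
  # only surviving particles (values 1..400) can be drawn, and their cached
  # distances travel with them
  expect_true(all(rs$ensemble$theta[, 1L] <= 400))
  expect_true(all(rs$ensemble$distances == 0.05))
  # a single survivor gives K copies of it
  ens1 <- particle_ensemble(matrix(1:4, ncol = 1L), c(0, 9, 9, 9))
  rs1 <- resample(update_weights(ens1, 1))
  expect_equal(rs1$k_resample, 1L)
  expect_true(all(rs1$ensemble$theta[, 1L] == 1))
})

test_that("a schedule of (Inf) returns the prior sample with ml = 1", {
  fit <- run_pa(toy_model(), toy_prior(), toy_obs(),
                annealing_schedule(Inf), K = 500, seed = 2)
  expect_equal(fit$ml_estimate, 1)
  expect_false(fit$extinct)
  expect_equal(nrow(fit$ensemble$theta), 500L)
  expect_equal(fit$ensemble$weights, rep(1 / 500, 500))
  set.seed(2)
  expect_equal(unname(fit$ensemble$theta[, 1L]),
               unname(sample_prior(toy_prior(), 500)[, 1L]))
})

test_that("PA marginal likelihood matches the analytic toy mass and rejection", {
  sched <- annealing_schedule(c(Inf, 1, 0.1, 0.01))
  exact <- toy_mass(0.01)
  expect_equal(exact, log10(0.6 / 0.4) / 2, tolerance = 1e-12)
  K <- 5000
  ml_pa <- ml_rej <- numeric(10)
  for (s in 1:10) {
    ml_pa[s] <- run_pa(toy_model(), toy_prior(), toy_obs(), sched, K = K,
                       mcmc_steps = 3, seed = 100 + s)$ml_estimate
    ml_rej[s] <- run_rejection(toy_model(), toy_prior(), toy_obs(),
                               eps = 0.01, n_trials = K,
                               seed = 200 + s)$ml_estimate
  }
  se <- sqrt(exact * (1 - exact) / K)
  expect_lt(abs(mean(ml_pa) - exact), 3 * sd(ml_pa) / sqrt(10) + 1e-9)
  expect_lt(abs(mean(ml_rej) - exact), 3 * se)
})

test_that("survival-fraction bookkeeping is consistent and non-increasing", {
  fit <- run_pa(toy_model(), toy_prior(), toy_obs(),
                annealing_schedule(c(Inf, 1, 0.1, 0.01)), K = 2000,
                mcmc_steps = 3, seed = 42)
  frac <- fit$resample_log$k_resample / fit$K
  running <- cumprod(frac)
  expect_true(all(diff(c(1, running)) <= 0))
  expect_equal(fit$ml_estimate,
               prod(frac) * sum(fit$ensemble$weights > 0) / fit$K)
  expect_true(fit$ml_estimate >= 0 && fit$ml_estimate <= 1)
  expect_length(fit$ess_trace, 3L)
})

test_that("final nonzero-weight particles satisfy the tolerance and the prior", {
  sched <- annealing_schedule(c(Inf, 1, 0.1, 0.01))
  fit <- run_pa(toy_model(), toy_prior(), toy_obs(), sched, K = 2000,
                mcmc_steps = 3, seed = 7)
  keep <- fit$ensemble$weights > 0
  expect_true(all(fit$ensemble$distances[keep] <= 0.01))
  th <- fit$ensemble$theta[keep, 1L]
  expect_true(all(th >= 0.1 & th <= 10))
  # posterior spread bounded by the acceptance interval half-width
  w <- fit$ensemble$weights[keep]
  mu <- sum(w * th) / sum(w)
  spread <- sqrt(sum(w * (th - mu)^2) / sum(w))
  expect_lt(spread, sqrt(0.01))
})

test_that("PA is deterministic given a seed and extinction degrades gracefully", {
  sched <- annealing_schedule(c(Inf, 1, 0.1, 0.01))
  a <- run_pa(toy_model(), toy_prior(), toy_obs(), sched, K = 500,
              mcmc_steps = 2, seed = 9)
  b <- run_pa(toy_model(), toy_prior(), toy_obs(), sched, K = 500,
              mcmc_steps = 2, seed = 9)
  expect_identical(a$ensemble$theta, b$ensemble$theta)
  expect_identical(a$ml_estimate, b$ml_estimate)
  # an unreachable observation extinguishes the ensemble without error
  ext <- run_pa(toy_model(), toy_prior(), time_series(1, 1e6),
                annealing_schedule(c(Inf, 1)), K = 100, seed = 1)
  expect_true(ext$extinct)
  expect_equal(ext$ml_estimate, 0)
})

test_that("schedules must decrease strictly", {
  expect_error(annealing_schedule(c(Inf, 1, 1)), "decreasing")
  expect_error(annealing_schedule(c(1, 2)), "decreasing")
  expect_error(annealing_schedule(c(Inf, -1)), ">= 0")
  expect_silent(annealing_schedule(c(Inf, 1, 0.5)))
})
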