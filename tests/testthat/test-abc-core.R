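test_that("SSE distance matches hand arithmetic and flags divergence", {
  a <- time_series(1:3, c(1, 2, 3))
  b <- time_series(1:3, c(0, 0, 0))
  expect_equal(sse_distance(a, a), 0)
  expect_equal(sse_distance(a, b), 14)
  expect_equal(sse_distance(a, time_series(1:3, c(1, NaN, 3))), Inf)
  expect_error(sse_distance(a, time_series(2:4, c(0, 0, 0))), "grids")
})

test_that("the indicator accepts the tolerance boundary and all of eps = Inf", {
  expect_equal(indicator(0.3, 0.3), 1)
  expect_equal(indicator(0.3000001, 0.3), 0)
  expect_equal(indicator(c(0, 1e6), Inf), c(1, 1))
  expect_equal(indicator(Inf, Inf), 1) # diverged particle at the prior level
  expect_error(indicator(1, -0.1), "nonnegative")
})

test_that("prior draws stay in bounds with the geometric-midpoint median", {
  prior <- ffl_default_prior()
  set.seed(1)
  th <- sample_prior(prior, 1e5)
  expect_true(all(th >= rep(prior$lower, each = nrow(th)) &
                    th <= rep(prior$upper, each = nrow(th))))
  # log-uniform => median at the geometric midpoint sqrt(lower*upper)
  med <- apply(th, 2L, stats::median)
  expect_equal(unname(med), sqrt(prior$lower * prior$upper),
               tolerance = 0.05)
  set.seed(99)
  a <- sample_prior(prior, 10)
  set.seed(99)
  b <- sample_prior(prior, 10)
  expect_identical(a, b)
  expect_error(log_uniform_prior(10, 0.1), "lower < upper")
  expect_error(log_uniform_prior(0, 1), "lower < upper")
})

test_that("the proposal perturbs one coordinate, within +/-0.25 decades, uniformly", {
  set.seed(2)
  theta <- ffl_answer_theta()
  kern <- proposal_kernel(0.25)
  n <- 1e5
  props <- t(vapply(seq_len(n), function(i) propose(theta, kern),
                    numeric(7L)))
  changed <- props != rep(theta, each = n)
  expect_true(all(rowSums(changed) == 1L)) # exactly one coordinate moves
  shift <- abs(log10(props) - rep(log10(theta), each = n))
  expect_lte(max(shift), 0.25)
  freq <- colSums(changed) / n
  expect_true(all(abs(freq - 1 / 7) < 0.01))
})

test_that("reversing a perturbation restores the parameter vector", {
  theta <- ffl_answer_theta()
  set.seed(3)
  for (i in 1:50) {
    prop <- propose(theta)
    j <- which(prop != theta)
    back <- prop
    back[j] <- 10^(log10(prop[j]) - (log10(prop[j]) - log10(theta[j])))
    expect_equal(back, theta)
  }
})

test_that("ABC-MCMC accepts in-support proposals and holds its contract", {
  m <- toy_model()
  prior <- toy_prior()
  obs <- toy_obs()
  kern <- proposal_kernel(0.25)
  # a particle outside the current support must not be moved
  expect_error(abc_mcmc_step(2, d_current = 2.25, eps = 1, prior, kern, m,
                             obs),
               "inside the current support")
  set.seed(8)
  # with eps = Inf acceptance is governed by the prior bounds alone
  n_acc <- 0L
  bad <- 0L
  theta <- 0.5
  for (i in 1:500) {
    st <- abc_mcmc_step(theta, 0, Inf, prior, kern, m, obs)
    ok <- if (st$accepted) {
      st$theta >= prior$lower && st$theta <= prior$upper
    } else {
      identical(st$theta, theta)
    }
    bad <- bad + !ok
    theta <- st$theta
    n_acc <- n_acc + st$accepted
  }
  expect_equal(bad, 0L)
  expect_gt(n_acc, 400) # interior start: most proposals land in bounds
  # returned distance is always within tolerance
  st <- abc_mcmc_step(0.45, (0.45 - 0.5)^2, eps = 0.01, prior, kern, m, obs)
  expect_lte(st$distance, 0.01)
})

test_that("a long ABC-MCMC chain is uniform over the accepted log-interval", {
  # target = prior x indicator on the toy: flat in log10(theta) over
  # |theta - 0.5| <= 0.1; chi-square uniformity check on 20 bins
  m <- toy_model()
  prior <- toy_prior()
  obs <- toy_obs()
  kern <- proposal_kernel(0.25)
  eps <- 0.01
  set.seed(13)
  theta <- 0.5
  d <- 0
  draws <- numeric(20000)
  for (i in seq_along(draws)) {
    st <- abc_mcmc_step(theta, d, eps, prior, kern, m, obs)
    theta <- st$theta
    d <- st$distance
    draws[i] <- theta
  }
  lo <- log10(0.4)
  hi <- log10(0.6)
  bins <- cut(log10(draws), breaks = seq(lo, hi, length.out = 21L))
  # thin to reduce autocorrelation before the chi-square test
  counts <- table(bins[seq(1, length(draws), by = 10)])
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})
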