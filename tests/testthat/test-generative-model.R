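test_that("stimulus sampling matches the zero-mean Normal model", {
  env <- env_params(sigma_s = 1)
  set.seed(42)
  draws <- sample_stimulus(env, 1e5)
  expect_lt(abs(mean(draws)), 0.02)
  expect_lt(abs(sd(draws) - 1), 0.02)
  expect_lt(abs(mean(draws > 0) - 0.5), 0.01)

  set.seed(7)
  a <- sample_stimulus(env, 100)
  set.seed(7)
  b <- sample_stimulus(env, 100)
  expect_identical(a, b)
})

test_that("component means are affine in the stimulus", {
  expect_equal(component_means(policy_params(c(1.5, 0)), 0.7), 1.5)
  expect_equal(component_means(policy_params(c(1.25, 0, 1.75, 0)), -2),
               c(1.25, 1.75))
  expect_equal(component_means(policy_params(c(0, 1)), 2), 2)
})

test_that("action pmf matches direct evaluation of the mixture ordinates", {
  # means equidistant from both actions: coin flip
  expect_equal(action_pmf(policy_params(c(1.5, 0)), s = 0.3), c(0.5, 0.5))

  # single component at action 1: normalized Gaussian ordinates at 1 and 2
  p <- action_pmf(policy_params(c(1, 0)), s = 0)
  d <- dnorm(1:2, mean = 1, sd = 1)
  expect_equal(p, d / sum(d), tolerance = 1e-12)
  expect_equal(p[1], 1 / (1 + exp(-0.5)), tolerance = 1e-6)

  # two components, three actions, against a hand-rolled oracle
  pol <- policy_params(c(1.2, 0.5, 2.6, -0.3), n_actions = 3L, sigma_a = 0.8)
  s <- 0.4
  m <- c(1.2 + 0.5 * s, 2.6 - 0.3 * s)
  dens <- sapply(1:3, function(a) sum(dnorm(a, mean = m, sd = 0.8)))
  expect_equal(action_pmf(pol, s), dens / sum(dens), tolerance = 1e-12)
})

test_that("action pmf is a proper distribution on random instances", {
  set.seed(11)
  for (i in 1:1000) {
    pol <- random_policy(sample(1:3, 1), sample(2:5, 1))
    p <- action_pmf(pol, rnorm(1))
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("action pmf obeys reflection symmetry", {
  set.seed(12)
  for (i in 1:50) {
    na <- sample(2:4, 1)
    pol <- random_policy(sample(1:2, 1), na)
    mir <- policy_params(mirror_weights(pol$weights, na), na, pol$sigma_a)
    s <- rnorm(1)
    expect_equal(action_pmf(pol, s), rev(action_pmf(mir, -s)),
                 tolerance = 1e-12)
  }
})

test_that("p(action 1) decreases as the component mean moves toward 2", {
  means <- seq(1.05, 1.95, by = 0.05)
  p1 <- vapply(means, function(m) {
    action_pmf(policy_params(c(m, 0)), s = 0)[1]
  }, numeric(1))
  expect_true(all(diff(p1) < 0))
})

test_that("policy collapse is signalled on total underflow, and the limit pmf resolves it", {
  far <- policy_params(c(1e4, 0), sigma_a = 1)
  expect_error(action_pmf(far, 0), class = "policy_collapse")
  p <- action_pmf(far, 0, limit = TRUE)
  expect_equal(p, c(0, 1))  # point mass on the nearest action
  expect_error(sample_action(far, 0, u = 0.5), class = "policy_collapse")
  expect_equal(sample_action(far, 0, u = 0.5, limit = TRUE), 2L)
})

test_that("sampled actions follow the pmf", {
  pol <- policy_params(c(1.5, 0))
  set.seed(13)
  u <- runif(1e4)
  acts <- vapply(u, function(uu) sample_action(pol, 0, u = uu), integer(1))
  expect_lt(abs(mean(acts == 1L) - 0.5), 0.015)

  # concentrated policy: always the nearest action
  tight <- policy_params(c(1, 0), sigma_a = 0.05)
  acts <- vapply(runif(100), function(uu) sample_action(tight, 0, u = uu),
                 integer(1))
  expect_true(all(acts == 1L))

  # goodness of fit across random instances
  set.seed(14)
  for (i in 1:5) {
    pol <- random_policy(sample(1:2, 1), sample(2:4, 1))
    s <- rnorm(1)
    p <- action_pmf(pol, s)
    u <- runif(1e4)
    acts <- 1L + findInterval(u, cumsum(p)[-length(p)])
    obs <- tabulate(acts, nbins = pol$n_actions)
    expect_gt(chisq.test(obs, p = p)$p.value, 1e-3)
  }
})

test_that("reward mean encodes the stimulus-action contingency", {
  env <- env_params()  # alpha = 2, beta = 1.5
  expect_equal(reward_mean(env, a = 1, s = -1), 1)
  expect_equal(reward_mean(env, a = 2, s = 1), 1)
  expect_equal(reward_mean(env, a = 1, s = 1), -1)
  expect_equal(reward_mean(env, a = 2, s = 0), 0)
  # additive variant
  expect_equal(reward_mean(env, a = 2, s = 1, form = "additive"), 5.5)
})

test_that("sampled rewards are Normal around the reward mean", {
  env <- env_params()
  set.seed(15)
  draws <- sample_reward(env, a = 2, s = 1, n = 1e5)
  expect_lt(abs(mean(draws) - 1), 0.02)
  expect_lt(abs(sd(draws) - 1), 0.02)

  tight <- env_params(sigma_r = 1e-9)
  expect_equal(sample_reward(tight, a = 2, s = 1), 1, tolerance = 1e-6)

  set.seed(16)
  a <- sample_reward(env, 1, 0.5, n = 50)
  set.seed(16)
  b <- sample_reward(env, 1, 0.5, n = 50)
  expect_identical(a, b)
})

test_that("constructors validate their invariants", {
  expect_error(policy_params(c(1, 2, 3)), "even")
  expect_error(policy_params(c(1.5, 0), n_actions = 1), "n_actions")
  expect_error(policy_params(c(1.5, 0), sigma_a = 0), "sigma_a")
  expect_error(env_params(sigma_s = -1), "sigma_s")
  expect_error(env_params(sigma_r = 0), "sigma_r")
})
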