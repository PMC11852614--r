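test_that("history buffer is a bounded FIFO", {
  h <- new_history(3)
  expect_equal(history_length(h), 0L)
  for (i in 1:5) h <- history_append(h, s = i, a = 1L, r = 0)
  expect_equal(history_length(h), 3L)
  expect_true(history_full(h))
  expect_equal(h$s, c(3, 4, 5))  # oldest evicted, order preserved

  expect_error(new_history(0), "capacity")
  h2 <- as_history(1:10, rep(1L, 10), capacity = 4)
  expect_equal(h2$s, 7:10)
})

test_that("consistency loss is the summed surprisal of remembered actions", {
  # every recorded action has probability 1/2 under the symmetric policy
  h <- as_history(rep(0, 20), rep(1L, 20))
  expect_equal(consistency_loss(policy_params(c(1.5, 0)), h), 20 * log(2),
               tolerance = 1e-12)

  # near-certain recorded action: essentially zero surprisal
  h1 <- as_history(0, 1L)
  expect_lt(consistency_loss(policy_params(c(1, 0), sigma_a = 0.05), h1),
            1e-8)

  expect_error(consistency_loss(policy_params(c(1.5, 0)), new_history(5)),
               "non-empty")
})

test_that("consistency loss inherits reflection symmetry and ignores order", {
  set.seed(21)
  for (i in 1:20) {
    na <- sample(2:3, 1)
    pol <- random_policy(sample(1:2, 1), na)
    h <- random_history(15, na)
    mir_pol <- policy_params(mirror_weights(pol$weights, na), na, pol$sigma_a)
    mir_h <- as_history(-h$s, na + 1L - h$a, h$r)
    expect_equal(consistency_loss(pol, h), consistency_loss(mir_pol, mir_h),
                 tolerance = 1e-10)

    perm <- sample(history_length(h))
    h_perm <- as_history(h$s[perm], h$a[perm], h$r[perm])
    expect_equal(consistency_loss(pol, h), consistency_loss(pol, h_perm),
                 tolerance = 1e-12)
  }
})

test_that("consistency loss over sigma_a matches a brute-force scan", {
  h <- as_history(0, 1L)  # single pair, component mean at 1.4
  grid <- seq(0.2, 3, by = 0.05)
  la <- vapply(grid, function(sa) {
    consistency_loss(policy_params(c(1.4, 0), sigma_a = sa), h)
  }, numeric(1))
  # oracle: -log of the normalized Gaussian ordinates at the actions
  oracle <- vapply(grid, function(sa) {
    d <- dnorm(1:2, mean = 1.4, sd = sa)
    -log(d[1] / sum(d))
  }, numeric(1))
  expect_equal(la, oracle, tolerance = 1e-12)
  # loss decreases with sigma_a toward the scan's minimizer
  k <- which.min(la)
  expect_true(all(diff(la[1:k]) < 0))
})

test_that("reward loss is the negative expected mean reward over remembered stimuli", {
  env <- env_params()
  h <- as_history(c(-1, 1), c(1L, 2L))

  # near-deterministic "action 2 iff s > 0" policy: each stimulus pays +1
  det <- policy_params(c(1.5, 3), sigma_a = 0.3)
  expect_equal(reward_loss(det, h, env), -1, tolerance = 1e-6)

  # uniform policy: rewards cancel by symmetry
  expect_equal(reward_loss(policy_params(c(1.5, 0)), h, env), 0,
               tolerance = 1e-12)

  # all stimuli at zero: reward mean vanishes identically
  h0 <- as_history(c(0, 0, 0), c(1L, 2L, 1L))
  expect_equal(reward_loss(random_policy(), h0, env), 0, tolerance = 1e-12)

  # sum aggregation scales by the window size
  expect_equal(reward_loss(det, h, env, aggregate = "sum"), -2,
               tolerance = 1e-5)
})

test_that("compromise loss is the lambda mixture of its components", {
  env <- env_params()
  set.seed(22)
  for (i in 1:20) {
    pol <- random_policy()
    h <- random_history(10)
    lam <- runif(1)
    lb <- compromise_loss(pol, h, env, lam)
    expect_lt(abs(lb$l_lambda - (lam * lb$l_r + (1 - lam) * lb$l_a)), 1e-12)
    expect_gte(lb$l_a, 0)

    # affine in lambda: midpoint value is the mean of the endpoints
    l0 <- compromise_loss(pol, h, env, 0)$l_lambda
    l1 <- compromise_loss(pol, h, env, 1)$l_lambda
    lmid <- compromise_loss(pol, h, env, 0.5)$l_lambda
    expect_equal(lmid, (l0 + l1) / 2, tolerance = 1e-10)
    expect_equal(l0, lb$l_a, tolerance = 1e-12)
    expect_equal(l1, lb$l_r, tolerance = 1e-12)
  }
  expect_error(compromise_loss(random_policy(), random_history(5), env, 1.5),
               "lambda")
})

test_that("degenerate policies yield a large sentinel, not an error", {
  h <- as_history(c(-2, 2), c(1L, 2L))
  far <- policy_params(c(1e6, 0))
  la <- consistency_loss(far, h)
  expect_gt(la, 1e100)
  expect_true(is.finite(la))
  lr <- reward_loss(far, h, env_params())
  expect_gt(lr, 1e100)
})

test_that("R and compiled loss evaluations agree", {
  env <- env_params(alpha = 1.3, beta = 0.7)
  set.seed(23)
  for (i in 1:25) {
    na <- sample(2:4, 1)
    pol <- random_policy(sample(1:2, 1), na)
    h <- random_history(12, na)
    lam <- runif(1)
    r_loss <- compromise_loss(pol, h, env, lam)
    c_loss <- choicesym:::cpp_loss(pol$weights, h$s, h$a, h$r, na,
                                   pol$sigma_a, env$alpha, env$beta, lam,
                                   0L, 0L, 0L)
    expect_equal(c_loss[1], r_loss$l_a, tolerance = 1e-10)
    expect_equal(c_loss[2], r_loss$l_r, tolerance = 1e-10)
    expect_equal(c_loss[3], r_loss$l_lambda, tolerance = 1e-10)
  }
})
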