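test_that("running average is a centered moving mean with edge truncation", {
  expect_equal(running_average(rep(2, 10)), rep(2, 10))
  expect_equal(running_average(c(1, 2, 1, 2, 1))[3], 1.4)
  expect_equal(running_average(1:7, window = 1), as.numeric(1:7))
  # edges use only available points
  expect_equal(running_average(c(1, 2, 1, 2, 1))[1], mean(c(1, 2, 1)))
  expect_error(running_average(numeric(0)), "non-empty")
  expect_error(running_average(1:5, window = 4), "odd")
})

test_that("stoppage times report last occurrences with winner censoring", {
  set.seed(41)
  a <- rep(2L, 300)
  a[sample(1:137, 60)] <- 1L
  a[137] <- 1L  # action 1 last occurs exactly at step 137
  traj <- fixture_trajectory(rnorm(300), a)
  st <- stoppage_times(traj)
  expect_equal(st$last_step[1], 137L)
  expect_false(st$censored[1])
  expect_true(st$censored[2])  # the winner is still sampled at the end

  # an action that never occurs
  traj3 <- fixture_trajectory(rnorm(100), rep(c(1L, 2L), 50), n_actions = 3L)
  st3 <- stoppage_times(traj3)
  expect_true(is.na(st3$last_step[3]))
  expect_false(st3$sampled[3])
})

test_that("constructed behavior archetypes are labeled correctly", {
  set.seed(42)
  s <- rnorm(400)

  disc <- fixture_trajectory(s, apply_label_noise(rule_threshold(0, 2L)(s),
                                                  0.02))
  expect_equal(classify_run(disc)$label, "full_discrimination")

  mixed <- fixture_trajectory(s, rule_independent()(s))
  expect_equal(classify_run(mixed)$label, "intermingled")

  sand <- fixture_trajectory(s, rule_sandwich(0.5)(s))
  expect_equal(classify_run(sand)$label, "sandwich")

  half <- seq_along(s) <= 200
  sw <- integer(400)
  sw[half] <- rule_threshold(0, 2L)(s[half])
  sw[!half] <- rule_threshold(0, 1L)(s[!half])
  switching <- fixture_trajectory(s, sw)
  expect_equal(classify_run(switching)$label, "switching")

  dom <- fixture_trajectory(s, rule_dominant(2L)(s))
  expect_equal(classify_run(dom)$label, "non_discriminating")
})

test_that("every trajectory receives exactly one label, short runs flagged", {
  set.seed(43)
  short <- fixture_trajectory(rnorm(60), sample(1:2, 60, replace = TRUE))
  lab <- classify_run(short)
  expect_true(lab$label %in% c("full_discrimination", "intermingled",
                               "sandwich", "switching", "non_discriminating"))
  expect_match(lab$detail, "short-run")
})

test_that("classifier reaches 95% accuracy on a labeled synthetic bank", {
  set.seed(44)
  labels <- rep(c("full_discrimination", "intermingled", "sandwich",
                  "switching", "non_discriminating"),
                times = c(150, 100, 100, 75, 75))
  got <- vapply(labels, function(lb) {
    classify_run(make_labeled_trajectory(lb))$label
  }, character(1))
  accuracy <- mean(got == labels)
  expect_gte(accuracy, 0.95)
})

test_that("dominance direction tracks which action owns positive stimuli", {
  set.seed(45)
  s <- rnorm(400)
  expect_equal(dominance_direction(fixture_trajectory(s, rule_threshold(0, 2L)(s))),
               "action2_positive")
  expect_equal(dominance_direction(fixture_trajectory(s, rule_threshold(0, 1L)(s))),
               "action1_positive")
})

test_that("stoppage regression recovers exact linear structure", {
  x <- c(100, 150, 220, 300, 410)
  fit <- stoppage_regression(x, x + 20)
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 20, tolerance = 1e-9)

  set.seed(46)
  x <- rnorm(200, 200, 50)
  y <- sample(x + 20)  # shuffled pairing destroys the correlation
  expect_lt(abs(stoppage_regression(x, y)$r), 0.2)

  expect_error(stoppage_regression(c(1, 2), c(3, 4)), "at least 3")
})

test_that("batches are reproducible and aggregate consistently", {
  cfg <- sim_config(n_steps = 120L)
  a <- suppressMessages(batch_run(cfg, n_runs = 4L, seed_base = 11L))
  b <- suppressMessages(batch_run(cfg, n_runs = 4L, seed_base = 11L))
  expect_identical(a$labels, b$labels)
  expect_identical(a$first_stoppage, b$first_stoppage)
  expect_identical(a$behavior_freq, b$behavior_freq)
  expect_equal(sum(a$behavior_freq$pct), 100)
  expect_equal(a$n_runs, 4L)
  expect_error(batch_run(cfg, n_runs = 1L), "n_runs")
})

test_that("lambda sweep tabulates dominance and stoppage per lambda", {
  cfg <- sim_config(n_steps = 150L)
  sweep <- suppressMessages(
    lambda_sweep(cfg, c(0, 1), n_runs = 4L, seed_base = 21L))
  expect_equal(nrow(sweep), 2L)
  expect_identical(names(sweep),
                   c("lambda", "pct_action2_positive", "se", "mean_stoppage",
                     "sd_stoppage", "n_censored"))
  # pure reward weighting: every run keeps both actions (all censored)
  expect_equal(sweep$n_censored[sweep$lambda == 1], 4L)
  expect_equal(sweep$pct_action2_positive[sweep$lambda == 1], 100)
})
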