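test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_dataset(4, seed = 11)
  b <- simulate_dataset(4, seed = 11)
  expect_identical(a$trials, b$trials)
  expect_identical(a$participants, b$participants)
  expect_identical(a$truth$participants, b$truth$participants)
  c <- simulate_dataset(4, seed = 12)
  expect_false(identical(a$trials$invigoration, c$trials$invigoration))
})

test_that("every session covers the 8 condition cells equally", {
  ds <- simulate_dataset(2, seed = 5)
  counts <- with(ds$trials,
                 table(participant, session, reward_type,
                       reward_magnitude, difficulty))
  expect_true(all(counts == 6))
  # stimulation is a session property, balanced across order
  stim_per_sess <- unique(ds$trials[c("participant", "session",
                                      "stimulation")])
  expect_equal(nrow(stim_per_sess), 4L)
  expect_true(all(tapply(stim_per_sess$stimulation,
                         stim_per_sess$participant, sum) == 1))
})

test_that("ball EMA follows the stated recurrence and stays in the input range", {
  expect_equal(ball_ema(rep(3.7, 50)), rep(3.7, 50))  # fixed point
  s <- ball_ema(c(0, 1, 1), lambda = 0.6)
  expect_equal(s, c(0, 0.6, 0.84))
  expect_identical(ball_ema(numeric(0)), numeric(0))
  expect_error(ball_ema(c(-1, 2)), ">= 0")
  set.seed(1)
  for (i in 1:50) {
    x <- runif(60, 0, 100)
    s <- ball_ema(x)
    expect_true(all(s >= min(x) - 1e-12 & s <= max(x) + 1e-12))
  }
})

test_that("reward accrual pays completed seconds only and matches a brute-force scan", {
  rate <- 10
  expect_equal(accrue_reward(rep(90, 79), 0.85, 10, rate), 70)
  expect_equal(accrue_reward(rep(50, 300), 0.75, 1, rate), 0)
  brute <- function(s, thr, pts, rate) {
    above <- s >= thr * 100
    tokens <- 0; run <- 0
    for (a in above) {
      if (a) {
        run <- run + 1
        if (run == rate) { tokens <- tokens + pts; run <- 0 }
      } else run <- 0
    }
    tokens
  }
  set.seed(2)
  for (i in 1:200) {
    s <- runif(120, 0, 100)
    expect_equal(accrue_reward(s, 0.75, 10, rate), brute(s, 0.75, 10, rate))
  }
})

test_that("token-to-unit conversion floors at the stated exchange rate", {
  expect_equal(tokens_to_units(70), 14)
  expect_equal(tokens_to_units(0), 0)
  expect_equal(tokens_to_units(4), 0)
  expect_error(tokens_to_units(-1), ">= 0")
})

test_that("a noise-free work bout is an exact trapezoid; vanishing work degenerates to rest", {
  cfg <- task_config()
  s <- simulate_press_series(ramp_rate = 40, plateau = 80, work_mean = 40,
                             rest_mean = 2, config = cfg)
  t <- seq_len(300) / 10
  expect_equal(as.numeric(s), pmin(40 * t, 80))
  s0 <- simulate_press_series(ramp_rate = 40, plateau = 80, work_mean = 0,
                              rest_mean = 2, config = cfg)
  expect_true(all(s0 == 0))
  expect_true(attr(s0, "degenerate"))
})

test_that("simulated bout durations match the log-normal duration model", {
  cfg <- task_config(trial_duration = 300)
  work_mean <- 6; rest_mean <- 2.5; sdlog <- 0.25
  set.seed(31)
  draws <- numeric(0)
  for (i in 1:300) {
    s <- simulate_press_series(40, 80, work_mean, rest_mean, cfg,
                               duration_noise_sd = sdlog)
    keep <- attr(s, "bout_kind") == "work" & !attr(s, "bout_truncated")
    draws <- c(draws, (attr(s, "bout_end") - attr(s, "bout_start"))[keep])
  }
  expect_gt(length(draws), 9000)
  expected <- work_mean * exp(sdlog^2 / 2)  # log-normal mean
  expect_lt(abs(mean(draws) - expected) / expected, 0.02)
})

test_that("ratings track reward magnitude, difficulty and realized effort", {
  gp <- gen_params(wanting_noise_sd = 0, exertion_noise_sd = 0)
  w_hi <- simulate_ratings(1, 0, 50, 0, gp)[["wanting"]]
  w_lo <- simulate_ratings(0, 0, 50, 0, gp)[["wanting"]]
  expect_gt(w_hi, w_lo)
  # zero-effort trial: exertion sits at its intercept
  e0 <- simulate_ratings(0, 0, 0, 0, gp)[["exertion"]]
  expect_equal(e0, gp$exertion_intercept)
  e_hard <- simulate_ratings(0, 1, 0, 0, gp)[["exertion"]]
  expect_equal(e_hard, gp$exertion_intercept + gp$exertion_diff)
})

test_that("with stimulation effects silenced, taVNS and sham differ only by noise", {
  ds <- simulate_dataset(200, params = null_gen_params(), seed = 77)
  per <- with(ds$trials, tapply(invigoration, list(participant, stimulation),
                                mean, na.rm = TRUE))
  expect_gt(t.test(per[, "1"] - per[, "0"])$p.value, 0.001)
  per_m <- with(ds$trials, tapply(maintenance, list(participant, stimulation),
                                  mean, na.rm = TRUE))
  expect_gt(t.test(per_m[, "1"] - per_m[, "0"])$p.value, 0.001)
})

test_that("condition-mean differences converge to the configured effects", {
  gp <- gen_params()
  ds <- simulate_dataset(500, params = gp, seed = 99)
  tr <- ds$trials
  paired_diff <- function(value, code) {
    per <- tapply(value, list(tr$participant, code), mean, na.rm = TRUE)
    d <- per[, "1"] - per[, "0"]
    c(mean(d), sd(d) / sqrt(length(d)))
  }
  # taVNS - sham mean invigoration: ramp_stim + ramp_stim_food / 2
  d <- paired_diff(tr$invigoration, tr$stimulation)
  expect_lt(abs(d[1] - (gp$ramp_stim + gp$ramp_stim_food / 2)), 3 * d[2])
  # high - low reward magnitude on invigoration: ramp_rewmag
  d <- paired_diff(tr$invigoration, tr$reward_magnitude)
  expect_lt(abs(d[1] - gp$ramp_rewmag), 3 * d[2])
  # taVNS raises mean invigoration
  expect_gt(mean(tr$invigoration[tr$stimulation == 1], na.rm = TRUE),
            mean(tr$invigoration[tr$stimulation == 0], na.rm = TRUE))
})

test_that("stored press series reproduce the recorded indices and tokens", {
  ds <- simulate_dataset(2, seed = 13, keep_series = TRUE)
  re <- extract_indices(ds, ds$config)
  expect_equal(re$trials$invigoration, ds$trials$invigoration)
  expect_equal(re$trials$maintenance, ds$trials$maintenance)
  expect_equal(re$trials$mean_work_len, ds$trials$mean_work_len)
  # token conservation: session totals equal the sum of per-trial tokens
  tot <- with(ds$trials, tapply(tokens_earned, list(participant, session), sum))
  expect_equal(sum(tot), sum(ds$trials$tokens_earned))
  expect_true(all(ds$trials$tokens_earned >= 0))
})

test_that("infeasible configurations are rejected", {
  expect_error(task_config(threshold_easy = 0.9, threshold_hard = 0.85),
               "threshold")
  expect_error(task_config(ema_lambda = 0), "lambda")
  expect_error(gen_params(press_noise_sd = -1), "sds")
  expect_error(simulate_dataset(1), "n_participants")
})
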