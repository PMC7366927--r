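test_that("predicted durations follow work = A/SE, rest = A/SR with dummy-coded effects", {
  p <- ce_params(se_sham = 0.2, se_diff = 0.05, se_tavns = 0.03,
                 sr_sham = 0.4, sr_rewmag = 0.1, sr_tavns = 0.05,
                 a_rewmag = 0.2, a_tavns = 0.1)
  d <- predict_durations(p, 0, 0, 0)
  expect_equal(d[["work"]], 5)          # A = 1, SE = 0.2
  expect_equal(d[["rest"]], 1 / 0.4)
  # sham predictions are independent of every taVNS term
  p0 <- ce_params(se_sham = 0.2, se_diff = 0.05, se_tavns = 0,
                  sr_sham = 0.4, sr_rewmag = 0.1, sr_tavns = 0,
                  a_rewmag = 0.2, a_tavns = 0)
  for (rm in 0:1) for (df in 0:1) {
    expect_equal(predict_durations(p, 0, rm, df),
                 predict_durations(p0, 0, rm, df))
  }
  # doubling A with slopes fixed doubles both durations
  p2 <- ce_params(se_sham = 0.2, sr_sham = 0.4, a_rewmag = 1,
                  sr_rewmag = 0, se_diff = 0)
  expect_equal(predict_durations(p2, 0, 1, 0),
               2 * predict_durations(p2, 0, 0, 0))
})

test_that("durations are monotone in the cost-evidence parameters", {
  se_grid <- seq(0.1, 0.5, by = 0.05)
  work <- vapply(se_grid, function(se) {
    predict_durations(ce_params(se_sham = se), 0, 0, 0)[["work"]]
  }, numeric(1))
  expect_true(all(diff(work) < 0))
  sr_grid <- seq(0.2, 0.8, by = 0.05)
  rest <- vapply(sr_grid, function(sr) {
    predict_durations(ce_params(sr_sham = sr), 0, 0, 0)[["rest"]]
  }, numeric(1))
  expect_true(all(diff(rest) < 0))
  a_grid <- seq(0, 0.8, by = 0.1)
  both <- t(vapply(a_grid, function(a) {
    predict_durations(ce_params(a_rewmag = a), 0, 1, 0)
  }, numeric(2)))
  expect_true(all(diff(both[, 1]) > 0) && all(diff(both[, 2]) > 0))
})

test_that("a non-positive realized cell is rejected, naming the cell", {
  expect_error(ce_params(se_sham = 0.1, se_diff = -0.2),
               "stim=0, rewmag=0, diff=1")
})

test_that("the duration log-likelihood is the closed-form log-normal sum", {
  p <- ce_params(duration_noise_sd = 0.5)
  b1 <- data.frame(kind = "work", duration = 1 / p$se_sham,
                   stimulation = 0, reward_magnitude = 0, difficulty = 0)
  mu <- log(1 / p$se_sham)
  closed <- -log(b1$duration * 0.5 * sqrt(2 * pi)) -
    (log(b1$duration) - mu)^2 / (2 * 0.5^2)
  expect_equal(ce_log_likelihood(p, b1), closed, tolerance = 1e-12)
  b2 <- data.frame(kind = c("work", "rest"), duration = c(4, 2),
                   stimulation = 0:1, reward_magnitude = 0:1,
                   difficulty = 0:1)
  expect_equal(ce_log_likelihood(p, rbind(b1, b2)),
               ce_log_likelihood(p, b1) + ce_log_likelihood(p, b2))
  expect_error(ce_log_likelihood(p, transform(b1, duration = -1)),
               "positive")
})

test_that("the likelihood is maximized at the generating accumulation slope", {
  true_se <- 0.15
  cells <- expand.grid(stimulation = 0:1, reward_magnitude = 0:1,
                       difficulty = 0:1)
  make_bouts <- function(se) {
    p <- ce_params(se_sham = se)
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      d <- predict_durations(p, cells$stimulation[i],
                             cells$reward_magnitude[i], cells$difficulty[i])
      data.frame(kind = c("work", "rest"), duration = unname(d),
                 cells[i, ], row.names = NULL)
    }))
  }
  bouts <- make_bouts(true_se)
  grid <- seq(0.08, 0.30, by = 0.001)
  ll <- vapply(grid, function(se)
    ce_log_likelihood(ce_params(se_sham = se), bouts), numeric(1))
  expect_equal(grid[which.max(ll)], true_se, tolerance = 1e-9)
})

test_that("hierarchical fits are seed-reproducible and flag convergence honestly", {
  ds <- simulate_dataset(6, seed = 31)
  f1 <- suppressWarnings(fit_cost_evidence(ds$truth$bouts, n_adapt = 200,
                                           n_burn = 200, n_draws = 400,
                                           thin = 1, seed = 9))
  f2 <- suppressWarnings(fit_cost_evidence(ds$truth$bouts, n_adapt = 200,
                                           n_burn = 200, n_draws = 400,
                                           thin = 1, seed = 9))
  expect_equal(f1$summary, f2$summary)
  expect_type(f1$converged, "logical")
  expect_equal(nrow(f1$participant_means), 6L)
  expect_error(fit_cost_evidence(ds$truth$bouts[
    ds$truth$bouts$participant == "P001", ]), "participant")
})

test_that("a large injected taVNS effect on SE is detected", {
  gp <- gen_params(ce = ce_params(se_tavns = 0.05))
  ds <- simulate_dataset(8, params = gp, seed = 53)
  fit <- suppressWarnings(fit_cost_evidence(ds$truth$bouts, n_adapt = 300,
                                            n_burn = 300, n_draws = 800,
                                            seed = 53))
  s <- fit$summary[fit$summary$parameter == "se_tavns", ]
  expect_gt(s$ci_lower, 0)  # credible interval excludes 0
  expect_gt(as.numeric(tavns_bayes_factor(fit, "se_tavns")), 3)
})

test_that("Savage-Dickey density ratio behaves like a Bayes factor", {
  set.seed(14)
  # posterior equal to the prior: BF10 = 1
  draws <- rcauchy(50000, 0, 0.707)
  expect_equal(as.numeric(tavns_bayes_factor(draws)), 1, tolerance = 0.1)
  # posterior tightly concentrated at 0 favors the null
  expect_lt(as.numeric(tavns_bayes_factor(rnorm(5000, 0, 0.01))), 0.1)
  # analytic normal posterior: matches the exact density ratio
  post <- rnorm(50000, 0.3, 0.1)
  exact <- dcauchy(0, 0, 0.707) / dnorm(0, 0.3, 0.1)
  expect_equal(as.numeric(tavns_bayes_factor(post)), exact,
               tolerance = 0.05)
  # no posterior mass near 0: lower-bound flag
  far <- rnorm(2000, 50, 0.5)
  bf <- tavns_bayes_factor(far)
  expect_true(isTRUE(attr(bf, "lower_bound")))
  expect_gt(as.numeric(bf), 1e6)
})

test_that("posterior-predictive segment lengths recover the data; shuffling labels degrades them", {
  ds <- simulate_dataset(8, seed = 61)
  fit <- suppressWarnings(fit_cost_evidence(ds$truth$bouts, n_adapt = 300,
                                            n_burn = 300, n_draws = 600,
                                            seed = 61))
  rec <- posterior_predictive_segments(fit, ds$truth$bouts)
  expect_gt(attr(rec, "correlation"), 0.9)
  expect_equal(attr(rec, "slope"), 1, tolerance = 0.2)
  # negative control: shuffled participant labels collapse the fit toward
  # the group mean prediction
  set.seed(1)
  shuffled <- ds$truth$bouts
  relabel <- sample(unique(shuffled$participant))
  names(relabel) <- unique(shuffled$participant)
  shuffled$participant <- unname(relabel[shuffled$participant])
  rec_s <- posterior_predictive_segments(fit, shuffled)
  expect_lt(attr(rec_s, "correlation"), attr(rec, "correlation"))
})
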