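#' Task configuration
#'
#' Static parameters of the effort-allocation task: 48 trials per session, an
#' effort phase of 30 s sampled at 10 Hz, difficulty thresholds alternating
#' between 75% and 85% of the individual maximum press frequency, exponential
#' ball smoothing with weight 0.6, reward rates of 1 (low) or 10 (high)
#' points per completed second above threshold, and 5 tokens per kcal/cent.
#'
#' @param n_trials trials per session (48).
#' @param trial_duration effort-phase duration in seconds (30, matching the
#'   30-s stimulation bursts aligned with the effort phases).
#' @param sample_rate press-rate sampling rate in Hz (10).
#' @param threshold_easy,threshold_hard difficulty thresholds as fractions of
#'   the maximum frequency (0.75 / 0.85).
#' @param ema_lambda exponential smoothing weight for the ball (0.6).
#' @param points_per_s_low,points_per_s_high reward rates (1 / 10 points per
#'   completed second above threshold).
#' @param tokens_per_unit tokens per kcal or per cent (5).
#' @param plateau_margin percentage points above the difficulty threshold at
#'   which work-bout plateaus sit, guaranteeing reward accrual during work
#'   (default 5).
#' @param work_threshold segmentation threshold in % of maximum (default 10).
#' @param min_bout minimum segment duration in seconds (default 0.3).
#' @param plateau_prominence minimum rise for plateau detection (default 5).
#' @param difficulty_schedule `"alternating"` (easy/hard alternate trial by
#'   trial) or `"random"` (cell-balanced random order).
#' @return object of class `task_config`.
#' @export
task_config <- function(n_trials = 48, trial_duration = 30, sample_rate = 10,
                        threshold_easy = 0.75, threshold_hard = 0.85,
                        ema_lambda = 0.6, points_per_s_low = 1,
                        points_per_s_high = 10, tokens_per_unit = 5,
                        plateau_margin = 5, work_threshold = 10,
                        min_bout = 0.3, plateau_prominence = 5,
                        difficulty_schedule = c("alternating", "random")) {
  difficulty_schedule <- match.arg(difficulty_schedule)
  cfg <- as.list(environment())
  if (!(threshold_easy > 0 && threshold_easy < threshold_hard &&
        threshold_hard < 1)) {
    stop_field("need 0 < threshold_easy < threshold_hard < 1")
  }
  if (ema_lambda <= 0 || ema_lambda > 1) {
    stop_field("ema_lambda must be in (0, 1]")
  }
  if (!(points_per_s_high > points_per_s_low && points_per_s_low > 0)) {
    stop_field("need points_per_s_high > points_per_s_low > 0")
  }
  if (n_trials %% 8 != 0) {
    stop_field("n_trials must be a multiple of 8 so the condition cells balance")
  }
  class(cfg) <- "task_config"
  cfg
}

#' Generative parameters of the synthetic crossover dataset
#'
#' Ground truth for the simulator. Invigoration ramp rates are in %/s and
#' default to the magnitude of effects observed in taVNS effort studies of
#' this design (intercept near 55 %/s, reward-magnitude effect near +5.8,
#' difficulty effect near -2.4, additive taVNS effect +2.9 with a +1.3
#' taVNS-by-food interaction). Bout durations follow the cost-evidence model
#' in `ce`; its taVNS terms default to 0 (no stimulation effect on
#' cost-evidence accumulation). A trial-level motivation fluctuation couples
#' invigoration, wanting ratings and (weakly) work-bout length, so that
#' invigoration relates to wanting but not exertion while maintenance
#' relates to both.
#'
#' @param ramp_base mean invigoration ramp rate, %/s.
#' @param ramp_rewmag additive effect of high reward magnitude, %/s.
#' @param ramp_diff additive effect of hard difficulty, %/s.
#' @param ramp_stim additive taVNS effect, %/s.
#' @param ramp_stim_food additional taVNS effect on food-reward trials, %/s.
#' @param ramp_participant_sd between-participant sd of the ramp rate, %/s.
#' @param ramp_stim_participant_sd between-participant sd of the individual
#'   taVNS effect on the ramp rate, %/s; individual stimulation responses
#'   vary around the group effect, matching the random stimulation slopes of
#'   the crossover mixed model.
#' @param motivation_sd sd of the trial-level motivation fluctuation, %/s.
#' @param motivation_work_coef effect of the motivation fluctuation on log
#'   work-bout duration (per %/s).
#' @param press_noise_sd within-bout plateau jitter, percentage points.
#' @param ce group-level true [ce_params()].
#' @param ce_participant_sd named list of between-participant sds for the
#'   free cost-evidence parameters.
#' @param wanting_intercept,wanting_rewmag,wanting_motivation,wanting_noise_sd
#'   wanting-rating model (VAS units): intercept, reward-magnitude effect,
#'   loading on the motivation fluctuation, residual sd.
#' @param exertion_intercept,exertion_diff,exertion_maintenance,exertion_noise_sd
#'   exertion-rating model: intercept, difficulty effect, loading on realized
#'   maintenance (VAS units per %), residual sd.
#' @return object of class `gen_params`.
#' @export
gen_params <- function(ramp_base = 55.3, ramp_rewmag = 5.8,
                       ramp_diff = -2.4, ramp_stim = 2.9,
                       ramp_stim_food = 1.3, ramp_participant_sd = 8,
                       ramp_stim_participant_sd = 2,
                       motivation_sd = 6, motivation_work_coef = 0.01,
                       press_noise_sd = 4,
                       ce = ce_params(),
                       ce_participant_sd = list(
                         se_sham = 0.03, se_diff = 0.015, se_tavns = 0.01,
                         sr_sham = 0.08, sr_rewmag = 0.03, sr_tavns = 0.01,
                         a_rewmag = 0.05, a_tavns = 0.01),
                       wanting_intercept = 4, wanting_rewmag = 1.5,
                       wanting_motivation = 0.12, wanting_noise_sd = 1,
                       exertion_intercept = 2.5, exertion_diff = 1,
                       exertion_maintenance = 0.03,
                       exertion_noise_sd = 1) {
  gp <- as.list(environment())
  if (gp$ramp_base + min(0, gp$ramp_diff) + min(0, gp$ramp_rewmag) <= 0) {
    stop_field("ramp rates must stay positive in every condition cell")
  }
  sds <- c(ramp_participant_sd, ramp_stim_participant_sd, motivation_sd,
           press_noise_sd,
           wanting_noise_sd, exertion_noise_sd,
           unlist(ce_participant_sd))
  if (any(sds < 0)) stop_field("noise sds must be >= 0")
  class(gp) <- "gen_params"
  gp
}

#' Simulate one trial's press-rate series
#'
#' The series alternates work bouts and rest. A work bout ramps linearly from
#' 0 at `ramp_rate` %/s up to a plateau (`plateau` % of maximum, jittered by
#' `press_noise_sd`); during rest the press rate is 0 (the on-screen ball,
#' i.e. the smoothed series, decays geometrically). Bout durations are drawn
#' log-normally around the cost-evidence means `work_mean` and `rest_mean`
#' (multiplicative noise, log-sd `duration_noise_sd`), and the series is
#' truncated at the trial duration. Degenerate parameters (vanishing work
#' duration) produce an all-rest series, flagged via the `degenerate`
#' attribute.
#'
#' @param ramp_rate invigoration ramp rate, %/s (> 0).
#' @param plateau plateau height, % of maximum.
#' @param work_mean,rest_mean model-implied mean bout durations, s.
#' @param config a [task_config()].
#' @param duration_noise_sd log-scale sd of bout durations (0 = exact).
#' @param press_noise_sd plateau jitter sd in percentage points.
#' @return numeric series of length `round(sample_rate * trial_duration)`
#'   with attributes `bout_kind`, `bout_start`, `bout_end` (the generating
#'   schedule, truncated to the trial) and `degenerate`.
#' @export
simulate_press_series <- function(ramp_rate, plateau, work_mean, rest_mean,
                                  config = task_config(),
                                  duration_noise_sd = 0,
                                  press_noise_sd = 0) {
  stopifnot(ramp_rate > 0, plateau > 0, work_mean >= 0, rest_mean > 0)
  dt <- 1 / config$sample_rate
  n <- round(config$sample_rate * config$trial_duration)
  tt <- seq_len(n) * dt
  values <- numeric(n)
  kind <- character(0); b_start <- numeric(0); b_end <- numeric(0)
  b_trunc <- logical(0)
  t0 <- 0; working <- TRUE
  while (t0 < config$trial_duration) {
    mean_d <- if (working) work_mean else rest_mean
    d <- if (duration_noise_sd > 0) {
      mean_d * exp(rnorm(1, 0, duration_noise_sd))
    } else mean_d
    t1 <- min(t0 + d, config$trial_duration)
    if (working && d > dt / 2) {
      in_bout <- tt > t0 & tt <= t1
      v <- pmin(ramp_rate * (tt[in_bout] - t0), plateau)
      if (press_noise_sd > 0) {
        at_plateau <- v >= plateau
        v[at_plateau] <- pmax(0, v[at_plateau] +
                                rnorm(sum(at_plateau), 0, press_noise_sd))
      }
      values[in_bout] <- v
      kind <- c(kind, "work")
    } else if (!working) {
      kind <- c(kind, "rest")
    } else {
      kind <- c(kind, "rest")  # vanishing work bout degenerates to rest
    }
    b_start <- c(b_start, t0); b_end <- c(b_end, t1)
    b_trunc <- c(b_trunc, t0 + d > config$trial_duration)
    t0 <- t1
    working <- !working
  }
  attr(values, "bout_kind") <- kind
  attr(values, "bout_start") <- b_start
  attr(values, "bout_end") <- b_end
  attr(values, "bout_truncated") <- b_trunc
  attr(values, "degenerate") <- all(values == 0)
  values
}

#' Reward accrual from the smoothed series
#'
#' Only completed seconds are rewarded: within each maximal run of samples in
#' which the (smoothed) series stays at or above the difficulty threshold,
#' every complete 1-s window earns `points_per_s` points.
#'
#' @param smoothed smoothed press-rate series (% of maximum).
#' @param threshold difficulty threshold as a fraction of maximum (in (0,1)).
#' @param points_per_s reward rate.
#' @param sample_rate sampling rate in Hz.
#' @return tokens earned (non-negative integer).
#' @export
accrue_reward <- function(smoothed, threshold, points_per_s, sample_rate) {
  if (threshold <= 0 || threshold >= 1) {
    stop_field("threshold must be in (0, 1)")
  }
  r <- rle(smoothed >= threshold * 100)
  runs <- r$lengths[r$values]
  points_per_s * sum(floor(runs / sample_rate))
}

#' Convert tokens to reward units
#'
#' Tokens are exchanged at 1 kcal or 1 cent per `tokens_per_unit` tokens;
#' only whole units are paid out.
#'
#' @param tokens non-negative token count.
#' @param tokens_per_unit exchange rate (default 5).
#' @return units (kcal or cents).
#' @export
tokens_to_units <- function(tokens, tokens_per_unit = 5) {
  if (any(tokens < 0)) stop_field("tokens must be >= 0")
  floor(tokens / tokens_per_unit)
}

#' Simulate post-trial wanting and exertion ratings
#'
#' Wanting (benefit proxy) increases with reward magnitude and loads on the
#' trial's motivation fluctuation (which also drives invigoration); exertion
#' (cost proxy) increases with difficulty and with the realized effort
#' maintenance. Gaussian noise is added and ratings are clipped to the VAS.
#'
#' @param reward_magnitude,difficulty dummy codes (0/1).
#' @param maintenance realized effort maintenance of the trial (%).
#' @param motivation the trial's motivation fluctuation (%/s).
#' @param params a [gen_params()].
#' @param vas_scale VAS upper bound.
#' @return named vector `c(wanting = , exertion = )`.
#' @export
simulate_ratings <- function(reward_magnitude, difficulty, maintenance,
                             motivation, params = gen_params(),
                             vas_scale = 10) {
  wanting <- params$wanting_intercept +
    params$wanting_rewmag * reward_magnitude +
    params$wanting_motivation * motivation +
    rnorm(1, 0, params$wanting_noise_sd)
  exertion <- params$exertion_intercept +
    params$exertion_diff * difficulty +
    params$exertion_maintenance * maintenance +
    rnorm(1, 0, params$exertion_noise_sd)
  c(wanting = min(max(wanting, 0), vas_scale),
    exertion = min(max(exertion, 0), vas_scale))
}

session_schedule <- function(config) {
  # 8 condition cells, 6 repeats each; difficulty alternates (or is drawn
  # at random) and reward type x magnitude is shuffled within difficulty
  per_diff <- config$n_trials / 2
  if (config$difficulty_schedule == "alternating") {
    difficulty <- rep(c(0, 1), length.out = config$n_trials)
  } else {
    difficulty <- sample(rep(c(0, 1), each = per_diff))
  }
  combos <- expand.grid(reward_type = 0:1, reward_magnitude = 0:1)
  out <- data.frame(trial_index = seq_len(config$n_trials),
                    difficulty = difficulty,
                    reward_type = NA_real_, reward_magnitude = NA_real_)
  for (d in 0:1) {
    rows <- which(difficulty == d)
    cells <- combos[sample(rep(seq_len(4), per_diff / 4)), ]
    out$reward_type[rows] <- cells$reward_type
    out$reward_magnitude[rows] <- cells$reward_magnitude
  }
  out
}

draw_participant_ce <- function(gp) {
  # participant-level true parameters around the group truth; redraw until
  # every condition cell realizes positive A, SE, SR
  for (attempt in 1:100) {
    vals <- lapply(ce_free_names, function(f) {
      rnorm(1, gp$ce[[f]], gp$ce_participant_sd[[f]])
    })
    names(vals) <- ce_free_names
    p <- try(do.call(ce_params, c(vals, list(
      duration_noise_sd = gp$ce$duration_noise_sd))), silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
  stop_field("could not draw positive participant-level CE parameters")
}

#' Simulate a complete two-session crossover dataset
#'
#' Generates `n_participants` x 2 sessions x `n_trials` trials with balanced
#' assignment of stimulation order (taVNS first vs. second) and stimulation
#' side (left vs. right ear). Each session covers all 8 condition cells
#' equally (6 repeats per cell at 48 trials). Per trial, a press-rate series
#' is simulated from the participant's true cost-evidence parameters and
#' ramp rate, the motivation indices are extracted with the same machinery
#' applied to real data ([extract_trial_indices()]), reward is accrued from
#' the smoothed series, and ratings are drawn. Ground truth is attached for
#' recovery tests. Identical seeds give bit-identical datasets.
#'
#' @param n_participants number of participants (>= 2).
#' @param config a [task_config()].
#' @param params a [gen_params()].
#' @param seed integer seed.
#' @param keep_series store the press-rate series in the dataset's `press`
#'   table (default `FALSE`; they are always simulated, only storage is
#'   optional).
#' @param keep_bouts store the realized generating bout schedule (`truth$bouts`)
#'   for cost-evidence fitting harnesses (default `TRUE`).
#' @return an [effort_dataset()] with `truth` containing `params`, the
#'   per-participant true parameter table, and (optionally) realized bouts.
#' @export
simulate_dataset <- function(n_participants, config = task_config(),
                             params = gen_params(), seed = 1,
                             keep_series = FALSE, keep_bouts = TRUE) {
  stopifnot(inherits(config, "task_config"), inherits(params, "gen_params"))
  if (n_participants < 2) stop_field("need n_participants >= 2")
  set.seed(derive_seed(seed, "design"))
  ids <- sprintf("P%03d", seq_len(n_participants))
  participants <- tibble(
    participant = ids,
    stim_order = rep(c(0, 1), length.out = n_participants),
    stim_side = rep(c(0, 0, 1, 1), length.out = n_participants),
    max_press_frequency = pmax(3, rnorm(n_participants, 6, 1))
  )
  nt <- config$n_trials
  n_row <- n_participants * 2 * nt
  tr <- list(participant = character(n_row), session = integer(n_row),
             trial_index = integer(n_row), stimulation = numeric(n_row),
             reward_type = numeric(n_row), reward_magnitude = numeric(n_row),
             difficulty = numeric(n_row), wanting = numeric(n_row),
             exertion = numeric(n_row), invigoration = numeric(n_row),
             maintenance = numeric(n_row), n_work_segments = numeric(n_row),
             mean_work_len = numeric(n_row), mean_rest_len = numeric(n_row),
             tokens_earned = numeric(n_row))
  truth_rows <- vector("list", n_participants)
  press_acc <- if (keep_series) vector("list", n_row) else NULL
  bout_acc <- if (keep_bouts) vector("list", n_row) else NULL
  n_samp <- round(config$sample_rate * config$trial_duration)
  row <- 0L
  for (i in seq_len(n_participants)) {
    set.seed(derive_seed(seed, "participant", i))
    ce_i <- draw_participant_ce(params)
    ramp_i <- params$ramp_base + rnorm(1, 0, params$ramp_participant_sd)
    stim_eff_i <- params$ramp_stim +
      rnorm(1, 0, params$ramp_stim_participant_sd)
    truth_rows[[i]] <- c(ramp = ramp_i, ramp_stim = stim_eff_i,
                         unlist(ce_i[ce_free_names]))
    for (s in 1:2) {
      set.seed(derive_seed(seed, "session", i, s))
      stim <- as.numeric((participants$stim_order[i] == 1) == (s == 1))
      sched <- session_schedule(config)
      for (k in seq_len(nt)) {
        row <- row + 1L
        rm <- sched$reward_magnitude[k]; df <- sched$difficulty[k]
        rt <- sched$reward_type[k]
        m <- rnorm(1, 0, params$motivation_sd)
        ramp <- ramp_i + params$ramp_rewmag * rm + params$ramp_diff * df +
          stim * (stim_eff_i + params$ramp_stim_food * rt) + m
        ramp <- max(ramp, 5)
        cell <- realize_ce(ce_i, stim, rm, df)
        thr <- if (df == 1) config$threshold_hard else config$threshold_easy
        series <- simulate_press_series(
          ramp_rate = ramp, plateau = thr * 100 + config$plateau_margin,
          work_mean = (cell$A / cell$SE) *
            exp(params$motivation_work_coef * m),
          rest_mean = cell$A / cell$SR, config = config,
          duration_noise_sd = ce_i$duration_noise_sd,
          press_noise_sd = params$press_noise_sd)
        idx <- extract_fast(series, config)
        smoothed <- ball_ema(series, config$ema_lambda)
        pts <- if (rm == 1) config$points_per_s_high else
          config$points_per_s_low
        rat <- simulate_ratings(rm, df, idx[2], m, params)
        tr$participant[row] <- ids[i]; tr$session[row] <- s
        tr$trial_index[row] <- k; tr$stimulation[row] <- stim
        tr$reward_type[row] <- rt; tr$reward_magnitude[row] <- rm
        tr$difficulty[row] <- df
        tr$wanting[row] <- rat[[1]]; tr$exertion[row] <- rat[[2]]
        tr$invigoration[row] <- idx[1]; tr$maintenance[row] <- idx[2]
        tr$n_work_segments[row] <- idx[3]
        tr$mean_work_len[row] <- idx[4]; tr$mean_rest_len[row] <- idx[5]
        tr$tokens_earned[row] <- accrue_reward(smoothed, thr, pts,
                                               config$sample_rate)
        if (keep_series) press_acc[[row]] <- as.numeric(series)
        if (keep_bouts) {
          keep <- !attr(series, "bout_truncated")
          bout_acc[[row]] <- list(
            kind = attr(series, "bout_kind")[keep],
            duration = (attr(series, "bout_end") -
                          attr(series, "bout_start"))[keep])
        }
      }
    }
  }
  trials <- as_tibble(tr)
  tp <- do.call(rbind, truth_rows)
  truth <- list(params = params,
                participants = as_tibble(cbind(
                  tibble(participant = ids), as.data.frame(tp))))
  if (keep_bouts) {
    nb <- vapply(bout_acc, function(b) length(b$kind), integer(1))
    bouts <- tibble(
      participant = rep(tr$participant, nb),
      session = rep(tr$session, nb),
      trial_index = rep(tr$trial_index, nb),
      kind = unlist(lapply(bout_acc, `[[`, "kind")),
      duration = unlist(lapply(bout_acc, `[[`, "duration")),
      stimulation = rep(tr$stimulation, nb),
      reward_magnitude = rep(tr$reward_magnitude, nb),
      difficulty = rep(tr$difficulty, nb))
    truth$bouts <- bouts[bouts$duration > 1 / config$sample_rate, ]
  }
  press <- if (keep_series) {
    tibble(
      participant = rep(tr$participant, each = n_samp),
      session = rep(tr$session, each = n_samp),
      trial_index = rep(tr$trial_index, each = n_samp),
      sample_index = rep(seq_len(n_samp), n_row),
      value = unlist(press_acc))
  }
  effort_dataset(trials, participants, press = press,
                 truth = truth, config = config)
}
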