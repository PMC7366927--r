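# fixtures built in code

# balanced crossover dataset with known fixed effects, no random condition
# slopes beyond an optional per-participant stimulation effect
make_balanced_dataset <- function(n_p = 8,
                                  beta = c(intercept = 50, stim = 3,
                                           rewmag = 5, diff = -2,
                                           rm_diff = 1.5),
                                  stim_by_participant = NULL,
                                  noise_sd = 1, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(stimulation = 0:1, reward_type = 0:1,
                      reward_magnitude = 0:1, difficulty = 0:1, rep = 1:3)
  ids <- sprintf("P%03d", seq_len(n_p))
  stim_order <- rep(c(0, 1), length.out = n_p)
  if (is.null(stim_by_participant)) {
    stim_by_participant <- rep(beta[["stim"]], n_p)
  }
  tr <- do.call(rbind, lapply(seq_len(n_p), function(i) {
    g <- grid
    g$participant <- ids[i]
    # stimulation is a session property in the crossover
    g$session <- ifelse(g$stimulation == ifelse(stim_order[i] == 1, 1, 0),
                        1L, 2L)
    g$invigoration <- beta[["intercept"]] +
      stim_by_participant[i] * g$stimulation +
      beta[["rewmag"]] * g$reward_magnitude +
      beta[["diff"]] * g$difficulty +
      beta[["rm_diff"]] * g$reward_magnitude * g$difficulty +
      rnorm(nrow(g), 0, noise_sd)
    g
  }))
  tr <- tr[order(tr$participant, tr$session), ]
  tr$trial_index <- rep(1:24, times = 2 * n_p)
  tr$wanting <- 5
  tr$exertion <- 5
  tr$maintenance <- 50
  tr$n_work_segments <- 1
  tr$mean_work_len <- 5
  tr$mean_rest_len <- 2
  tr$tokens_earned <- 0
  tr$rep <- NULL
  participants <- data.frame(
    participant = ids, stim_order = stim_order,
    stim_side = rep(c(0, 1), each = ceiling(n_p / 2))[seq_len(n_p)],
    max_press_frequency = 6)
  effort_dataset(tr, participants)
}

# shared moderately sized simulation reused across test files
shared_sim20 <- simulate_dataset(20, seed = 42)

# null generator: stimulation has no effect whatsoever (sharp null)
null_gen_params <- function() {
  gen_params(ramp_stim = 0, ramp_stim_food = 0, ramp_stim_participant_sd = 0)
}

# hierarchical null: individual taVNS effects vary but average zero,
# matching the mixed model's random-stimulation-slope assumption
hier_null_gen_params <- function() {
  gen_params(ramp_stim = 0, ramp_stim_food = 0)
}
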