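# Independent literal-loop oracle for the ideal observer: explicit loops over
# every grid cell, no shared code with the package implementation.
oracle_observer <- function(chosen_pos, outcome, s = 0.05,
                            p_grid = seq(0.30, 1.00, by = 0.01),
                            payout_low = 0.2) {
  np <- length(p_grid)
  post <- matrix(1 / (4 * np), nrow = 4, ncol = np)
  snapshots <- vector("list", length(chosen_pos))
  for (t in seq_along(chosen_pos)) {
    lik <- matrix(NA_real_, 4, np)
    for (h in 1:4) {
      for (j in 1:np) {
        q <- if (h == chosen_pos[t]) p_grid[j] else payout_low
        lik[h, j] <- if (outcome[t] == 1) q else 1 - q
      }
    }
    tot <- 0
    for (h in 1:4) for (j in 1:np) {
      post[h, j] <- post[h, j] * lik[h, j]
      tot <- tot + post[h, j]
    }
    for (h in 1:4) for (j in 1:np) post[h, j] <- post[h, j] / tot
    snapshots[[t]] <- post
    prior <- matrix(NA_real_, 4, np)
    for (h in 1:4) for (j in 1:np) {
      prior[h, j] <- (1 - s) * post[h, j] + s / (4 * np)
    }
    post <- prior
  }
  snapshots
}

# Trial tibble for one run with fully specified choices/outcomes.
make_trials <- function(chosen, outcome, true_high = 0L, payout_high = 0.9,
                        run = 0L) {
  tibble::tibble(
    run = run, t = seq_along(chosen) - 1L,
    chosen = as.integer(chosen), outcome = as.integer(outcome),
    true_high = as.integer(true_high), payout_high = payout_high
  )
}

# Small cohort (trials + beliefs + labels) for pipeline tests.
make_small_cohort <- function(n_subjects = 2, n_trials = 60, n_runs = 2,
                              master_seed = 7L) {
  cfg <- task_config(n_trials_per_run = n_trials, n_runs = n_runs)
  trials <- simulate_cohort(cfg, n_subjects, agent_policy("softmax"),
                            master_seed = master_seed)
  trials <- label_trials(trials)
  beliefs <- run_observer_cohort(trials, available_ids = cfg$available_ids)
  list(config = cfg, trials = trials, beliefs = beliefs,
       available = cfg$available_ids)
}
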