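#' Configuration for the restless four-armed bandit task
#'
#' Eight options exist in total but only four are available for selection in
#' any given run; one available option pays out with high probability (70% or
#' 90%) and the remaining three with 20%. The identity of the high-reward
#' option moves to one of the other three available options after a variable
#' number of trials (regime lengths drawn from a rounded normal with mean 20
#' and SD 5, truncated below at 1), independently of behaviour.
#'
#' @param n_options_total Total number of options on screen (default 8).
#' @param n_available Number of options selectable per run (default 4).
#' @param available_ids List (length `n_runs`) of integer vectors of option
#'   ids (0-based) available in each run. The default alternates two disjoint
#'   sets so that every option is available in exactly two runs, which is what
#'   allows cross-run pairs covering all options for decoding.
#' @param payout_low Reward probability of the low options (default 0.2).
#' @param payout_high_set Possible high payout rates (default `c(0.7, 0.9)`),
#'   re-drawn uniformly at every regime switch.
#' @param regime_mean,regime_sd Mean and SD (in trials) of regime length.
#' @param n_trials_per_run,n_runs Trials per run and number of runs.
#' @param seed Integer seed used when no explicit seed is passed downstream.
#' @return A list of class `task_config`.
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$payout_high_set
task_config <- function(n_options_total = 8,
                        n_available = 4,
                        available_ids = NULL,
                        payout_low = 0.2,
                        payout_high_set = c(0.7, 0.9),
                        regime_mean = 20,
                        regime_sd = 5,
                        n_trials_per_run = 200,
                        n_runs = 4,
                        seed = 1L) {
  if (is.null(available_ids)) {
    first <- seq_len(n_available) - 1L
    second <- seq_len(n_available) + n_available - 1L
    available_ids <- rep(list(first, second), length.out = n_runs)
  }
  cfg <- list(
    n_options_total = as.integer(n_options_total),
    n_available = as.integer(n_available),
    available_ids = lapply(available_ids, as.integer),
    payout_low = payout_low,
    payout_high_set = payout_high_set,
    regime_mean = regime_mean,
    regime_sd = regime_sd,
    n_trials_per_run = as.integer(n_trials_per_run),
    n_runs = as.integer(n_runs),
    seed = as.integer(seed)
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  if (!(cfg$payout_low > 0 && cfg$payout_low < min(cfg$payout_high_set))) {
    stop("task_config: payout_low must be in (0, min(payout_high_set))", call. = FALSE)
  }
  if (max(cfg$payout_high_set) > 1) {
    stop("task_config: payout rates must be probabilities", call. = FALSE)
  }
  if (cfg$n_available > cfg$n_options_total) {
    stop("task_config: n_available exceeds n_options_total", call. = FALSE)
  }
  if (cfg$regime_mean <= 0) stop("task_config: regime_mean must be positive", call. = FALSE)
  if (length(cfg$available_ids) != cfg$n_runs) {
    stop("task_config: available_ids must have one entry per run", call. = FALSE)
  }
  ok <- vapply(cfg$available_ids, function(a) {
    length(a) == cfg$n_available && all(a >= 0 & a < cfg$n_options_total) && !anyDuplicated(a)
  }, logical(1))
  if (!all(ok)) stop("task_config: invalid available_ids", call. = FALSE)
  invisible(cfg)
}

# Draw regime lengths (rounded normal, truncated below at 1) summing past
# n_trials, then cut back to the run length.
draw_regime_lengths <- function(n_trials, regime_mean, regime_sd) {
  lens <- integer(0)
  while (sum(lens) < n_trials) {
    l <- max(1L, as.integer(round(rnorm(1, regime_mean, regime_sd))))
    lens <- c(lens, l)
  }
  lens
}

#' Generate the hidden environment timeline for every run
#'
#' Regime lengths are drawn as `round(Normal(regime_mean, regime_sd))`
#' truncated below at one trial. At every regime boundary the high-reward
#' option moves uniformly to one of the other three available options and its
#' payout rate is re-drawn uniformly from `payout_high_set`. Switches are
#' independent of agent behaviour.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble with one row per trial: `run`, `t` (0-based within run),
#'   `true_high` (option id), `payout_high`. Regime boundary indices per run
#'   are stored in `attr(, "regime_boundaries")`.
#' @export
#' @examples
#' env <- generate_environment(task_config(), seed = 7)
#' head(env)
generate_environment <- function(config, seed = config$seed) {
  validate_task_config(config)
  with_seed(seed, {
    runs <- purrr::map(seq_len(config$n_runs) - 1L, function(r) {
      avail <- config$available_ids[[r + 1L]]
      lens <- draw_regime_lengths(config$n_trials_per_run, config$regime_mean, config$regime_sd)
      n_reg <- length(lens)
      highs <- integer(n_reg)
      rates <- numeric(n_reg)
      highs[1] <- sample(avail, 1)
      rates[1] <- sample(config$payout_high_set, 1)
      if (n_reg > 1) {
        for (i in 2:n_reg) {
          highs[i] <- sample(setdiff(avail, highs[i - 1]), 1)
          rates[i] <- sample(config$payout_high_set, 1)
        }
      }
      true_high <- rep(highs, lens)[seq_len(config$n_trials_per_run)]
      payout_high <- rep(rates, lens)[seq_len(config$n_trials_per_run)]
      boundaries <- cumsum(lens)
      boundaries <- boundaries[boundaries < config$n_trials_per_run]
      list(
        tbl = tibble::tibble(
          run = r,
          t = seq_len(config$n_trials_per_run) - 1L,
          true_high = true_high,
          payout_high = payout_high
        ),
        boundaries = boundaries
      )
    })
    env <- dplyr::bind_rows(purrr::map(runs, "tbl"))
    attr(env, "regime_boundaries") <- purrr::map(runs, "boundaries")
    env
  })
}

#' Define an agent policy for the bandit simulation
#'
#' @param kind One of `"random"` (uniform over available options),
#'   `"greedy"` (argmax of the ideal observer's prior beliefs entering the
#'   trial, ties to the lowest option id), `"softmax"` (two-temperature
#'   softmax on prior beliefs: `beta_exploit` when the intended best option
#'   equals the previous choice, `beta_explore` otherwise), or `"replay"`
#'   (a fixed choice sequence).
#' @param beta_explore,beta_exploit Inverse temperatures for the softmax
#'   policy (acting on belief probabilities, so useful values are large).
#' @param choices Integer vector of option ids for `kind = "replay"`.
#' @return A list of class `agent_policy`.
#' @export
agent_policy <- function(kind = c("softmax", "random", "greedy", "replay"),
                         beta_explore = 4, beta_exploit = 12, choices = NULL) {
  kind <- match.arg(kind)
  if (kind == "replay" && is.null(choices)) {
    stop("replay policy requires a choice sequence", call. = FALSE)
  }
  structure(
    list(kind = kind, beta_explore = beta_explore,
         beta_exploit = beta_exploit, choices = choices),
    class = "agent_policy"
  )
}

#' Simulate one agent interacting with an environment timeline
#'
#' Outcomes are Bernoulli draws with rate `payout_high` when the chosen
#' option is the current high-reward option and `payout_low` otherwise.
#' Belief-based policies (`greedy`, `softmax`) consult the ideal observer
#' online, acting on the post-leak prior beliefs entering each trial.
#'
#' @param env Environment tibble from [generate_environment()].
#' @param config The [task_config()] used to generate `env`.
#' @param policy An [agent_policy()].
#' @param seed Integer seed for choices and outcomes.
#' @param observer_cfg An [observer_config()] for belief-based policies.
#' @return A tibble of trial records: `run`, `t`, `chosen`, `outcome`,
#'   `true_high`, `payout_high`, `iti_jitter` (seconds, uniform on 0-4;
#'   carried for fixture realism, unused by the trial-indexed analyses).
#' @export
#' @examples
#' cfg <- task_config(n_trials_per_run = 50, n_runs = 1)
#' env <- generate_environment(cfg, seed = 2)
#' trials <- run_agent(env, cfg, agent_policy("random"), seed = 3)
run_agent <- function(env, config, policy, seed = 1L,
                      observer_cfg = observer_config()) {
  stopifnot(inherits(policy, "agent_policy"))
  with_seed(seed, {
    out <- vector("list", config$n_runs)
    offset <- 0L
    for (r in seq_len(config$n_runs) - 1L) {
      env_r <- env[env$run == r, ]
      n <- nrow(env_r)
      avail <- sort(config$available_ids[[r + 1L]])
      belief <- if (policy$kind %in% c("greedy", "softmax")) init_belief(observer_cfg) else NULL
      chosen <- integer(n)
      outcome <- integer(n)
      prev_choice <- NA_integer_
      for (t in seq_len(n)) {
        ch <- switch(policy$kind,
          random = sample(avail, 1),
          replay = policy$choices[offset + t],
          greedy = {
            m <- belief_marginals(belief)
            avail[which.max(m)]
          },
          softmax = {
            m <- belief_marginals(belief)
            intended <- avail[which.max(m)]
            beta <- if (!is.na(prev_choice) && intended == prev_choice) {
              policy$beta_exploit
            } else {
              policy$beta_explore
            }
            pr <- exp(beta * m - logsumexp(beta * m))
            avail[sample.int(4, 1, prob = pr)]
          }
        )
        rate <- if (ch == env_r$true_high[t]) env_r$payout_high[t] else config$payout_low
        o <- rbinom(1, 1, rate)
        chosen[t] <- ch
        outcome[t] <- o
        prev_choice <- ch
        if (!is.null(belief)) {
          belief <- update_with_outcome(belief, match(ch, avail), o)
          belief <- apply_leak(belief, observer_cfg$s)
        }
      }
      out[[r + 1L]] <- tibble::tibble(
        run = r, t = env_r$t, chosen = chosen, outcome = outcome,
        true_high = env_r$true_high, payout_high = env_r$payout_high,
        iti_jitter = runif(n, 0, 4)
      )
      offset <- offset + n
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate a cohort of subjects on independent environments
#'
#' Each subject receives an independent, reproducible random substream
#' derived from the master seed, a fresh environment timeline, and a fresh
#' agent trajectory (default: four runs of 200 trials, i.e. 800 trials per
#' subject).
#'
#' @param config A [task_config()].
#' @param n_subjects Number of simulated subjects.
#' @param policy An [agent_policy()].
#' @param master_seed Integer master seed.
#' @param observer_cfg Observer configuration for belief-based policies.
#' @return A tibble of trial records with a leading `subject` column (1-based).
#' @export
#' @examples
#' cohort <- simulate_cohort(task_config(n_trials_per_run = 40, n_runs = 2),
#'                           n_subjects = 2, agent_policy("random"),
#'                           master_seed = 11)
#' dplyr::count(cohort, subject)
simulate_cohort <- function(config, n_subjects, policy, master_seed = 1L,
                            observer_cfg = observer_config()) {
  stopifnot(n_subjects >= 1)
  purrr::map_dfr(seq_len(n_subjects), function(s) {
    env <- generate_environment(config, seed = derive_seed(master_seed, s, 1))
    tr <- run_agent(env, config, policy, seed = derive_seed(master_seed, s, 2),
                    observer_cfg = observer_cfg)
    dplyr::bind_cols(tibble::tibble(subject = s), tr)
  })
}
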