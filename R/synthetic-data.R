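#' Configuration for synthetic multivoxel pattern generation
#'
#' Two region archetypes are generated. A `state_mixture` region encodes the
#' belief state probabilistically: each trial's pattern is a belief-weighted
#' mixture of fixed option prototypes, so decoding of the chosen option is
#' strong when uncertainty is low. An `action_code` region encodes only the
#' chosen action: the pattern is the chosen option's prototype (plus an
#' optional bleed toward a neighbouring option, emulating motor/visual
#' somatotopy) and never depends on beliefs.
#'
#' @param n_voxels Number of voxels in the region.
#' @param region_kind `"state_mixture"` or `"action_code"`.
#' @param gain Signal gain `g` multiplying the prototype mixture.
#' @param noise_sd Gaussian voxel noise SD added to every trial pattern.
#' @param neighbor_bleed Weight in `[0, 1)` of the adjacent option's prototype
#'   (action regions only; adjacency is the option-id ring `(id + 1) mod 8`).
#' @param orthogonalize If `TRUE`, option prototypes are orthonormalized
#'   (worst-case separability); default `FALSE` leaves realistic overlap.
#' @param seed Integer seed for prototypes and noise.
#' @return A list of class `neural_gen_config`.
#' @export
neural_gen_config <- function(n_voxels = 200,
                              region_kind = c("state_mixture", "action_code"),
                              gain = 1,
                              noise_sd = 1.2,
                              neighbor_bleed = 0,
                              orthogonalize = FALSE,
                              seed = 1L) {
  region_kind <- match.arg(region_kind)
  stopifnot(n_voxels >= 1, noise_sd >= 0, neighbor_bleed >= 0, neighbor_bleed < 1)
  structure(
    list(n_voxels = as.integer(n_voxels), region_kind = region_kind,
         gain = gain, noise_sd = noise_sd, neighbor_bleed = neighbor_bleed,
         orthogonalize = orthogonalize, seed = as.integer(seed)),
    class = "neural_gen_config"
  )
}

# One fixed standard-normal prototype per option (rows: options 0..7).
region_prototypes <- function(config, n_options = 8) {
  with_seed(derive_seed(config$seed, 991L), {
    pro <- matrix(rnorm(n_options * config$n_voxels), nrow = n_options)
    if (config$orthogonalize) {
      pro <- t(qr.Q(qr(t(pro)))[, seq_len(n_options)]) * sqrt(config$n_voxels)
    }
    pro
  })
}

#' Generate trial patterns for a state-coding (belief-mixture) region
#'
#' Each trial's pattern is `gain * sum_i w_i * prototype_i + noise`, where the
#' weights `w_i` are the trial's posterior marginal beliefs over the four
#' available options. An optional per-trial flattening `f_t` mixes the weights
#' toward uniform, `w' = (1 - f_t) w + f_t / 4`; the pupil generator uses this
#' hook to plant a pupil-linked loss of representational selectivity.
#'
#' @param trials Trial tibble for one subject (needs `run`, `t`, `chosen`).
#' @param beliefs Matching [run_observer()] series (posterior `pH1..pH4`).
#' @param config A [neural_gen_config()] with `region_kind = "state_mixture"`.
#' @param flatten Optional numeric vector (one value per trial in `[0, 1]`)
#'   of flattening weights.
#' @param available Optional list of available option-id vectors, one per run
#'   (in run-id order); defaults to the distinct chosen ids observed per run.
#' @param seed Noise seed (default derived from the config seed).
#' @return A list of class `pattern_matrix`: `activity` (trials x voxels),
#'   `chosen`, `run`, `available` (list per run), `prototypes`.
#' @export
generate_state_region_patterns <- function(trials, beliefs, config,
                                           flatten = NULL, available = NULL,
                                           seed = derive_seed(config$seed, 1L)) {
  stopifnot(config$region_kind == "state_mixture")
  if (nrow(trials) != nrow(beliefs)) {
    stop("generate_state_region_patterns: trials/beliefs misaligned", call. = FALSE)
  }
  if (!is.null(flatten) && length(flatten) != nrow(trials)) {
    stop("generate_state_region_patterns: flatten length mismatch", call. = FALSE)
  }
  pro <- region_prototypes(config)
  w <- as.matrix(beliefs[, c("pH1", "pH2", "pH3", "pH4")])
  if (!is.null(flatten)) {
    f <- clip(flatten, 0, 1)
    w <- (1 - f) * w + f / 4
  }
  # map hypothesis positions to option ids per run
  n <- nrow(trials)
  mix <- matrix(0, nrow = n, ncol = config$n_voxels)
  avail_by_run <- available_by_run(trials, available)
  for (r in sort(unique(trials$run))) {
    idx <- which(trials$run == r)
    avail <- avail_by_run[[as.character(r)]]
    mix[idx, ] <- w[idx, , drop = FALSE] %*% pro[avail + 1L, , drop = FALSE]
  }
  act <- with_seed(seed, {
    config$gain * mix + matrix(rnorm(n * config$n_voxels, sd = config$noise_sd),
                               nrow = n)
  })
  structure(
    list(activity = act, chosen = trials$chosen, run = trials$run,
         available = avail_by_run, prototypes = pro, config = config),
    class = "pattern_matrix"
  )
}

#' Generate trial patterns for an action-coding region
#'
#' The pattern is `gain * prototype_chosen + neighbor_bleed * gain *
#' prototype_adjacent + noise`; weights never depend on beliefs, so decoding
#' from such a region is insensitive to model entropy.
#'
#' @inheritParams generate_state_region_patterns
#' @param config A [neural_gen_config()] with `region_kind = "action_code"`.
#' @return A `pattern_matrix` (see [generate_state_region_patterns()]).
#' @export
generate_action_region_patterns <- function(trials, config, available = NULL,
                                            seed = derive_seed(config$seed, 2L)) {
  stopifnot(config$region_kind == "action_code")
  pro <- region_prototypes(config)
  n <- nrow(trials)
  adj <- (trials$chosen + 1L) %% 8L
  mix <- pro[trials$chosen + 1L, , drop = FALSE] +
    config$neighbor_bleed * pro[adj + 1L, , drop = FALSE]
  act <- with_seed(seed, {
    config$gain * mix + matrix(rnorm(n * config$n_voxels, sd = config$noise_sd),
                               nrow = n)
  })
  avail_by_run <- available_by_run(trials, available)
  structure(
    list(activity = act, chosen = trials$chosen, run = trials$run,
         available = avail_by_run, prototypes = pro, config = config),
    class = "pattern_matrix"
  )
}

# Available option ids per run, keyed by run id: explicit list (run-id order)
# or inferred from the observed choices.
available_by_run <- function(trials, available = NULL) {
  runs <- sort(unique(trials$run))
  out <- list()
  for (i in seq_along(runs)) {
    out[[as.character(runs[i])]] <- if (is.null(available)) {
      sort(unique(trials$chosen[trials$run == runs[i]]))
    } else {
      sort(available[[i]])
    }
  }
  out
}

#' Configuration for synthetic pupil traces
#'
#' The generator emulates a per-trial baseline pupil level whose
#' trial-to-trial changes couple to uncertainty-increasing (unrewarded)
#' outcomes: each unrewarded trial emits a non-negative latent arousal pulse
#' `z_t = s_t * u_t`, with iid lognormal gain `u_t` and amplitude
#' `s_t = (1 - pulse_entropy_weight) * pulse_scale +
#' pulse_entropy_weight * max(0, dENT_t)`, that raises the next trial's
#' baseline by `coupling_a * z_t`. By default the amplitude is the fixed
#' `pulse_scale` (`pulse_entropy_weight = 0`): tying the amplitude to the
#' trial's entropy increment couples the pupil to the observer's own
#' mean-reverting entropy dynamics and smears the planted lag-0 coupling
#' into the adjacent lags, so the entropy scaling is off by default and
#' available as a knob. Pulses accumulate into a latent
#' arousal level with slow decay (`pulse_decay`), emulating the sustained
#' post-omission elevation of baseline pupil size, so the trial-to-trial
#' *change* in baseline isolates the current trial's pulse. The same latent
#' level, scaled by `extra_flattening_c`, can be injected into state-region
#' mixture weights to plant the pupil-to-representation coupling. Blinks are
#' inserted as missing-sample gaps and Gaussian measurement noise is added.
#'
#' @param sample_rate Samples per second (default 100 for test speed; set
#'   1000 to mirror typical eyetracker acquisition).
#' @param baseline_mean Mean pupil size, arbitrary units.
#' @param baseline_sd Trial-to-trial SD of the baseline level.
#' @param coupling_a Pupil units added to the next baseline per pulse unit.
#' @param pulse_sd SD of the lognormal pulse gain `u_t`.
#' @param pulse_scale Fixed pulse amplitude (default 0.5, roughly the mean
#'   entropy increase after an omission, keeping the units comparable).
#' @param pulse_entropy_weight Weight in `[0, 1]` of the trial's entropy
#'   increase in the pulse amplitude (default 0; 1 scales pulses fully by
#'   the entropy increment).
#' @param pulse_decay Per-trial retention of the latent arousal level
#'   (default 0.9; 0 makes pulses one-trial transients).
#' @param extra_flattening_c Belief-flattening per pulse unit for the linked
#'   state-region generator (0 disables the planted coupling).
#' @param blink_rate Blinks per second (each blink blanks ~100 ms).
#' @param noise_sd Measurement noise SD (sample-wise).
#' @param trial_duration_s,feedback_offset_s Trial length and the time of
#'   feedback within the trial, in seconds.
#' @param seed Integer seed.
#' @return A list of class `pupil_gen_config`.
#' @export
pupil_gen_config <- function(sample_rate = 100,
                             baseline_mean = 1000,
                             baseline_sd = 20,
                             coupling_a = 40,
                             pulse_sd = 1,
                             pulse_scale = 0.5,
                             pulse_entropy_weight = 0,
                             pulse_decay = 0.9,
                             extra_flattening_c = 0.35,
                             blink_rate = 0.1,
                             noise_sd = 5,
                             trial_duration_s = 3,
                             feedback_offset_s = 2,
                             seed = 1L) {
  stopifnot(sample_rate > 0, blink_rate >= 0, noise_sd >= 0,
            feedback_offset_s > 0, feedback_offset_s < trial_duration_s,
            pulse_decay >= 0, pulse_decay < 1,
            pulse_entropy_weight >= 0, pulse_entropy_weight <= 1,
            pulse_scale >= 0)
  structure(
    list(sample_rate = sample_rate, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, coupling_a = coupling_a,
         pulse_sd = pulse_sd, pulse_scale = pulse_scale,
         pulse_entropy_weight = pulse_entropy_weight,
         pulse_decay = pulse_decay,
         extra_flattening_c = extra_flattening_c,
         blink_rate = blink_rate, noise_sd = noise_sd,
         trial_duration_s = trial_duration_s,
         feedback_offset_s = feedback_offset_s, seed = as.integer(seed)),
    class = "pupil_gen_config"
  )
}

# Latent arousal pulses on unrewarded trials, with trial-specific lognormal
# gain; amplitude mixes a fixed scale with the trial's entropy increase per
# config. Returns one value per trial (>= 0).
pupil_pulses <- function(trials, beliefs, config, seed) {
  dent <- numeric(nrow(beliefs))
  for (r in unique(beliefs$run)) {
    idx <- which(beliefs$run == r)
    dent[idx] <- delta_prev(beliefs$entropy[idx])
  }
  dent[is.na(dent)] <- 0
  w <- config$pulse_entropy_weight
  amp <- (1 - w) * config$pulse_scale + w * pmax(0, dent)
  with_seed(seed, {
    u <- exp(rnorm(nrow(trials), 0, config$pulse_sd))
    ifelse(trials$outcome == 0, amp * u, 0)
  })
}

#' Generate a synthetic raw pupil trace for one subject
#'
#' @param trials Trial tibble for one subject.
#' @param beliefs Matching [run_observer()] series.
#' @param config A [pupil_gen_config()].
#' @param seed Integer seed (default derived from the config seed).
#' @return A list of class `pupil_raw`: `trace` (tibble `run`, `time_ms`,
#'   `value`, `is_missing`), `feedback_ms` (tibble `run`, `t`, `feedback_ms`),
#'   `planted` (tibble `run`, `t`, `baseline`, `pulse`, `level` -- the latent
#'   arousal level after the trial's feedback).
#' @export
generate_pupil_trace <- function(trials, beliefs, config = pupil_gen_config(),
                                 seed = derive_seed(config$seed, 3L)) {
  pulses <- pupil_pulses(trials, beliefs, config, derive_seed(seed, 7L))
  sr <- config$sample_rate
  spt <- round(config$trial_duration_s * sr)  # samples per trial
  with_seed(seed, {
    traces <- list(); fbs <- list(); plant <- list()
    for (r in sort(unique(trials$run))) {
      idx <- which(trials$run == r)
      n <- length(idx)
      base <- numeric(n)
      level <- numeric(n)
      base[1] <- config$baseline_mean
      lv <- 0
      for (i in seq_len(n)) {
        lv <- config$pulse_decay * lv + pulses[idx[i]]
        level[i] <- lv
        if (i < n) {
          base[i + 1] <- config$baseline_mean + config$coupling_a * lv +
            rnorm(1, 0, config$baseline_sd)
        }
      }
      value <- rep(base, each = spt) + rnorm(n * spt, 0, config$noise_sd)
      time_ms <- (seq_len(n * spt) - 1) / sr * 1000
      missing <- rep(FALSE, n * spt)
      n_blinks <- stats::rpois(1, config$blink_rate * n * config$trial_duration_s)
      if (n_blinks > 0) {
        starts <- sample.int(n * spt, n_blinks)
        width <- max(1L, round(0.1 * sr))
        for (st in starts) missing[st:min(st + width - 1L, n * spt)] <- TRUE
      }
      value[missing] <- NA_real_
      traces[[as.character(r)]] <- tibble::tibble(
        run = r, time_ms = time_ms, value = value, is_missing = missing
      )
      fbs[[as.character(r)]] <- tibble::tibble(
        run = r, t = trials$t[idx],
        feedback_ms = ((seq_len(n) - 1) * spt) / sr * 1000 +
          config$feedback_offset_s * 1000
      )
      plant[[as.character(r)]] <- tibble::tibble(
        run = r, t = trials$t[idx], baseline = base, pulse = pulses[idx],
        level = level
      )
    }
    structure(
      list(trace = dplyr::bind_rows(traces),
           feedback_ms = dplyr::bind_rows(fbs),
           planted = dplyr::bind_rows(plant),
           config = config),
      class = "pupil_raw"
    )
  })
}

#' Generate a per-trial univariate signal coupled to entropy change
#'
#' `signal_t = b * dENT_t + noise`, with `dENT_t = entropy_t - entropy_{t-1}`
#' within run (`NA` on each run's first trial). Emulates a region whose
#' activity tracks increases in model entropy.
#'
#' @param beliefs A [run_observer()] series.
#' @param b Coupling coefficient.
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return Tibble `run`, `t`, `dent`, `signal`.
#' @export
generate_univariate_signal <- function(beliefs, b = 1, noise_sd = 0.5, seed = 1L) {
  dent <- numeric(nrow(beliefs))
  for (r in unique(beliefs$run)) {
    idx <- which(beliefs$run == r)
    dent[idx] <- delta_prev(beliefs$entropy[idx])
  }
  with_seed(seed, {
    tibble::tibble(
      run = beliefs$run, t = beliefs$t, dent = dent,
      signal = b * dent + rnorm(nrow(beliefs), 0, noise_sd)
    )
  })
}

#' Generate a complete synthetic cohort dataset
#'
#' Runs the full generative chain for `n_subjects`: bandit simulation, ideal
#' observer, phase labels, state- and action-region patterns (with the pupil
#' pulse injected into the state-region weights when
#' `pupil_cfg$extra_flattening_c > 0`), pupil traces, and a univariate
#' entropy-change signal. Everything is deterministic given the configs and
#' `master_seed`.
#'
#' @param n_subjects Number of subjects (default 19).
#' @param task_cfg,observer_cfg,policy Task, observer and agent settings.
#' @param state_cfg,action_cfg [neural_gen_config()]s for the two regions.
#' @param pupil_cfg A [pupil_gen_config()].
#' @param univariate_b,univariate_sd Coupling and noise of the univariate
#'   signal.
#' @param master_seed Integer master seed.
#' @return A list of class `cohort_dataset` with elements `trials` (labelled
#'   cohort tibble), `beliefs`, `patterns` (per subject: `state`, `action`),
#'   `pupil` (per subject `pupil_raw`), `univariate` (tibble with `subject`),
#'   and `configs`.
#' @export
generate_cohort_dataset <- function(n_subjects = 19,
                                    task_cfg = task_config(),
                                    observer_cfg = observer_config(),
                                    policy = agent_policy("softmax"),
                                    state_cfg = neural_gen_config(region_kind = "state_mixture"),
                                    action_cfg = neural_gen_config(region_kind = "action_code"),
                                    pupil_cfg = pupil_gen_config(),
                                    univariate_b = 1,
                                    univariate_sd = 0.5,
                                    master_seed = 1L) {
  avail <- task_cfg$available_ids
  trials <- simulate_cohort(task_cfg, n_subjects, policy, master_seed,
                            observer_cfg = observer_cfg)
  trials <- label_trials(trials)
  beliefs <- run_observer_cohort(trials, observer_cfg, available_ids = avail)
  subjects <- sort(unique(trials$subject))
  patterns <- list(); pupil <- list(); univ <- list()
  for (s in subjects) {
    tr <- trials[trials$subject == s, ]
    be <- beliefs[beliefs$subject == s, ]
    pu_seed <- derive_seed(master_seed, s, 30L)
    pu <- generate_pupil_trace(tr, be, pupil_cfg, seed = pu_seed)
    # the arousal level after trial t's feedback degrades the NEXT trial's
    # representation, with the same sustained decay it has on the baseline
    # pupil, so pupil change and representation change share one latent input
    level_next <- numeric(nrow(tr))
    for (r in unique(pu$planted$run)) {
      idx <- which(pu$planted$run == r)
      level_next[idx] <- c(0, head(pu$planted$level[idx], -1))
    }
    # smooth saturating map into [0, 1): behaves like c * level for small
    # levels without a hard clip that would distort the planted coupling
    flatten <- 1 - exp(-pupil_cfg$extra_flattening_c * level_next)
    s_cfg <- state_cfg; s_cfg$seed <- derive_seed(master_seed, s, 10L)
    a_cfg <- action_cfg; a_cfg$seed <- derive_seed(master_seed, s, 20L)
    patterns[[as.character(s)]] <- list(
      state = generate_state_region_patterns(tr, be, s_cfg, flatten = flatten,
                                             available = avail),
      action = generate_action_region_patterns(tr, a_cfg, available = avail)
    )
    pupil[[as.character(s)]] <- pu
    u <- generate_univariate_signal(be, b = univariate_b, noise_sd = univariate_sd,
                                    seed = derive_seed(master_seed, s, 40L))
    univ[[as.character(s)]] <- dplyr::bind_cols(tibble::tibble(subject = s), u)
  }
  structure(
    list(trials = trials, beliefs = beliefs, patterns = patterns,
         pupil = pupil, univariate = dplyr::bind_rows(univ),
         configs = list(task = task_cfg, observer = observer_cfg,
                        policy = policy, state = state_cfg, action = action_cfg,
                        pupil = pupil_cfg, master_seed = master_seed)),
    class = "cohort_dataset"
  )
}

#' Generate a volumetric pattern dataset with a planted informative region
#'
#' Embeds a `state_mixture` signal inside a rectangular sub-block of a 3D
#' volume of otherwise pure-noise voxels, for searchlight recovery tests.
#'
#' @param trials,beliefs One subject's trials and belief series.
#' @param shape Integer 3-vector, volume dimensions in voxels.
#' @param signal_corner,signal_size Integer 3-vectors: lower corner (1-based)
#'   and size of the informative block.
#' @param gain,noise_sd Signal gain inside the block and global noise SD.
#' @param seed Integer seed.
#' @return A list: `activity` (trials x voxels), `coords` (voxels x 3 matrix),
#'   `signal_voxels` (indices of the informative block), `chosen`, `run`,
#'   `available`.
#' @export
generate_volume_dataset <- function(trials, beliefs, shape = c(12, 12, 12),
                                    signal_corner = c(3, 3, 3),
                                    signal_size = c(4, 4, 4),
                                    gain = 1, noise_sd = 1.5, seed = 1L) {
  coords <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                                  z = seq_len(shape[3])))
  in_block <- coords[, 1] >= signal_corner[1] & coords[, 1] < signal_corner[1] + signal_size[1] &
    coords[, 2] >= signal_corner[2] & coords[, 2] < signal_corner[2] + signal_size[2] &
    coords[, 3] >= signal_corner[3] & coords[, 3] < signal_corner[3] + signal_size[3]
  n_sig <- sum(in_block)
  cfg <- neural_gen_config(n_voxels = n_sig, region_kind = "state_mixture",
                           gain = gain, noise_sd = noise_sd, seed = seed)
  sig <- generate_state_region_patterns(trials, beliefs, cfg)
  n <- nrow(trials)
  act <- with_seed(derive_seed(seed, 5L), {
    matrix(rnorm(n * nrow(coords), sd = noise_sd), nrow = n)
  })
  act[, in_block] <- sig$activity
  list(activity = act, coords = coords, signal_voxels = which(in_block),
       chosen = trials$chosen, run = trials$run, available = sig$available)
}
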