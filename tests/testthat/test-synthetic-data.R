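test_that("noiseless state patterns are exact prototype mixtures", {
  co <- make_small_cohort(n_subjects = 1, n_trials = 20, n_runs = 1)
  cfg <- neural_gen_config(n_voxels = 30, region_kind = "state_mixture",
                           gain = 2, noise_sd = 0, seed = 5)
  # one-hot beliefs: pattern equals gain * prototype of that option
  be <- co$beliefs
  be[, c("pH1", "pH2", "pH3", "pH4")] <- 0
  be$pH2 <- 1
  pat <- generate_state_region_patterns(co$trials, be, cfg, available = co$available)
  avail <- pat$available[[1]]
  expect_equal(pat$activity[1, ], 2 * pat$prototypes[avail[2] + 1, ],
               tolerance = 1e-12)
  # uniform beliefs: pattern equals gain * mean prototype
  be[, c("pH1", "pH2", "pH3", "pH4")] <- 0.25
  pat <- generate_state_region_patterns(co$trials, be, cfg, available = co$available)
  expect_equal(pat$activity[1, ],
               2 * colMeans(pat$prototypes[avail + 1, ]), tolerance = 1e-12)
})

test_that("full flattening erases option information from the weights", {
  co <- make_small_cohort(n_subjects = 1, n_trials = 10, n_runs = 1)
  cfg <- neural_gen_config(n_voxels = 20, noise_sd = 0, seed = 6)
  flat <- generate_state_region_patterns(co$trials, co$beliefs, cfg,
                                         flatten = rep(1, 10),
                                         available = co$available)
  # all trials collapse to the same mean-prototype pattern
  expect_lt(max(abs(sweep(flat$activity, 2, flat$activity[1, ]))), 1e-12)
})

test_that("action patterns ignore beliefs and respect the bleed", {
  co <- make_small_cohort(n_subjects = 1, n_trials = 20, n_runs = 1)
  cfg <- neural_gen_config(n_voxels = 30, region_kind = "action_code",
                           gain = 1.5, noise_sd = 0, neighbor_bleed = 0, seed = 7)
  pat <- generate_action_region_patterns(co$trials, cfg, available = co$available)
  ch <- co$trials$chosen[1]
  expect_equal(pat$activity[1, ], 1.5 * pat$prototypes[ch + 1, ],
               tolerance = 1e-12)
  cfgb <- neural_gen_config(n_voxels = 30, region_kind = "action_code",
                            gain = 1.5, noise_sd = 0, neighbor_bleed = 0.4, seed = 7)
  patb <- generate_action_region_patterns(co$trials, cfgb, available = co$available)
  adj <- (ch + 1L) %% 8L
  expect_equal(patb$activity[1, ],
               1.5 * (pat$prototypes[ch + 1, ] + 0.4 * pat$prototypes[adj + 1, ]),
               tolerance = 1e-12)
})

test_that("bleed concentrates decoding confusions on the adjacent option", {
  co <- make_small_cohort(n_subjects = 1, n_trials = 100, n_runs = 4,
                          master_seed = 41)
  cfg <- neural_gen_config(n_voxels = 60, region_kind = "action_code",
                           noise_sd = 1.5, neighbor_bleed = 0.7, seed = 8)
  pat <- generate_action_region_patterns(co$trials, cfg, available = co$available)
  rs <- decode_patterns(pat, k = 20)
  probs <- attr(rs, "probabilities")
  # mean probability of the adjacent option exceeds other non-chosen options
  adj_p <- mean(probs[cbind(seq_len(nrow(probs)),
                            match((pat$chosen + 1L) %% 8L, 0:7))])
  others <- vapply(seq_len(nrow(probs)), function(i) {
    excl <- c(pat$chosen[i], (pat$chosen[i] + 1L) %% 8L)
    mean(probs[i, !(0:7 %in% excl)])
  }, numeric(1))
  expect_gt(adj_p, mean(others))
})

test_that("univariate signal has the planted coupling and a clean null", {
  co <- make_small_cohort(n_subjects = 1, n_trials = 200, n_runs = 4,
                          master_seed = 42)
  # null: no coupling
  null_sig <- generate_univariate_signal(co$beliefs, b = 0, noise_sd = 1, seed = 9)
  ok <- complete.cases(null_sig[, c("dent", "signal")])
  expect_lt(abs(cor(null_sig$dent[ok], null_sig$signal[ok])), 0.1)
  # recovery: OLS estimate of b within 2 SE of truth
  sig <- generate_univariate_signal(co$beliefs, b = 1, noise_sd = 0.1, seed = 10)
  fit <- fit_ols(cbind(bias = 1, dent = sig$dent), sig$signal)
  b_hat <- fit$estimate[fit$term == "dent"]
  b_se <- fit$se[fit$term == "dent"]
  expect_lt(abs(b_hat - 1), 2 * b_se)
  # determinism
  sig2 <- generate_univariate_signal(co$beliefs, b = 1, noise_sd = 0.1, seed = 10)
  expect_identical(sig, sig2)
})

test_that("pupil generator honours its degenerate settings", {
  co <- make_small_cohort(n_subjects = 1, n_trials = 30, n_runs = 1)
  cfg <- pupil_gen_config(coupling_a = 0, baseline_sd = 0, noise_sd = 0,
                          blink_rate = 0)
  pu <- generate_pupil_trace(co$trials, co$beliefs, cfg, seed = 11)
  expect_true(all(!pu$trace$is_missing))
  expect_lt(max(abs(pu$trace$value - cfg$baseline_mean)), 1e-9)
})

test_that("pupil baseline changes recover the planted coupling gain", {
  co <- make_small_cohort(n_subjects = 1, n_trials = 200, n_runs = 4,
                          master_seed = 43)
  cfg <- pupil_gen_config(coupling_a = 40, baseline_sd = 2, noise_sd = 0,
                          blink_rate = 0)
  pu <- generate_pupil_trace(co$trials, co$beliefs, cfg, seed = 12)
  pl <- pu$planted
  dlevel <- unlist(lapply(split(pl$level, pl$run),
                          function(x) diff(c(0, head(x, -1)))))
  dbase <- unlist(lapply(split(pl$baseline, pl$run), diff))
  fit <- fit_ols(cbind(bias = 1, dlevel = dlevel), dbase)
  a_hat <- fit$estimate[fit$term == "dlevel"]
  a_se <- fit$se[fit$term == "dlevel"]
  expect_lt(abs(a_hat - 40), 3 * a_se)
})

test_that("pulses occur only on unrewarded trials", {
  co <- make_small_cohort(n_subjects = 1, n_trials = 100, n_runs = 2,
                          master_seed = 44)
  pu <- generate_pupil_trace(co$trials, co$beliefs, pupil_gen_config(), seed = 13)
  expect_true(all(pu$planted$pulse[co$trials$outcome == 1] == 0))
  expect_true(any(pu$planted$pulse[co$trials$outcome == 0] > 0))
})

test_that("cohort dataset is deterministic and shape-consistent", {
  cfg <- task_config(n_trials_per_run = 30, n_runs = 4)
  ncfg <- neural_gen_config(n_voxels = 20)
  acfg <- neural_gen_config(n_voxels = 20, region_kind = "action_code")
  ds1 <- generate_cohort_dataset(n_subjects = 2, task_cfg = cfg,
                                 state_cfg = ncfg, action_cfg = acfg,
                                 master_seed = 45)
  ds2 <- generate_cohort_dataset(n_subjects = 2, task_cfg = cfg,
                                 state_cfg = ncfg, action_cfg = acfg,
                                 master_seed = 45)
  expect_identical(ds1$trials, ds2$trials)
  expect_identical(ds1$patterns[["1"]]$state$activity,
                   ds2$patterns[["1"]]$state$activity)
  for (s in names(ds1$patterns)) {
    n_tr <- sum(ds1$trials$subject == as.integer(s))
    expect_equal(dim(ds1$patterns[[s]]$state$activity), c(n_tr, 20))
    expect_equal(dim(ds1$patterns[[s]]$action$activity), c(n_tr, 20))
  }
})
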