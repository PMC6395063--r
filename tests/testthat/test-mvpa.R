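test_that("run pairing covers all options in each half", {
  pr <- pair_runs_split(0:3, list(0:3, 4:7, 0:3, 4:7))
  covered <- lapply(pr$pairs, function(p) {
    sort(unique(unlist(list(0:3, 4:7, 0:3, 4:7)[p + 1])))
  })
  expect_true(all(vapply(covered, function(x) setequal(x, 0:7), logical(1))))
  # both fold directions partition the runs
  tests <- sort(unlist(lapply(pr$folds, `[[`, "test")))
  expect_equal(tests, 0:3)
  expect_error(pair_runs_split(0:3, list(0:3, 0:3, 0:3, 0:3),
                               all_options = 0:7), "no pairing")
})

test_that("PCA reduction reconstructs low-rank data exactly", {
  set.seed(71)
  basis <- matrix(rnorm(3 * 40), nrow = 3)
  load_true <- matrix(rnorm(50 * 3), ncol = 3)
  x <- load_true %*% basis
  red <- reduce_dimensions(x, k = 20)
  expect_lte(ncol(red$components), 3)  # k capped at rank
  recon <- red$loadings %*% t(red$components)
  xc <- sweep(x, 2, red$center)
  expect_lt(max(abs(recon - xc)), 1e-8)
  # components orthonormal
  g <- crossprod(red$components)
  expect_lt(max(abs(g - diag(ncol(red$components)))), 1e-8)
})

test_that("PCA reconstruction error is non-increasing in k", {
  set.seed(72)
  x <- matrix(rnorm(60 * 30), nrow = 60)
  errs <- vapply(c(2, 5, 10, 20), function(k) {
    red <- reduce_dimensions(x, k = k)
    xc <- sweep(x, 2, red$center)
    sum((xc - red$loadings %*% t(red$components))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  expect_error(reduce_dimensions(x, k = 0), "at least 1")
  expect_error(reduce_dimensions(x[1, , drop = FALSE]), "at least 2 trials")
})

test_that("oversampling balances classes by deterministic cycling", {
  idx <- 1:25
  labels <- rep(c("a", "b", "c", "d"), c(10, 7, 5, 3))
  out <- balance_training_set(idx, labels)
  expect_equal(as.numeric(table(labels[out])), rep(10, 4))
  # deterministic: same result twice
  expect_identical(out, balance_training_set(idx, labels))
  # already balanced: unchanged multiset
  bal <- balance_training_set(1:8, rep(c("a", "b"), each = 4))
  expect_equal(sort(bal), 1:8)
  expect_error(balance_training_set(integer(0), character(0)), "empty")
})

test_that("classifier is exact on separable data and reproducible", {
  set.seed(73)
  proto <- matrix(rnorm(8 * 10), nrow = 8) * 5
  labels <- rep(0:7, each = 6)
  x <- proto[labels + 1, ]
  pr1 <- train_and_classify(x, labels, x, classes = 0:7, seed = 42)
  pr2 <- train_and_classify(x, labels, x, classes = 0:7, seed = 42)
  expect_identical(pr1, pr2)
  expect_equal(rowSums(pr1), rep(1, nrow(pr1)), tolerance = 1e-9)
  modal <- as.integer(colnames(pr1)[max.col(pr1)])
  expect_equal(mean(modal == labels), 1)
  expect_error(train_and_classify(x, rep(0:6, length.out = 48), x, classes = 0:7),
               "absent")
})

test_that("structureless patterns decode at 8-way chance with zero RS", {
  co <- make_small_cohort(n_subjects = 1, n_trials = 100, n_runs = 4,
                          master_seed = 74)
  stats <- vapply(1:3, function(i) {
    noise <- list(
      activity = beliefstate:::with_seed(75 + i, {
        matrix(rnorm(nrow(co$trials) * 50), ncol = 50)
      }),
      chosen = co$trials$chosen, run = co$trials$run,
      available = beliefstate:::available_by_run(co$trials, co$available)
    )
    rs <- decode_patterns(noise, k = 20)
    f <- fit_ols(cbind(bias = 1, entropy = co$beliefs$entropy), rs$rep_strength)
    c(acc = mean(rs$accurate), rs = mean(rs$rep_strength),
      t_ent = f$statistic[f$term == "entropy"])
  }, numeric(3))
  # 8-way classifier on noise: accuracy at chance (1/8); RS close to 0 (a
  # small calibration offset from oversampling is tolerated); and no spurious
  # entropy effect
  expect_lt(abs(mean(stats["acc", ]) - 1 / 8), 0.06)
  expect_lt(abs(mean(stats["rs", ])), 0.5)
  expect_lt(abs(mean(stats["t_ent", ])), 2)
})

test_that("representation strength matches its closed-form examples", {
  pr <- matrix(1 / 8, nrow = 1, ncol = 8, dimnames = list(NULL, 0:7))
  expect_equal(representation_strength(pr, chosen = 2, available = 0:3), 0,
               tolerance = 1e-12)

  pr2 <- matrix(0.5 / 7, nrow = 1, ncol = 8, dimnames = list(NULL, 0:7))
  pr2[1, "2"] <- 0.5
  expect_equal(representation_strength(pr2, chosen = 2, available = 0:7),
               log(13), tolerance = 1e-10)

  # certainty is clipped to a finite value
  pr3 <- matrix(0, nrow = 1, ncol = 8, dimnames = list(NULL, 0:7))
  pr3[1, "2"] <- 1
  rs <- representation_strength(pr3, chosen = 2, available = 0:3)
  expect_true(is.finite(rs))
  expect_error(representation_strength(pr3, chosen = 5, available = 0:3),
               "not in available")
})

test_that("sum aggregation is available behind the flag", {
  pr <- matrix(0.5 / 7, nrow = 1, ncol = 8, dimnames = list(NULL, 0:7))
  pr[1, "2"] <- 0.5
  rs_mean <- representation_strength(pr, 2, 0:7, aggregate = "mean")
  rs_sum <- representation_strength(pr, 2, 0:7, aggregate = "sum")
  expect_gt(rs_mean, rs_sum)  # mean of unchosen < their sum -> bigger ratio
})

test_that("voxelwise residualization removes exactly the nuisance span", {
  set.seed(76)
  n <- 60
  x <- matrix(rnorm(n * 10), nrow = n)
  nuis <- cbind(1, rnorm(n))
  # orthogonal nuisance leaves patterns unchanged
  x_orth <- qr.resid(qr(nuis), x)
  expect_lt(max(abs(residualize_voxelwise(x_orth, nuis) - x_orth)), 1e-10)
  # a voxel equal to a nuisance column residualizes to zero
  x2 <- cbind(x, nuis[, 2])
  res <- residualize_voxelwise(x2, nuis)
  expect_lt(max(abs(res[, 11])), 1e-10)
  expect_error(residualize_voxelwise(x, cbind(1, 1)), "rank deficient")
})

test_that("state-region decoding is better on low-entropy trials", {
  co <- make_small_cohort(n_subjects = 1, n_trials = 200, n_runs = 4,
                          master_seed = 77)
  cfg <- neural_gen_config(n_voxels = 100, noise_sd = 1, seed = 78)
  pat <- generate_state_region_patterns(co$trials, co$beliefs, cfg,
                                        available = co$available)
  rs <- decode_patterns(pat, k = 20)
  lowhigh <- split(rs$accurate, co$beliefs$entropy > median(co$beliefs$entropy))
  expect_gt(mean(lowhigh$`FALSE`), mean(lowhigh$`TRUE`))
})

test_that("searchlight recovers a planted informative block", {
  co <- make_small_cohort(n_subjects = 1, n_trials = 120, n_runs = 4,
                          master_seed = 79)
  vol <- generate_volume_dataset(co$trials, co$beliefs, shape = c(10, 10, 10),
                                 signal_corner = c(3, 3, 3),
                                 signal_size = c(4, 4, 4),
                                 gain = 2, noise_sd = 0.5, seed = 80)
  # subsample centers on a coarse lattice for speed
  coords <- vol$coords
  mask <- coords[, 1] %% 3 == 0 & coords[, 2] %% 3 == 0 & coords[, 3] %% 3 == 0
  stat <- function(rs) mean(rs$p_chosen)
  map <- searchlight_map(vol, stat, radius = 2, centers = which(mask),
                         min_voxels = 8, k = 10)
  done <- map[!map$skipped, ]
  peak <- done[which.max(done$stat), ]
  expect_true(peak$voxel %in% vol$signal_voxels)
})

test_that("voxel shuffling preserves each trial's value multiset", {
  co <- make_small_cohort(n_subjects = 1, n_trials = 20, n_runs = 1)
  cfg <- neural_gen_config(n_voxels = 15, seed = 81)
  pat <- generate_state_region_patterns(co$trials, co$beliefs, cfg,
                                        available = co$available)
  seen <- list()
  stat <- function(p) {
    seen[[length(seen) + 1]] <<- p$activity
    0
  }
  expect_warning(shuffle_bias_check(pat, stat, n_perm = 3, seed = 82),
                 "uninformative")
  for (perm in seen[-1]) {
    for (i in seq_len(nrow(perm))) {
      expect_equal(sort(perm[i, ]), sort(pat$activity[i, ]))
    }
  }
})
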