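test_that("design recipes produce the documented columns", {
  co <- make_small_cohort(n_subjects = 1, n_trials = 80, n_runs = 2,
                          master_seed = 91)
  d4 <- build_design("GLM4", co$trials, co$beliefs)
  expect_equal(colnames(d4$X), c("bias", "entropy"))
  expect_equal(d4$dependent, "rep_strength")
  expect_equal(d4$subset, co$trials$core_exploit)

  d4r <- build_design("GLM4", co$trials, co$beliefs, per_run_bias = TRUE)
  expect_equal(colnames(d4r$X), c("bias_run0", "bias_run1", "entropy"))

  d1 <- build_design("GLM1", co$trials, co$beliefs)
  expect_equal(colnames(d1$X), c("exploit", "explore"))
  expect_true(all(rowSums(d1$X) == 1))  # indicators partition the trials

  d3 <- build_design("GLM3", co$trials, co$beliefs)
  expect_false("bias" %in% colnames(d3$X))  # phase indicators span the bias
  expect_true(all(c("exploit", "explore", "entropy", "reward") %in% colnames(d3$X)))

  d2 <- build_design("GLM2", co$trials, co$beliefs)
  expect_equal(colnames(d2$X),
               c("bias", "entropy", "reward", "switch_next", "last_exploit",
                 "first_exploit"))

  ex <- list(signal = rnorm(nrow(co$trials)), global_mean = rnorm(nrow(co$trials)))
  d8 <- build_design("GLM8", co$trials, co$beliefs, extra = ex)
  expect_true(all(c("signal", "global_mean", "dent_prev") %in% colnames(d8$X)))

  # collinear columns are named in the error
  ex_bad <- list(signal = rep(1, nrow(co$trials)), global_mean = rnorm(nrow(co$trials)))
  expect_error(build_design("GLM8", co$trials, co$beliefs, extra = ex_bad),
               "collinear")
  expect_error(build_design("GLM99", co$trials, co$beliefs), "unknown recipe")
})

test_that("OLS is exact on noiseless data and matches lm on a fixture", {
  X <- cbind(bias = 1, x = as.numeric(1:10))
  f <- fit_ols(X, 1 + 2 * (1:10))
  expect_equal(f$estimate, c(1, 2), tolerance = 1e-12)

  # 5-point fixture cross-checked against the reference implementation
  x <- c(1.2, 2.1, 2.9, 4.3, 5.2)
  y <- c(2.2, 4.5, 5.1, 9.0, 10.3)
  ours <- fit_ols(cbind(bias = 1, x = x), y)
  ref <- summary(lm(y ~ x))$coefficients
  expect_equal(ours$estimate, unname(ref[, 1]), tolerance = 1e-10)
  expect_equal(ours$se, unname(ref[, 2]), tolerance = 1e-10)
  expect_equal(ours$statistic, unname(ref[, 3]), tolerance = 1e-10)

  expect_error(fit_ols(cbind(1, 1:3, rnorm(3), rnorm(3)), rnorm(3)),
               "more observations")
})

test_that("group t-test handles the degenerate inputs", {
  z <- suppressWarnings(group_ttest(rep(0, 10)))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_warning(group_ttest(rep(0, 10)), "zero variance")
  expect_error(group_ttest(5), "at least 2")
})

test_that("group t-test power matches the noncentral-t prediction", {
  n <- 19
  mu <- 0.5
  reject <- beliefstate:::with_seed(92, {
    vapply(1:2000, function(i) {
      group_ttest(rnorm(n, mu, 1))$p < 0.05
    }, logical(1))
  })
  predicted <- {
    ncp <- mu * sqrt(n)
    tc <- qt(0.975, n - 1)
    1 - pt(tc, n - 1, ncp) + pt(-tc, n - 1, ncp)
  }
  mc_se <- sqrt(predicted * (1 - predicted) / 2000)
  expect_lt(abs(mean(reject) - predicted), 4 * mc_se)
})

test_that("coupling regression recovers a planted slope and lag shifts kill it", {
  # direct construction: random-walk pupil, drs = slope * dpupil + noise
  set.seed(93)
  slope <- -0.5
  n_sub <- 8
  n <- 120
  mk <- function(s) {
    pupil <- cumsum(rnorm(n, 0, 1))
    rs <- numeric(n)
    rs[1] <- 0
    for (i in 2:n) rs[i] <- rs[i - 1] + slope * (pupil[i] - pupil[i - 1]) +
        rnorm(1, 0, 0.3)
    list(
      trials = tibble::tibble(subject = s, run = 0L, t = 0:(n - 1),
                              chosen = 0L,
                              outcome = rep(c(0L, 1L), n / 2),
                              phase = "exploit", core_exploit = TRUE),
      beliefs = tibble::tibble(subject = s, run = 0L, t = 0:(n - 1),
                               entropy = runif(n)),
      rs = tibble::tibble(subject = s, run = 0L, t = 0:(n - 1),
                          rep_strength = rs),
      pupil = tibble::tibble(subject = s, run = 0L, t = 0:(n - 1),
                             baseline = pupil)
    )
  }
  parts <- lapply(1:n_sub, mk)
  trials <- dplyr::bind_rows(lapply(parts, `[[`, "trials"))
  beliefs <- dplyr::bind_rows(lapply(parts, `[[`, "beliefs"))
  rs <- dplyr::bind_rows(lapply(parts, `[[`, "rs"))
  pupil <- dplyr::bind_rows(lapply(parts, `[[`, "pupil"))

  cp <- delta_coupling_regression(rs, pupil, beliefs, trials, lag = 0)
  expect_lt(abs(cp$unrewarded$mean - slope), 0.1)
  expect_lt(abs(cp$rewarded$mean - slope), 0.1)
  expect_lt(cp$unrewarded$p, 0.001)

  cp1 <- delta_coupling_regression(rs, pupil, beliefs, trials, lag = 1)
  expect_lt(abs(cp1$unrewarded$mean), 0.15)
  expect_gt(cp1$unrewarded$p, 0.05)
})

test_that("median split uses the documented tie rule and rejects constants", {
  d <- tibble::tibble(subject = 1,
                      dpupil = c(1, 2, 3, 4, 5),
                      drs = c(10, 10, 10, 0, 0))
  # median (3) goes to the lower half: high = {4, 5}
  g <- suppressWarnings(median_split_contrast(dplyr::bind_rows(d, dplyr::mutate(d, subject = 2))))
  expect_equal(g$estimates, rep(mean(c(0, 0)) - mean(c(10, 10, 10)), 2))

  bad <- tibble::tibble(subject = 1, dpupil = rep(1, 6), drs = rnorm(6))
  expect_error(median_split_contrast(bad), "identical")
})

test_that("GLM7 recovers a planted entropy-change coupling within 2 SE", {
  co <- make_small_cohort(n_subjects = 1, n_trials = 200, n_runs = 4,
                          master_seed = 94)
  sig <- generate_univariate_signal(co$beliefs, b = 0.8, noise_sd = 0.3,
                                    seed = 95)
  des <- build_design("GLM7", co$trials, co$beliefs)
  f <- fit_ols(des, sig$signal)
  b_hat <- f$estimate[f$term == "dent_prev"]
  b_se <- f$se[f$term == "dent_prev"]
  expect_lt(abs(b_hat - 0.8), 2 * b_se)
})

test_that("cluster correction finds planted clusters and nothing in noise", {
  dims <- c(8, 8, 8)
  nvox <- prod(dims)
  n_sub <- 19
  set.seed(96)
  noise <- matrix(rnorm(n_sub * nvox), nrow = n_sub)
  res0 <- cluster_mass_correction(noise, dims, n_perm = 100, seed = 97)
  expect_true(all(!res0$clusters$significant) || nrow(res0$clusters) == 0)

  # plant a strong 3x3x3 block
  coords <- as.matrix(expand.grid(1:8, 1:8, 1:8))
  block <- which(coords[, 1] %in% 3:5 & coords[, 2] %in% 3:5 & coords[, 3] %in% 3:5)
  planted <- noise
  planted[, block] <- planted[, block] + 1.5
  res1 <- cluster_mass_correction(planted, dims, n_perm = 100, seed = 97)
  expect_gt(nrow(res1$clusters), 0)
  expect_true(any(res1$clusters$significant))
  # the significant cluster sits on the planted block
  sup <- which(res1$tmap > res1$tcrit)
  expect_gt(mean(sup %in% block), 0.9)
})

test_that("sample sizes reproduce the exact noncentral-t calculations", {
  expect_equal(sample_size_t(0.89), 17)
  expect_equal(sample_size_t(1.58), 6)
  expect_equal(sample_size_t(1.77), 5)
  # cross-check the power function against the reference solver
  ref <- power.t.test(delta = 0.89, sd = 1, sig.level = 0.05, power = 0.8,
                      type = "two.sample", alternative = "one.sided")$n
  expect_equal(sample_size_t(0.89), ceiling(ref))
  # monotonicity
  ds <- c(0.3, 0.6, 0.9, 1.5)
  ns <- vapply(ds, sample_size_t, numeric(1))
  expect_true(all(diff(ns) <= 0))
  expect_gte(sample_size_t(0.89, power = 0.9), sample_size_t(0.89, power = 0.8))
  expect_error(sample_size_t(-1), "positive")
  expect_error(sample_size_t(1e-4, n_max = 100), "unattainable")
})

test_that("tidiers return the expected shapes", {
  g <- group_ttest(rnorm(10, 1), label = "demo")
  expect_equal(nrow(tidy(g)), 1)
  expect_true(all(c("estimate", "statistic", "p.value") %in% names(tidy(g))))
  expect_equal(glance(g)$n_subjects, 10)
})
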