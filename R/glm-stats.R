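#' Ordinary least squares with classical standard errors
#'
#' @param X Design matrix (or a `design_matrix`, whose subset mask is then
#'   applied).
#' @param y Dependent series.
#' @return A tibble of class `ols_fit`: `term`, `estimate`, `se`, `statistic`,
#'   `p.value`; residual df in `attr(, "df")`.
#' @export
#' @examples
#' X <- cbind(bias = 1, x = 1:10)
#' fit_ols(X, 1 + 2 * (1:10))
fit_ols <- function(X, y) {
  if (inherits(X, "design_matrix")) {
    keep <- X$subset
    y <- y[keep]
    X <- X$X[keep, , drop = FALSE]
  }
  X <- as.matrix(X)
  cc <- stats::complete.cases(X) & !is.na(y)
  X <- X[cc, , drop = FALSE]
  y <- y[cc]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("fit_ols: need more observations than columns", call. = FALSE)
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df <- n - p
  sigma2 <- rss / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(xtx_inv) * sigma2)
  est <- fit$coefficients
  out <- tibble::tibble(
    term = colnames(X) %||% paste0("x", seq_len(p)),
    estimate = unname(est), se = se,
    statistic = unname(est) / se,
    p.value = 2 * pt(-abs(unname(est) / se), df)
  )
  attr(out, "df") <- df
  class(out) <- c("ols_fit", class(out))
  out
}

#' One-sample t-test across subjects on per-subject effects
#'
#' The group-level stage: subject-wise regression coefficients are tested
#' against zero with a one-sample t-test (the summary-statistics approach to
#' group inference).
#'
#' @param estimates Numeric vector of per-subject effects.
#' @param direction `"two.sided"` (default), `"less"`, or `"greater"`.
#' @param label Optional description of the effect.
#' @return A list of class `group_result`: `estimates`, `mean`, `t`, `df`,
#'   `p`, `conf.int` (95%), `direction`, `zero_variance` flag, `label`.
#' @export
group_ttest <- function(estimates, direction = "two.sided", label = NULL) {
  estimates <- estimates[!is.na(estimates)]
  if (length(estimates) < 2) stop("group_ttest: need at least 2 subjects", call. = FALSE)
  zero_var <- isTRUE(all.equal(var(estimates), 0)) || var(estimates) == 0
  if (zero_var) {
    warning("group_ttest: zero variance across subjects", call. = FALSE)
    tt <- list(statistic = c(t = if (mean(estimates) == 0) 0 else Inf * sign(mean(estimates))),
               parameter = c(df = length(estimates) - 1),
               p.value = if (mean(estimates) == 0) 1 else 0,
               conf.int = rep(mean(estimates), 2))
  } else {
    tt <- t.test(estimates, mu = 0, alternative = direction)
  }
  structure(
    list(estimates = estimates, mean = mean(estimates),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, conf.int = as.numeric(tt$conf.int),
         direction = direction, zero_variance = zero_var, label = label),
    class = "group_result"
  )
}

#' @export
#' @method print group_result
print.group_result <- function(x, ...) {
  cat(sprintf("Group one-sample t-test%s\n",
              if (!is.null(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  n = %d, mean = %.4g, t(%d) = %.3f, p = %.4g (%s)\n",
              length(x$estimates), x$mean, x$df, x$t, x$p, x$direction))
  invisible(x)
}

#' Group-level trial-wise regression for a cohort
#'
#' Per subject, builds the named recipe's design ([build_design()]), fits OLS
#' against the dependent series, and extracts one coefficient; the subject
#' coefficients are then tested against zero with [group_ttest()].
#'
#' @param recipe Recipe id (`"GLM1"`..`"GLM8"`).
#' @param trials Labelled cohort tibble (`subject` column required).
#' @param beliefs Cohort belief series.
#' @param dependent Tibble `subject`, `run`, `t`, `value` with the dependent
#'   series, or the name of a column in `trials`/`beliefs`.
#' @param coef Name of the design column to take to the group level.
#' @param pupil Optional cohort baseline tibble (with `subject`).
#' @param extra Optional function `(subject_id) -> named list` of extra
#'   series, or a single named list reused for every subject.
#' @param per_run_bias Passed to [build_design()] (default TRUE: trial-wise
#'   analyses concatenate runs).
#' @param direction Alternative for the group test.
#' @return A `group_result`.
#' @export
run_group_glm <- function(recipe, trials, beliefs, dependent, coef,
                          pupil = NULL, extra = NULL, per_run_bias = TRUE,
                          direction = "two.sided") {
  subjects <- sort(unique(trials$subject))
  betas <- vapply(subjects, function(s) {
    tr <- trials[trials$subject == s, ]
    be <- beliefs[beliefs$subject == s, ]
    pu <- if (!is.null(pupil)) pupil[pupil$subject == s, ] else NULL
    ex <- if (is.function(extra)) extra(s) else extra
    des <- build_design(recipe, tr, be, pupil = pu, extra = ex,
                        per_run_bias = per_run_bias)
    yv <- if (is.character(dependent)) {
      if (dependent %in% names(tr)) tr[[dependent]] else be[[dependent]]
    } else {
      d <- dependent[dependent$subject == s, ]
      d$value[match(paste(tr$run, tr$t), paste(d$run, d$t))]
    }
    fit <- fit_ols(des, yv)
    fit$estimate[match(coef, fit$term)]
  }, numeric(1))
  group_ttest(betas, direction = direction,
              label = paste0(recipe, ": ", coef))
}

#' Per-trial change table joining representation strength, pupil and entropy
#'
#' Aligns the representation-strength, pupil-baseline and entropy series for
#' a cohort and computes their trial-to-next-trial changes
#' (`dx(t) = x_{t+1} - x_t` within run), together with the current trial's
#' reward and core-exploit status. `lag` shifts the pupil series by whole
#' trials before differencing (the temporal-specificity control).
#'
#' @param rs Cohort representation-strength tibble (`subject`, `run`, `t`,
#'   `rep_strength`).
#' @param pupil Cohort baseline tibble (`subject`, `run`, `t`, `baseline`,
#'   optionally `excluded`).
#' @param beliefs Cohort belief series.
#' @param trials Labelled cohort trial tibble.
#' @param lag Integer trial shift of the pupil series (default 0).
#' @return Tibble `subject`, `run`, `t`, `drs`, `dpupil`, `dent`, `rewarded`,
#'   `core`.
#' @export
coupling_delta_table <- function(rs, pupil, beliefs, trials, lag = 0) {
  purrr::map_dfr(sort(unique(trials$subject)), function(s) {
    tr <- trials[trials$subject == s, ]
    be <- beliefs[beliefs$subject == s, ]
    r <- rs[rs$subject == s, ]
    pu <- pupil[pupil$subject == s, ]
    purrr::map_dfr(sort(unique(tr$run)), function(rr) {
      ti <- tr[tr$run == rr, ]; ti <- ti[order(ti$t), ]
      bi <- be[be$run == rr, ]; bi <- bi[order(bi$t), ]
      key <- paste(rr, ti$t)
      rsv <- r$rep_strength[match(key, paste(r$run, r$t))]
      pb <- pu$baseline[match(key, paste(pu$run, pu$t))]
      if ("excluded" %in% names(pu)) {
        pb[pu$excluded[match(key, paste(pu$run, pu$t))] %in% TRUE] <- NA_real_
      }
      # lagged pupil: pupil value taken from trial t + lag
      n <- length(pb)
      pb_lag <- rep(NA_real_, n)
      src <- seq_len(n) + lag
      ok <- src >= 1 & src <= n
      pb_lag[ok] <- pb[src[ok]]
      tibble::tibble(
        subject = s, run = rr, t = ti$t,
        drs = delta_next(rsv),
        dpupil = delta_next(pb_lag),
        dent = delta_next(bi$entropy),
        rewarded = ti$outcome == 1,
        core = ti$core_exploit
      )
    })
  })
}

#' Pupil-to-representation coupling regression (reward-split, with lag control)
#'
#' Per subject, on core-exploit trials with valid pupil baselines on the
#' current and next trial, regresses the change in representation strength
#' from the current trial to the next on the corresponding change in baseline
#' pupil size (with the change in model entropy and a bias as co-regressors),
#' separately for rewarded and unrewarded trials. The per-subject pupil
#' coefficients are tested at the group level per split, and the
#' rewarded-minus-unrewarded difference with a paired t-test. `lag` shifts
#' the pupil series by whole trials relative to the representation-strength
#' series (the temporal-specificity control; the planted effect should exist
#' at lag 0 only).
#'
#' @param rs Cohort representation-strength tibble (`subject`, `run`, `t`,
#'   `rep_strength`).
#' @param pupil Cohort baseline tibble (`subject`, `run`, `t`, `baseline`,
#'   optionally `excluded`).
#' @param beliefs Cohort belief series.
#' @param trials Labelled cohort trial tibble.
#' @param lag Integer trial shift applied to the pupil series (default 0).
#' @param min_trials Minimum usable trials per split; subjects below it are
#'   excluded from that split (default 10).
#' @return A list of class `coupling_result`: `unrewarded`, `rewarded`
#'   (group_results on the pupil coefficient), `difference` (paired t-test:
#'   rewarded minus unrewarded), `per_subject` tibble, `lag`.
#' @export
delta_coupling_regression <- function(rs, pupil, beliefs, trials, lag = 0,
                                      min_trials = 10) {
  tab <- coupling_delta_table(rs, pupil, beliefs, trials, lag = lag)
  per <- purrr::map_dfr(sort(unique(trials$subject)), function(s) {
    rows <- tab[tab$subject == s, ]
    rows <- rows[rows$core & complete.cases(rows[, c("drs", "dpupil", "dent")]), ]
    fit_split <- function(d) {
      if (nrow(d) < min_trials) return(NA_real_)
      f <- fit_ols(cbind(bias = 1, dpupil = d$dpupil, dent = d$dent), d$drs)
      f$estimate[f$term == "dpupil"]
    }
    tibble::tibble(
      subject = s,
      beta_unrewarded = fit_split(rows[!rows$rewarded, ]),
      beta_rewarded = fit_split(rows[rows$rewarded, ]),
      n_unrewarded = sum(!rows$rewarded),
      n_rewarded = sum(rows$rewarded)
    )
  })
  unrew <- group_ttest(per$beta_unrewarded, label = "dpupil -> dRS (unrewarded)")
  rew <- group_ttest(per$beta_rewarded, label = "dpupil -> dRS (rewarded)")
  both <- complete.cases(per[, c("beta_unrewarded", "beta_rewarded")])
  diff_t <- t.test(per$beta_rewarded[both], per$beta_unrewarded[both], paired = TRUE)
  structure(
    list(unrewarded = unrew, rewarded = rew,
         difference = list(t = unname(diff_t$statistic),
                           df = unname(diff_t$parameter),
                           p = diff_t$p.value,
                           mean = unname(diff_t$estimate)),
         per_subject = per, lag = lag),
    class = "coupling_result"
  )
}

#' @export
#' @method print coupling_result
print.coupling_result <- function(x, ...) {
  cat(sprintf("Pupil-representation coupling (lag %d)\n", x$lag))
  cat(sprintf("  unrewarded: mean beta = %.4g, t(%d) = %.2f, p = %.4g\n",
              x$unrewarded$mean, x$unrewarded$df, x$unrewarded$t, x$unrewarded$p))
  cat(sprintf("  rewarded:   mean beta = %.4g, t(%d) = %.2f, p = %.4g\n",
              x$rewarded$mean, x$rewarded$df, x$rewarded$t, x$rewarded$p))
  cat(sprintf("  difference (rew - unrew): t(%d) = %.2f, p = %.4g\n",
              x$difference$df, x$difference$t, x$difference$p))
  invisible(x)
}

#' Median-split contrast of representation-strength change by pupil change
#'
#' Per subject, splits the supplied trials at the subject's median pupil
#' change (trials at the median go to the lower half) and compares the mean
#' change in representation strength between the high and low halves; the
#' per-subject differences (high minus low) are tested across subjects.
#'
#' @param data Tibble with columns `subject`, `drs`, `dpupil` (already
#'   restricted to the trial subset of interest).
#' @return A `group_result` on the per-subject mean differences.
#' @export
median_split_contrast <- function(data) {
  diffs <- purrr::map_dbl(sort(unique(data$subject)), function(s) {
    d <- data[data$subject == s, ]
    d <- d[complete.cases(d[, c("drs", "dpupil")]), ]
    if (nrow(d) < 4) return(NA_real_)
    med <- median(d$dpupil)
    if (all(d$dpupil == d$dpupil[1])) {
      stop("median_split_contrast: all pupil changes identical for subject ", s,
           call. = FALSE)
    }
    hi <- d$dpupil > med
    mean(d$drs[hi]) - mean(d$drs[!hi])
  })
  group_ttest(diffs, label = "mean dRS, high minus low dpupil half")
}
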