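#' Label trials as exploitation or exploration
#'
#' An exploit block begins on the first trial on which the agent selects the
#' current true high-reward option and receives reward, and ends on the last
#' trial before the choice switches to a different option (so within a block
#' all choices are identical, by construction). All other trials are explore.
#' If the environment switches mid-block while the agent keeps choosing the
#' old option, those trials remain exploit until the choice switches: the end
#' rule is purely choice-based. A new block cannot begin before the previous
#' one ends.
#'
#' @param trials Trial tibble for one subject (`run`, `t`, `chosen`,
#'   `outcome`, `true_high`).
#' @return The input with added columns `phase` (`"explore"`/`"exploit"`) and
#'   `block_id` (integer per exploit block, `NA` on explore trials).
#' @export
#' @examples
#' tr <- tibble::tibble(run = 0, t = 0:5, chosen = c(1, 2, 2, 2, 2, 3),
#'                      outcome = c(0, 0, 1, 1, 1, 0), true_high = 2,
#'                      payout_high = 0.9)
#' label_phases(tr)$phase
label_phases <- function(trials) {
  lab_run <- function(df) {
    df <- df[order(df$t), ]
    n <- nrow(df)
    phase <- rep("explore", n)
    block <- rep(NA_integer_, n)
    b <- 0L
    i <- 1L
    while (i <= n) {
      starts <- df$chosen[i] == df$true_high[i] && df$outcome[i] == 1
      if (starts) {
        j <- i
        while (j < n && df$chosen[j + 1L] == df$chosen[i]) j <- j + 1L
        b <- b + 1L
        phase[i:j] <- "exploit"
        block[i:j] <- b
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
    df$phase <- phase
    df$block_id <- block
    df
  }
  grouping <- if ("subject" %in% names(trials)) c("subject", "run") else "run"
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::group_modify(function(df, key) lab_run(df)) |>
    dplyr::ungroup()
}

#' Core-exploitation mask
#'
#' Flags exploit trials at distance at least `k` trials after the preceding
#' choice switch and at least `k` trials before the next choice switch, so
#' that within the flagged trials there is no variation in overt action close
#' by. Run boundaries count as switches.
#'
#' @param labels Output of [label_phases()].
#' @param k Minimum distance in trials from the surrounding switches
#'   (default 5).
#' @return Logical vector aligned with the rows of `labels`.
#' @export
core_exploit_mask <- function(labels, k = 5) {
  if (k < 0) stop("core_exploit_mask: k must be non-negative", call. = FALSE)
  mask_run <- function(df) {
    df <- df[order(df$t), ]
    n <- nrow(df)
    # switch indices: positions (1-based) at which a new choice segment starts
    sw <- c(1L, which(df$chosen[-1] != df$chosen[-n]) + 1L, n + 1L)
    prev_sw <- sw[findInterval(seq_len(n), sw)]
    next_sw <- vapply(seq_len(n), function(i) sw[which(sw > i)[1]], numeric(1))
    df$core_exploit <- df$phase == "exploit" &
      (seq_len(n) - prev_sw) >= k & (next_sw - seq_len(n)) >= k
    df
  }
  grouping <- if ("subject" %in% names(labels)) c("subject", "run") else "run"
  out <- labels |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::group_modify(function(df, key) mask_run(df)) |>
    dplyr::ungroup()
  # restore original row order
  key <- do.call(paste, c(labels[grouping], list(labels$t)))
  okey <- do.call(paste, c(out[grouping], list(out$t)))
  out$core_exploit[match(key, okey)]
}

#' Add phase labels and the core-exploit flag to a trial table
#'
#' Convenience wrapper running [label_phases()] then [core_exploit_mask()].
#'
#' @param trials Trial tibble (single subject or cohort with `subject`).
#' @param k Core-exploit distance (default 5).
#' @return Labelled tibble with `phase`, `block_id`, `core_exploit`.
#' @export
label_trials <- function(trials, k = 5) {
  lab <- label_phases(trials)
  lab$core_exploit <- core_exploit_mask(lab, k = k)
  lab
}

softmax_loglik <- function(beta, p_mat, chosen_pos) {
  z <- beta * p_mat
  sum(z[cbind(seq_len(nrow(z)), chosen_pos)] - apply(z, 1, logsumexp))
}

fit_softmax_one <- function(p_mat, chosen_pos, upper = 100) {
  if (nrow(p_mat) < 5) {
    return(list(beta = NA_real_, loglik = NA_real_, accuracy = NA_real_,
                n = nrow(p_mat), skipped = TRUE, non_identified = FALSE))
  }
  opt <- optimize(function(b) -softmax_loglik(b, p_mat, chosen_pos),
                  interval = c(0, upper), tol = 1e-6)
  beta <- opt$minimum
  # argmax of the fitted policy = argmax of beliefs; ties to lowest position
  pred <- apply(p_mat, 1, which.max)
  list(beta = beta, loglik = -opt$objective,
       accuracy = mean(pred == chosen_pos), n = nrow(p_mat),
       skipped = FALSE, non_identified = beta > 0.995 * upper)
}

#' Fit phase-specific softmax choice policies by maximum likelihood
#'
#' Fits two multinomial softmax policies on the option beliefs `p(H_i)` --
#' one to explore trials and one to exploit trials -- where the probability
#' of choosing option `i` is proportional to `exp(beta * p(H_i))` over the
#' four available options. Beliefs are the post-leak prior marginals entering
#' each trial (a choice cannot depend on the not-yet-seen outcome). `beta` is
#' bounded to `[0, upper]`; estimates at the bound are flagged non-identified
#' (perfectly greedy data give an unbounded likelihood). Accuracy is the
#' fraction of trials on which the fitted policy's modal option (ties broken
#' toward the lowest option id) matches the actual choice. Phases with fewer
#' than 5 trials are flagged and skipped.
#'
#' @param trials Trial tibble for one subject.
#' @param beliefs Matching [run_observer()] output.
#' @param labels Matching [label_phases()] output (or `trials` already
#'   labelled); only the `phase` column is used.
#' @param upper Upper bound for `beta` (default 100).
#' @return An object of class `softmax_fit`: a list with per-phase entries
#'   (`beta`, `loglik`, `accuracy`, `n`, flags).
#' @export
fit_softmax_policy <- function(trials, beliefs, labels = trials, upper = 100) {
  stopifnot(nrow(trials) == nrow(beliefs), nrow(trials) == nrow(labels))
  prior <- as.matrix(beliefs[, c("prior_pH1", "prior_pH2", "prior_pH3", "prior_pH4")])
  chosen_pos <- integer(nrow(trials))
  for (r in unique(trials$run)) {
    idx <- trials$run == r
    avail <- sort(unique(trials$chosen[idx]))
    chosen_pos[idx] <- match(trials$chosen[idx], avail)
  }
  fits <- lapply(c(explore = "explore", exploit = "exploit"), function(ph) {
    sel <- labels$phase == ph
    fit_softmax_one(prior[sel, , drop = FALSE], chosen_pos[sel], upper = upper)
  })
  structure(
    list(explore = fits$explore, exploit = fits$exploit,
         beta_explore = fits$explore$beta, beta_exploit = fits$exploit$beta,
         accuracy_explore = fits$explore$accuracy,
         accuracy_exploit = fits$exploit$accuracy,
         log_likelihood = sum(c(fits$explore$loglik, fits$exploit$loglik), na.rm = TRUE)),
    class = "softmax_fit"
  )
}

#' @export
#' @method print softmax_fit
print.softmax_fit <- function(x, ...) {
  cat("Softmax policy fit (choice probability ~ exp(beta * p(H_i)))\n")
  cat(sprintf("  explore: beta = %.3f, accuracy = %.3f (n = %d)%s\n",
              x$explore$beta, x$explore$accuracy, x$explore$n,
              if (isTRUE(x$explore$non_identified)) " [at bound]" else ""))
  cat(sprintf("  exploit: beta = %.3f, accuracy = %.3f (n = %d)%s\n",
              x$exploit$beta, x$exploit$accuracy, x$exploit$n,
              if (isTRUE(x$exploit$non_identified)) " [at bound]" else ""))
  invisible(x)
}

fit_logistic_safe <- function(x, y) {
  if (length(unique(y)) < 2) return(list(slope = NA_real_, excluded = TRUE))
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  slope <- coef(fit)[["x"]]
  if (!fit$converged || abs(slope) > 50) {
    # near-separation: ridge-penalized fallback
    warning("switch_logistic: separation detected; using ridge-penalized fit",
            call. = FALSE)
    xm <- cbind(x, jitter_col = 0)  # glmnet needs >= 2 columns
    slope <- tryCatch({
      gfit <- glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                             lambda = 1e-3, standardize = FALSE)
      as.numeric(coef(gfit))[2]
    }, error = function(e) slope)  # too few rows even for the ridge fit
  }
  list(slope = slope, excluded = FALSE)
}

#' Does uncertainty predict the decision to start exploring?
#'
#' On exploit trials with reward omission, regresses (logistically, per
#' subject) whether the next trial initiates exploration (a choice switch)
#' on a trial-wise uncertainty predictor, then tests the per-subject slopes
#' against zero with a one-sample t-test.
#'
#' Subjects with no omission trials, or with all-identical outcomes, are
#' excluded with a warning; complete separation falls back to a
#' ridge-penalized fit.
#'
#' @param cohort Labelled cohort trial tibble (`subject`, `run`, `t`,
#'   `chosen`, `outcome`, `phase`).
#' @param beliefs Cohort belief series from [run_observer_cohort()].
#' @param predictor `"entropy"` or `"relative_uncertainty"`.
#' @return A `group_result` object (see [group_ttest()]) whose per-subject
#'   estimates are the logistic slopes.
#' @export
switch_logistic <- function(cohort, beliefs, predictor = c("entropy", "relative_uncertainty")) {
  predictor <- match.arg(predictor)
  stopifnot("phase" %in% names(cohort))
  dat <- dplyr::bind_cols(
    cohort[, c("subject", "run", "t", "chosen", "outcome", "phase")],
    beliefs[, predictor]
  )
  slopes <- purrr::map_dbl(sort(unique(dat$subject)), function(s) {
    d <- dat[dat$subject == s, ]
    d <- d |>
      dplyr::group_by(.data$run) |>
      dplyr::arrange(.data$t, .by_group = TRUE) |>
      dplyr::mutate(switch_next = c(.data$chosen[-1] != .data$chosen[-dplyr::n()], NA)) |>
      dplyr::ungroup()
    d <- d[d$phase == "exploit" & d$outcome == 0 & !is.na(d$switch_next), ]
    if (nrow(d) == 0) {
      warning(sprintf("switch_logistic: subject %s has no omission trials; excluded", s),
              call. = FALSE)
      return(NA_real_)
    }
    res <- fit_logistic_safe(d[[predictor]], as.integer(d$switch_next))
    if (res$excluded) {
      warning(sprintf("switch_logistic: subject %s has constant outcomes; excluded", s),
              call. = FALSE)
      return(NA_real_)
    }
    res$slope
  })
  group_ttest(slopes[!is.na(slopes)], label = paste0("switch ~ ", predictor))
}
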