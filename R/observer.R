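#' Configuration of the Bayesian ideal observer
#'
#' The observer tracks a joint posterior over four hypotheses (which of the
#' four available options is the high-reward option) crossed with a grid of
#' candidate high payout rates `p = 0.30, 0.31, ..., 1.00` (71 values; the
#' lower bound keeps the high rate above the fixed 0.2 of the low options).
#' Between trials the posterior is mixed with a uniform distribution over the
#' full 4 x 71 grid with weight `s` (the leak), so the model can forget and
#' track environmental switches.
#'
#' @param s Leak / switch probability per trial (default 1/20 = 0.05, the true
#'   mean switch frequency of the task).
#' @param p_grid Payout-rate grid (default `seq(0.30, 1.00, by = 0.01)`).
#' @param payout_low Fixed reward probability of non-high options (0.2).
#' @param log_base Base for entropy (`exp(1)` for nats, the default, or 2).
#' @return A list of class `observer_config`.
#' @export
#' @examples
#' observer_config()$s
observer_config <- function(s = 0.05,
                            p_grid = seq(0.30, 1.00, by = 0.01),
                            payout_low = 0.2,
                            log_base = exp(1)) {
  if (s < 0 || s >= 1) stop("observer_config: s must be in [0, 1)", call. = FALSE)
  if (any(diff(p_grid) <= 0) || any(p_grid <= 0) || any(p_grid > 1)) {
    stop("observer_config: p_grid must be strictly increasing within (0, 1]", call. = FALSE)
  }
  structure(
    list(s = s, p_grid = p_grid, payout_low = payout_low,
         log_base = log_base, n_hyp = 4L),
    class = "observer_config"
  )
}

#' Initialize a uniform belief grid
#'
#' @param config An [observer_config()].
#' @return A `n_hyp x length(p_grid)` matrix of class `belief_grid` with all
#'   cells equal (1/284 at defaults), config attached as an attribute.
#' @export
#' @examples
#' b <- init_belief(observer_config())
#' dim(b); sum(b)
init_belief <- function(config = observer_config()) {
  k <- length(config$p_grid)
  b <- matrix(1 / (config$n_hyp * k), nrow = config$n_hyp, ncol = k)
  structure(b, class = c("belief_grid", "matrix"), config = config)
}

belief_config <- function(belief) attr(belief, "config")

#' Bayes update of the belief grid after one outcome
#'
#' Each cell `(h, p)` is multiplied by the likelihood of the observed outcome
#' under the payout matrix `M[h, chosen, p]`, which equals `p` when the
#' hypothesized high option `h` is the chosen option and the fixed low rate
#' (0.2) otherwise; the grid is then renormalized.
#'
#' @param belief A `belief_grid`.
#' @param chosen Hypothesis position of the chosen option, 1..4 (i.e. the rank
#'   of the chosen option id within the sorted available set of its run).
#' @param outcome 0 (no reward) or 1 (reward).
#' @return The updated, normalized `belief_grid`.
#' @export
#' @examples
#' b <- update_with_outcome(init_belief(), chosen = 1, outcome = 1)
#' rowSums(b)  # 0.52, 0.16, 0.16, 0.16
update_with_outcome <- function(belief, chosen, outcome) {
  cfg <- belief_config(belief)
  if (!chosen %in% seq_len(cfg$n_hyp)) {
    stop("update_with_outcome: chosen must be a hypothesis position 1..4", call. = FALSE)
  }
  if (!outcome %in% c(0, 1)) stop("update_with_outcome: outcome must be 0 or 1", call. = FALSE)
  q <- matrix(cfg$payout_low, nrow = cfg$n_hyp, ncol = length(cfg$p_grid))
  q[chosen, ] <- cfg$p_grid
  lik <- if (outcome == 1) q else 1 - q
  b <- unclass(belief) * lik
  tot <- sum(b)
  if (!is.finite(tot) || tot <= 0) {
    stop("update_with_outcome: zero total likelihood", call. = FALSE)
  }
  structure(b / tot, class = class(belief), config = cfg)
}

#' Apply the uniform leak (transition function)
#'
#' Returns `(1 - s) * belief + s * uniform`, the mixing with a uniform
#' distribution over the full hypothesis-by-payout grid that serves as the
#' prior for the next trial.
#'
#' @param belief A `belief_grid`.
#' @param s Leak weight in `[0, 1)`; defaults to the config value.
#' @return The leaked `belief_grid`.
#' @export
apply_leak <- function(belief, s = belief_config(belief)$s) {
  if (s < 0 || s >= 1) stop("apply_leak: s must be in [0, 1)", call. = FALSE)
  cfg <- belief_config(belief)
  u <- 1 / length(belief)
  structure((1 - s) * unclass(belief) + s * u, class = class(belief), config = cfg)
}

#' Marginal belief that each option is the high-reward option
#'
#' @param belief A `belief_grid`.
#' @return A 4-vector of marginals (sums over the payout grid).
#' @export
belief_marginals <- function(belief) rowSums(unclass(belief))

#' Shannon entropy of a marginal belief vector
#'
#' `-sum(p * log(p))` with the convention `0 * log(0) = 0`.
#'
#' @param marginals Normalized probability vector.
#' @param base Logarithm base (default natural log, i.e. nats).
#' @return Scalar entropy.
#' @export
#' @examples
#' belief_entropy(rep(0.25, 4))  # log(4)
belief_entropy <- function(marginals, base = exp(1)) {
  if (any(marginals < 0)) stop("belief_entropy: negative probabilities", call. = FALSE)
  p <- marginals[marginals > 0]
  -sum(p * log(p, base = base))
}

#' Summaries of a belief grid
#'
#' Computes the option marginals, the entropy over hypotheses, relative
#' uncertainty, and the expected value of selecting each option,
#' `EV(i) = sum_{h,p} mass(h,p) * M[h,i,p]`.
#'
#' Relative uncertainty is implemented as `1 - max_i p(H_i)` (the probability
#' mass not on the modal hypothesis); this is a package definition chosen for
#' its monotone relation to entropy, as the measure has no canonical closed
#' form in this setting. An alternative can be supplied via `ru_fun`.
#'
#' @param belief A `belief_grid`.
#' @param ru_fun Optional function of the marginal 4-vector returning a scalar
#'   relative-uncertainty value.
#' @return A list: `marginals` (4-vector), `entropy`, `relative_uncertainty`,
#'   `expected_value` (4-vector, by hypothesis position).
#' @export
#' @examples
#' belief_summaries(init_belief())$expected_value  # all 0.3125
belief_summaries <- function(belief, ru_fun = NULL) {
  cfg <- belief_config(belief)
  b <- unclass(belief)
  m <- rowSums(b)
  # EV(i): chosen == h contributes sum_p mass(h, p) * p; others contribute
  # payout_low times their total mass.
  ev_own <- as.numeric(b %*% cfg$p_grid)
  ev <- vapply(seq_len(cfg$n_hyp), function(i) {
    ev_own[i] + cfg$payout_low * (1 - m[i])
  }, numeric(1))
  ru <- if (is.null(ru_fun)) 1 - max(m) else ru_fun(m)
  list(
    marginals = m,
    entropy = belief_entropy(m, base = cfg$log_base),
    relative_uncertainty = ru,
    expected_value = ev
  )
}

#' Run the ideal observer over a table of trials
#'
#' Processes runs independently, re-initializing the belief to uniform at the
#' start of each run. For every trial the reported quantities come from the
#' posterior after incorporating that trial's outcome (the belief state at
#' the point of feedback); the leak is applied between trial `t`'s posterior
#' and trial `t + 1`'s prior. The post-leak prior marginals entering each
#' trial are also recorded (`prior_pH*`), since choice policies act on those.
#'
#' @param trials Trial tibble with columns `run`, `t`, `chosen`, `outcome`
#'   (one subject; see [run_observer_cohort()] for many).
#' @param config An [observer_config()].
#' @param available_ids List of available option-id vectors, one per run
#'   (defaults to the distinct chosen ids observed per run, which is correct
#'   for complete simulated data).
#' @return A `belief_series` tibble: `run`, `t`, `chosen`, `pH1..pH4`
#'   (posterior marginals by hypothesis position), `entropy`,
#'   `relative_uncertainty`, `ev_chosen`, `p_chosen` (posterior belief in the
#'   chosen option), `prior_pH1..prior_pH4`.
#' @export
run_observer <- function(trials, config = observer_config(), available_ids = NULL) {
  if (nrow(trials) == 0) {
    return(tibble::tibble(
      run = integer(), t = integer(), chosen = integer(),
      pH1 = numeric(), pH2 = numeric(), pH3 = numeric(), pH4 = numeric(),
      entropy = numeric(), relative_uncertainty = numeric(),
      ev_chosen = numeric(), p_chosen = numeric(),
      prior_pH1 = numeric(), prior_pH2 = numeric(),
      prior_pH3 = numeric(), prior_pH4 = numeric()
    ))
  }
  runs <- sort(unique(trials$run))
  out <- vector("list", length(runs))
  for (ri in seq_along(runs)) {
    tr <- trials[trials$run == runs[ri], ]
    tr <- tr[order(tr$t), ]
    avail <- if (is.null(available_ids)) {
      sort(unique(tr$chosen))
    } else {
      sort(available_ids[[ri]])
    }
    if (!all(tr$chosen %in% avail)) {
      stop("run_observer: chosen option outside the available set", call. = FALSE)
    }
    n <- nrow(tr)
    belief <- init_belief(config)
    res <- matrix(NA_real_, nrow = n, ncol = 12)
    for (i in seq_len(n)) {
      prior_m <- belief_marginals(belief)
      pos <- match(tr$chosen[i], avail)
      belief <- update_with_outcome(belief, pos, tr$outcome[i])
      s <- belief_summaries(belief)
      res[i, ] <- c(s$marginals, s$entropy, s$relative_uncertainty,
                    s$expected_value[pos], s$marginals[pos], prior_m)
      if (i < n) belief <- apply_leak(belief, config$s)
    }
    out[[ri]] <- tibble::tibble(
      run = tr$run, t = tr$t, chosen = tr$chosen,
      pH1 = res[, 1], pH2 = res[, 2], pH3 = res[, 3], pH4 = res[, 4],
      entropy = res[, 5], relative_uncertainty = res[, 6],
      ev_chosen = res[, 7], p_chosen = res[, 8],
      prior_pH1 = res[, 9], prior_pH2 = res[, 10],
      prior_pH3 = res[, 11], prior_pH4 = res[, 12]
    )
  }
  out <- dplyr::bind_rows(out)
  class(out) <- c("belief_series", class(out))
  out
}

#' Run the ideal observer for every subject of a cohort
#'
#' @param cohort Trial tibble with a `subject` column.
#' @param config An [observer_config()].
#' @param available_ids Optional list of available option-id vectors per run
#'   (shared across subjects).
#' @return Belief-series tibble with a leading `subject` column.
#' @export
run_observer_cohort <- function(cohort, config = observer_config(),
                                available_ids = NULL) {
  out <- cohort |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_modify(function(df, key) run_observer(df, config, available_ids)) |>
    dplyr::ungroup()
  class(out) <- c("belief_series", class(out))
  out
}
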