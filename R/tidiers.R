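# broom-style tidiers for the package's result objects.

#' Tidy a group-level test result
#'
#' @param x A `group_result`.
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate`, `statistic`, `df`, `p.value`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.group_result <- function(x, ...) {
  tibble::tibble(
    term = x$label %||% "effect", estimate = x$mean, statistic = x$t,
    df = x$df, p.value = x$p, conf.low = x$conf.int[1], conf.high = x$conf.int[2]
  )
}

#' @rdname tidy.group_result
#' @export
glance.group_result <- function(x, ...) {
  tibble::tibble(n_subjects = length(x$estimates), statistic = x$t, df = x$df,
                 p.value = x$p, zero_variance = x$zero_variance)
}

#' Tidy a softmax policy fit
#'
#' @param x A `softmax_fit`.
#' @param ... Unused.
#' @return Tibble with one row per phase: `phase`, `beta`, `accuracy`, `n`,
#'   `non_identified`, `skipped`.
#' @export
tidy.softmax_fit <- function(x, ...) {
  purrr::map_dfr(c("explore", "exploit"), function(ph) {
    f <- x[[ph]]
    tibble::tibble(phase = ph, beta = f$beta, accuracy = f$accuracy, n = f$n,
                   non_identified = f$non_identified, skipped = f$skipped)
  })
}

#' @rdname tidy.softmax_fit
#' @export
glance.softmax_fit <- function(x, ...) {
  tibble::tibble(log_likelihood = x$log_likelihood,
                 beta_explore = x$beta_explore, beta_exploit = x$beta_exploit)
}

#' Tidy a pupil-coupling regression result
#'
#' @param x A `coupling_result`.
#' @param ... Unused.
#' @return Tibble with rows for the unrewarded split, rewarded split, and
#'   their paired difference.
#' @export
tidy.coupling_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "unrewarded", estimate = x$unrewarded$mean,
                   statistic = x$unrewarded$t, df = x$unrewarded$df,
                   p.value = x$unrewarded$p),
    tibble::tibble(term = "rewarded", estimate = x$rewarded$mean,
                   statistic = x$rewarded$t, df = x$rewarded$df,
                   p.value = x$rewarded$p),
    tibble::tibble(term = "rewarded - unrewarded", estimate = x$difference$mean,
                   statistic = x$difference$t, df = x$difference$df,
                   p.value = x$difference$p)
  )
}

#' Tidy a cluster-mass permutation result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return The cluster table (one row per suprathreshold cluster).
#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' @rdname tidy.cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    tcrit = x$tcrit, n_perm = length(x$null_max_mass), alpha = x$alpha,
    direction = x$direction
  )
}

#' Tidy a voxel-shuffle bias check
#'
#' @param x A `shuffle_bias`.
#' @param ... Unused.
#' @return One-row tibble: `observed`, `null_mean`, `null_sd`, `null_skewness`,
#'   `p.value`, `n_perm`.
#' @export
tidy.shuffle_bias <- function(x, ...) {
  z <- (x$null - mean(x$null)) / sd(x$null)
  tibble::tibble(
    observed = x$observed, null_mean = mean(x$null), null_sd = sd(x$null),
    null_skewness = mean(z^3), p.value = x$p, n_perm = length(x$null)
  )
}
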