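#' Power of an independent two-sample t-test (exact noncentral t)
#'
#' @param n Per-group sample size.
#' @param d Standardized effect size (Cohen's d).
#' @param alpha Significance level.
#' @param tails `"one"` or `"two"`.
#' @return Power in `[0, 1]`.
#' @export
power_two_sample_t <- function(n, d, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  a <- if (tails == "one") alpha else alpha / 2
  tcrit <- qt(1 - a, df)
  pow <- 1 - pt(tcrit, df, ncp = ncp)
  if (tails == "two") pow <- pow + pt(-tcrit, df, ncp = ncp)
  pow
}

#' Minimum per-group sample size for a two-sample t-test
#'
#' Searches for the smallest integer per-group `n` at which an independent
#' two-sample t-test (equal group sizes) attains the target power for a
#' standardized effect `d`, using the exact noncentral-t power function.
#'
#' @param d Standardized effect size (> 0).
#' @param alpha Significance level (default 0.05).
#' @param tails `"one"` (default) or `"two"`.
#' @param power Target power (default 0.8).
#' @param n_max Search cap (default 1e6); exceeding it errors as unattainable.
#' @return Minimum per-group sample size (integer).
#' @export
#' @examples
#' sample_size_t(0.89)  # 17
#' sample_size_t(1.58)  # 6
#' sample_size_t(1.77)  # 5
sample_size_t <- function(d, alpha = 0.05, tails = "one", power = 0.8,
                          n_max = 1e6) {
  if (d <= 0) stop("sample_size_t: d must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("sample_size_t: alpha must be in (0, 1)", call. = FALSE)
  if (power <= 0.5 || power >= 1) stop("sample_size_t: power must be in (0.5, 1)", call. = FALSE)
  n <- 2L
  while (power_two_sample_t(n, d, alpha, tails) < power) {
    n <- n + 1L
    if (n > n_max) stop("sample_size_t: target power unattainable within n_max", call. = FALSE)
  }
  n
}
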