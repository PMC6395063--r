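#' Interpolate blinks in a pupil trace
#'
#' Interior gaps of missing samples are filled linearly between the last
#' valid sample before and the first valid sample after the gap. Gaps at the
#' start or end of a run have no flanking anchor and are never extrapolated;
#' their samples stay missing, and trials whose entire baseline window falls
#' in such a gap are flagged lost downstream.
#'
#' @param trace Tibble with columns `run`, `time_ms`, `value`, `is_missing`.
#' @return The trace with interior gaps filled (`is_missing` updated to mark
#'   only unfilled samples).
#' @export
#' @examples
#' tr <- tibble::tibble(run = 0, time_ms = 0:6 * 10,
#'                      value = c(4, NA, NA, NA, 8, 9, 10),
#'                      is_missing = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' interpolate_blinks(tr)$value  # gap filled 5, 6, 7
interpolate_blinks <- function(trace) {
  fill_run <- function(df) {
    v <- df$value
    miss <- df$is_missing | is.na(v)
    if (!any(miss)) {
      df$is_missing <- miss
      return(df)
    }
    ok <- which(!miss)
    if (length(ok) >= 2) {
      # linear interpolation between flanking valid samples; no extrapolation
      filled <- stats::approx(x = df$time_ms[ok], y = v[ok], xout = df$time_ms,
                              method = "linear", rule = 1)$y
      interior <- miss & !is.na(filled)
      v[interior] <- filled[interior]
      miss <- miss & !interior
    }
    df$value <- v
    df$is_missing <- miss
    df
  }
  trace |>
    dplyr::group_by(.data$run) |>
    dplyr::group_modify(function(df, key) fill_run(df)) |>
    dplyr::ungroup()
}

#' Normalize a pupil trace as percent change from the run mean
#'
#' Each retained (non-missing) sample is expressed as
#' `100 * (value - run_mean) / run_mean`, where `run_mean` is the mean over
#' retained samples of that run; runs are normalized independently.
#'
#' @param trace A (cleaned) trace tibble (`run`, `time_ms`, `value`,
#'   `is_missing`).
#' @return The trace with `value` replaced by the normalized percentage.
#' @export
normalize_trace <- function(trace) {
  norm_run <- function(df) {
    m <- mean(df$value[!df$is_missing], na.rm = TRUE)
    if (!is.finite(m) || m <= 0) {
      stop("normalize_trace: run mean is not positive", call. = FALSE)
    }
    df$value <- 100 * (df$value - m) / m
    df
  }
  trace |>
    dplyr::group_by(.data$run) |>
    dplyr::group_modify(function(df, key) norm_run(df)) |>
    dplyr::ungroup()
}

#' Per-trial baseline pupil size
#'
#' The baseline is the mean of the samples in the half-open window
#' `[feedback - window_ms, feedback)` preceding each trial's feedback (20 ms
#' by default; 20 samples at 1000 Hz). Trials whose window contains no valid
#' sample are flagged lost.
#'
#' @param trace Normalized trace tibble.
#' @param feedback Tibble `run`, `t`, `feedback_ms`.
#' @param window_ms Window length in ms (default 20).
#' @return Tibble `run`, `t`, `baseline`, `lost`.
#' @export
baseline_per_trial <- function(trace, feedback, window_ms = 20) {
  eps <- 1e-9
  purrr::map_dfr(sort(unique(feedback$run)), function(r) {
    tr <- trace[trace$run == r, ]
    tr <- tr[order(tr$time_ms), ]
    fb <- feedback[feedback$run == r, ]
    # half-open window [fb - window, fb): index range via sorted times
    lo <- findInterval(fb$feedback_ms - window_ms - eps, tr$time_ms) + 1L
    hi <- findInterval(fb$feedback_ms - eps, tr$time_ms)
    base <- vapply(seq_len(nrow(fb)), function(i) {
      if (lo[i] > hi[i]) return(NA_real_)
      v <- tr$value[lo[i]:hi[i]]
      v <- v[!tr$is_missing[lo[i]:hi[i]] & !is.na(v)]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    tibble::tibble(run = r, t = fb$t, baseline = base, lost = is.na(base))
  })
}

#' Apply the standard pupil trial exclusions
#'
#' Drops the first `n_lead_trials` trials of each run (to avoid
#' luminance-change transients at run start), trials whose baseline
#' measurement was lost, and -- when `core_exploit_only` -- trials outside
#' the core-exploitation subset.
#'
#' @param baselines Output of [baseline_per_trial()].
#' @param labels Labelled trial tibble (needs `run`, `t`, and `core_exploit`
#'   when `core_exploit_only = TRUE`).
#' @param n_lead_trials Leading trials removed per run (default 25).
#' @param core_exploit_only Restrict to core-exploit trials (default FALSE).
#' @return `baselines` with columns `excluded` (logical) and `reason`
#'   (`NA`, `"lead"`, `"lost"`, or `"not_core"`; the first applicable in that
#'   order).
#' @export
apply_exclusions <- function(baselines, labels = NULL, n_lead_trials = 25,
                             core_exploit_only = FALSE) {
  out <- baselines
  reason <- rep(NA_character_, nrow(out))
  reason[out$t < n_lead_trials] <- "lead"
  reason[is.na(reason) & out$lost] <- "lost"
  if (core_exploit_only) {
    stopifnot(!is.null(labels), "core_exploit" %in% names(labels))
    key <- paste(out$run, out$t)
    lkey <- paste(labels$run, labels$t)
    core <- labels$core_exploit[match(key, lkey)]
    reason[is.na(reason) & !core] <- "not_core"
  }
  out$excluded <- !is.na(reason)
  out$reason <- reason
  out
}

#' Full pupil preprocessing for one subject
#'
#' Blink interpolation, percent normalization per run, baseline extraction,
#' and trial exclusions, in the standard order.
#'
#' @param pupil A `pupil_raw` object (or a list with `trace` and
#'   `feedback_ms`).
#' @param labels Labelled trials for the exclusion step (optional).
#' @param window_ms Baseline window (default 20 ms).
#' @param n_lead_trials Leading trials removed per run (default 25).
#' @param core_exploit_only Passed to [apply_exclusions()].
#' @return Tibble `run`, `t`, `baseline`, `lost`, `excluded`, `reason`.
#' @export
preprocess_pupil <- function(pupil, labels = NULL, window_ms = 20,
                             n_lead_trials = 25, core_exploit_only = FALSE) {
  cleaned <- interpolate_blinks(pupil$trace)
  normed <- normalize_trace(cleaned)
  base <- baseline_per_trial(normed, pupil$feedback_ms, window_ms = window_ms)
  apply_exclusions(base, labels, n_lead_trials = n_lead_trials,
                   core_exploit_only = core_exploit_only)
}
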