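# Trial-wise design-matrix recipes (GLM1..GLM8) for one subject.

# Within-run derived series used by several recipes.
derived_series <- function(trials, beliefs, pupil = NULL) {
  stopifnot(nrow(trials) == nrow(beliefs))
  n <- nrow(trials)
  out <- tibble::tibble(
    run = trials$run, t = trials$t,
    entropy = beliefs$entropy, p_chosen = beliefs$p_chosen,
    reward = as.numeric(trials$outcome),
    exploit = as.numeric(trials$phase == "exploit"),
    explore = as.numeric(trials$phase == "explore"),
    switch_next = NA_real_, last_exploit = NA_real_, first_exploit = NA_real_,
    dent_prev = NA_real_, dent_next = NA_real_,
    dpupil_next = NA_real_
  )
  if (!is.null(pupil)) {
    key <- paste(trials$run, trials$t)
    pb <- pupil$baseline
    pb[pupil$excluded %||% rep(FALSE, nrow(pupil))] <- NA_real_
    out$pupil_baseline <- pb[match(key, paste(pupil$run, pupil$t))]
  }
  for (r in unique(trials$run)) {
    idx <- which(trials$run == r)
    ph <- trials$phase[idx]
    ch <- trials$chosen[idx]
    out$switch_next[idx] <- as.numeric(c(ch[-1] != ch[-length(ch)], NA))
    out$last_exploit[idx] <- as.numeric(c(ph[-length(ph)] == "exploit" & ph[-1] == "explore", NA))
    out$first_exploit[idx] <- as.numeric(c(ph[-length(ph)] == "explore" & ph[-1] == "exploit", NA))
    out$dent_prev[idx] <- delta_prev(out$entropy[idx])
    out$dent_next[idx] <- delta_next(out$entropy[idx])
    if (!is.null(pupil)) out$dpupil_next[idx] <- delta_next(out$pupil_baseline[idx])
  }
  out
}

glm_recipes <- list(
  GLM1 = list(cols = c("exploit", "explore"), bias = FALSE, subset = "all",
              dependent = "univariate"),
  GLM2 = list(cols = c("entropy", "reward", "switch_next", "last_exploit", "first_exploit"),
              bias = TRUE, subset = "all", dependent = "univariate"),
  GLM3 = list(cols = c("exploit", "explore", "entropy", "reward", "switch_next",
                       "last_exploit", "first_exploit"),
              bias = FALSE, subset = "all", dependent = "univariate"),
  GLM4 = list(cols = "entropy", bias = TRUE, subset = "core_exploit",
              dependent = "rep_strength"),
  GLM5 = list(cols = "p_chosen", bias = TRUE, subset = "core_exploit",
              dependent = "rep_strength"),
  GLM6 = list(cols = c("dpupil_next", "dent_next"), bias = TRUE,
              subset = "core_exploit", dependent = "d_rep_strength"),
  GLM7 = list(cols = "dent_prev", bias = TRUE, subset = "core_exploit",
              dependent = "univariate"),
  GLM8 = list(cols = c("signal", "dent_prev", "global_mean"), bias = TRUE,
              subset = "core_exploit", dependent = "d_pupil")
)

#' Build a trial-wise design matrix from a named recipe
#'
#' Implements the regression recipes used throughout the analyses:
#' \describe{
#'   \item{GLM1}{exploit / explore indicators (no extra bias; the indicators
#'     span the intercept). Dependent: univariate activity; all trials.}
#'   \item{GLM2}{bias, model entropy, reward, choice-switch-on-next-trial,
#'     last-exploit-trial and first-exploit-trial indicators; all trials.}
#'   \item{GLM3}{the union of GLM1 and GLM2 regressors (bias dropped: the
#'     phase indicators span it); all trials.}
#'   \item{GLM4}{bias + entropy; dependent: representation strength;
#'     core-exploit trials.}
#'   \item{GLM5}{bias + belief in the exploited option `p(H_chosen)`;
#'     dependent: representation strength; core-exploit trials.}
#'   \item{GLM6}{bias + change in baseline pupil from the current trial to
#'     the next + change in entropy; dependent: change in representation
#'     strength; core-exploit trials, analysed per reward split.}
#'   \item{GLM7}{bias + change in entropy (current minus previous);
#'     dependent: univariate activity; core-exploit trials.}
#'   \item{GLM8}{bias + regional univariate signal + change in entropy +
#'     whole-brain mean signal; dependent: change in baseline pupil;
#'     core-exploit trials. `signal` and `global_mean` come from `extra`.}
#' }
#' With `per_run_bias = TRUE` the bias column is replaced by one indicator
#' per run (the convention when runs are concatenated).
#'
#' @param recipe Recipe id, `"GLM1"` .. `"GLM8"`.
#' @param trials Labelled trial tibble for one subject (needs `phase`,
#'   `core_exploit`).
#' @param beliefs Matching [run_observer()] series.
#' @param pupil Optional per-trial baseline tibble (`run`, `t`, `baseline`,
#'   optionally `excluded`).
#' @param extra Optional named list of extra per-trial series (e.g. `signal`,
#'   `global_mean` for GLM8).
#' @param per_run_bias Use one bias column per run (default FALSE).
#' @return A list of class `design_matrix`: `X` (numeric matrix), `subset`
#'   (logical row mask for the recipe's trial subset), `dependent` (name of
#'   the dependent series the recipe expects), `recipe`.
#' @export
build_design <- function(recipe, trials, beliefs, pupil = NULL, extra = NULL,
                         per_run_bias = FALSE) {
  if (!recipe %in% names(glm_recipes)) {
    stop("build_design: unknown recipe ", recipe, call. = FALSE)
  }
  recipe_def <- glm_recipes[[recipe]]
  ser <- derived_series(trials, beliefs, pupil)
  if (!is.null(extra)) for (nm in names(extra)) ser[[nm]] <- extra[[nm]]
  missing_cols <- setdiff(recipe_def$cols, names(ser))
  if (length(missing_cols)) {
    stop("build_design: recipe ", recipe, " needs series: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(recipe_def$cols)) stop("build_design: duplicated regressor", call. = FALSE)
  X <- as.matrix(ser[, recipe_def$cols, drop = FALSE])
  if (recipe_def$bias) {
    if (per_run_bias) {
      runs <- sort(unique(trials$run))
      B <- vapply(runs, function(r) as.numeric(trials$run == r), numeric(nrow(trials)))
      colnames(B) <- paste0("bias_run", runs)
      X <- cbind(B, X)
    } else {
      X <- cbind(bias = 1, X)
    }
  }
  cc <- stats::complete.cases(X)
  if (qr(X[cc, , drop = FALSE])$rank < ncol(X)) {
    # name the offending columns for the error message
    Xc <- X[cc, , drop = FALSE]
    qrX <- qr(Xc)
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("build_design: rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  subset <- switch(recipe_def$subset,
    all = rep(TRUE, nrow(trials)),
    core_exploit = trials$core_exploit,
    exploit = trials$phase == "exploit"
  )
  structure(list(X = X, subset = subset, dependent = recipe_def$dependent,
                 recipe = recipe),
            class = "design_matrix")
}
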