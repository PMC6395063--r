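#' Run the full synthetic study pipeline
#'
#' Generates a synthetic cohort ([generate_cohort_dataset()]), decodes the
#' state- and action-coding regions ([decode_patterns()]), preprocesses the
#' pupil traces ([preprocess_pupil()]), and runs the main analyses: the
#' entropy-on-representation-strength group regressions (GLM4) in both
#' regions, the belief regression (GLM5) in the state region, the
#' pupil-coupling regression with reward split (GLM6 analog), the
#' median-split contrast, and the entropy switch-prediction logistic
#' regression.
#'
#' @param n_subjects Number of subjects (default 19).
#' @param master_seed Master seed for everything (default 1).
#' @param k,decay Decoding parameters (see [decode_patterns()]).
#' @param n_lead_trials Pupil lead-in exclusion per run (default 25).
#' @param ... Passed to [generate_cohort_dataset()] (configs).
#' @return A list of class `study_result`: the dataset, the per-region
#'   representation-strength tibbles (`rs_state`, `rs_action`), pupil
#'   baselines, and the analysis objects (`glm4_state`, `glm4_action`,
#'   `glm5_state`, `coupling`, `median_split`, `switch_entropy`).
#' @export
run_study <- function(n_subjects = 19, master_seed = 1L, k = 20, decay = 1,
                      n_lead_trials = 25, ...) {
  ds <- generate_cohort_dataset(n_subjects = n_subjects,
                                master_seed = master_seed, ...)
  decoded <- decode_cohort(ds, k = k, decay = decay)
  pupil_base <- preprocess_pupil_cohort(ds, n_lead_trials = n_lead_trials)
  glm4_state <- run_group_glm("GLM4", ds$trials, ds$beliefs,
                              dependent = rs_as_dependent(decoded$rs_state),
                              coef = "entropy")
  glm4_action <- run_group_glm("GLM4", ds$trials, ds$beliefs,
                               dependent = rs_as_dependent(decoded$rs_action),
                               coef = "entropy")
  glm5_state <- run_group_glm("GLM5", ds$trials, ds$beliefs,
                              dependent = rs_as_dependent(decoded$rs_state),
                              coef = "p_chosen")
  coupling <- delta_coupling_regression(decoded$rs_state, pupil_base,
                                        ds$beliefs, ds$trials, lag = 0)
  tab <- coupling_delta_table(decoded$rs_state, pupil_base, ds$beliefs, ds$trials)
  tab <- tab[tab$core & !tab$rewarded, ]
  med <- median_split_contrast(tab)
  sw <- switch_logistic(ds$trials, ds$beliefs, predictor = "entropy")
  structure(
    list(data = ds, rs_state = decoded$rs_state, rs_action = decoded$rs_action,
         pupil_baselines = pupil_base,
         glm4_state = glm4_state, glm4_action = glm4_action,
         glm5_state = glm5_state, coupling = coupling, median_split = med,
         switch_entropy = sw, master_seed = master_seed),
    class = "study_result"
  )
}

#' Decode every subject's regions of a cohort dataset
#'
#' @param ds A `cohort_dataset`.
#' @param k,decay,aggregate,seed Passed to [decode_patterns()].
#' @return List with `rs_state` and `rs_action`: cohort tibbles
#'   `subject`, `run`, `t`, `rep_strength`, `p_chosen`, `accurate`.
#' @export
decode_cohort <- function(ds, k = 20, decay = 1, aggregate = "mean", seed = 42L) {
  one_region <- function(region) {
    purrr::map_dfr(names(ds$patterns), function(s) {
      tr <- ds$trials[ds$trials$subject == as.integer(s), ]
      rs <- decode_patterns(ds$patterns[[s]][[region]], k = k, decay = decay,
                            aggregate = aggregate, seed = seed)
      tibble::tibble(subject = as.integer(s), run = tr$run, t = tr$t,
                     rep_strength = rs$rep_strength, p_chosen = rs$p_chosen,
                     accurate = rs$accurate)
    })
  }
  list(rs_state = one_region("state"), rs_action = one_region("action"))
}

#' Preprocess every subject's pupil trace of a cohort dataset
#'
#' @param ds A `cohort_dataset`.
#' @param n_lead_trials Leading trials removed per run (default 25).
#' @return Cohort tibble `subject`, `run`, `t`, `baseline`, `lost`,
#'   `excluded`, `reason`.
#' @export
preprocess_pupil_cohort <- function(ds, n_lead_trials = 25) {
  purrr::map_dfr(names(ds$pupil), function(s) {
    lab <- ds$trials[ds$trials$subject == as.integer(s), ]
    out <- preprocess_pupil(ds$pupil[[s]], labels = lab,
                            n_lead_trials = n_lead_trials)
    dplyr::bind_cols(tibble::tibble(subject = as.integer(s)), out)
  })
}

rs_as_dependent <- function(rs) {
  tibble::tibble(subject = rs$subject, run = rs$run, t = rs$t,
                 value = rs$rep_strength)
}

#' Summary report of a study result
#'
#' @param x A `study_result`.
#' @return A tibble with one row per headline effect: `effect`, `estimate`,
#'   `statistic`, `df`, `p.value`.
#' @export
study_report <- function(x) {
  row <- function(effect, g) {
    tibble::tibble(effect = effect, estimate = g$mean, statistic = g$t,
                   df = g$df, p.value = g$p)
  }
  dplyr::bind_rows(
    row("entropy -> rep strength (state region)", x$glm4_state),
    row("entropy -> rep strength (action region)", x$glm4_action),
    row("belief p(H_chosen) -> rep strength (state region)", x$glm5_state),
    row("dpupil -> dRS, unrewarded core-exploit", x$coupling$unrewarded),
    row("dpupil -> dRS, rewarded core-exploit", x$coupling$rewarded),
    tibble::tibble(effect = "dpupil -> dRS, rewarded minus unrewarded",
                   estimate = x$coupling$difference$mean,
                   statistic = x$coupling$difference$t,
                   df = x$coupling$difference$df,
                   p.value = x$coupling$difference$p),
    row("median split: dRS, high minus low dpupil", x$median_split),
    row("entropy -> switch next (logistic slope)", x$switch_entropy)
  )
}

#' @export
#' @method print study_result
print.study_result <- function(x, ...) {
  cat(sprintf("Synthetic study: %d subjects, master seed %d\n",
              length(unique(x$data$trials$subject)), x$master_seed))
  print(study_report(x), n = Inf)
  invisible(x)
}
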