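#' Merge component scores with covariates into a model-ready long table
#'
#' @param scores score table from [pc_weighted_scores()].
#' @param covariates cohort table.
#' @return long data.frame: one row per subject x condition with the score
#'   as `dv`, the condition as `outcome`, and all covariates.
#' @export
scores_long <- function(scores, covariates) {
  out <- data.frame(subject_id = scores$subject, outcome = scores$condition,
                    dv = scores$value, stringsAsFactors = FALSE)
  merge(out, covariates, by = "subject_id")
}

#' Risky-choice proportions in long format
#'
#' @param behavior output of [risky_choice_proportion()].
#' @param covariates cohort table.
#' @return long data.frame with `prev_outcome` (gain/loss) and `dv`.
#' @export
behavior_long <- function(behavior, covariates) {
  long <- rbind(
    data.frame(subject_id = behavior$subject_id, prev_outcome = "gain",
               dv = behavior$risky_after_gain, stringsAsFactors = FALSE),
    data.frame(subject_id = behavior$subject_id, prev_outcome = "loss",
               dv = behavior$risky_after_loss, stringsAsFactors = FALSE))
  long <- long[!is.na(long$dv), ]
  merge(long, covariates, by = "subject_id")
}

#' Run the full analysis in memory
#'
#' Orchestrates the whole chain on synthetic data: simulate a cohort, task
#' behavior and per-trial amplitudes; render, preprocess and average each
#' subject's EEG (streamed subject-by-subject to bound memory); transform
#' ERPs to delta/theta time-frequency surfaces; fit a separate PCA per
#' band, select the delta-RewP and theta-FRN components and score them at
#' the configured sensors; compute risky-choice behavior; screen theta for
#' an age association; and fit the dimensional mixed models.
#'
#' @param config a [generator_config()].
#' @param seed master seed.
#' @param bands a [band_config()].
#' @param delta_sensor,theta_sensor scoring sensors (`"auto-max"` allowed).
#' @param between between-subject terms for the dimensional models.
#' @param robust robust mixed-model fitting.
#' @param min_epochs minimum kept epochs per condition.
#' @param fit_models fit the mixed models (disable for component-level
#'   studies).
#' @param which_bands bands to decompose (subset of `c("delta", "theta")`;
#'   replicate studies that only need one component skip the other band).
#' @return list: cohort, trials, behavior tables; tfpca models, score
#'   tables, selected components; age screen; model results.
#' @export
run_study <- function(config = generator_config(), seed = 1L,
                      bands = band_config(),
                      delta_sensor = "Cz", theta_sensor = "FCz",
                      between = c("reexperiencing", "avoidance", "dysphoria",
                                  "hyperarousal", "audit_c", "mtbi_severity"),
                      robust = TRUE, min_epochs = 10L, fit_models = TRUE,
                      which_bands = c("delta", "theta")) {
  cohort <- simulate_cohort(config$n_subjects, config, seed)
  trials <- simulate_behavior(cohort, config, seed)
  trials <- simulate_trial_amplitudes(cohort, trials, config, seed)

  erps <- vector("list", nrow(cohort))
  for (s in seq_len(nrow(cohort))) {
    ep <- simulate_subject_epochs(cohort[s, ],
                                  trials[trials$subject_id == cohort$subject_id[s], ],
                                  config, seed = child_seed(seed, "epochs", s))
    erps[[s]] <- preprocess_epochs(ep, min_epochs = min_epochs)
  }

  surfaces <- erp_band_surfaces(erps, bands, which_bands = which_bands)
  pca_delta <- pca_theta <- cd <- ct <- sc_delta <- sc_theta <- NULL
  if ("delta" %in% which_bands) {
    Xd <- build_data_matrix(surfaces$delta)
    pca_delta <- fit_tfpca(Xd)
    cd <- select_component(pca_delta, "delta-RewP")
    sc_delta <- pc_weighted_scores(pca_delta, Xd, cd, delta_sensor, "delta-RewP")
  }
  if ("theta" %in% which_bands) {
    Xt <- build_data_matrix(surfaces$theta)
    pca_theta <- fit_tfpca(Xt)
    ct <- select_component(pca_theta, "theta-FRN")
    sc_theta <- pc_weighted_scores(pca_theta, Xt, ct, theta_sensor, "theta-FRN")
  }

  behavior <- risky_choice_proportion(trials)
  age_screen <- if (is.null(sc_theta)) NULL else screen_age(sc_theta, cohort)

  models <- NULL
  if (fit_models && length(which_bands) == 2L) {
    dl <- scores_long(sc_delta, cohort)
    tl <- scores_long(sc_theta, cohort)
    bl <- behavior_long(behavior, cohort)
    extra <- if (age_screen$include_age) "age" else character()
    models <- list(
      delta = fit_mixed_model(dl, model_spec("dv", "outcome", between,
                                             robust = robust)),
      theta = fit_mixed_model(tl, model_spec("dv", "outcome", between,
                                             covariates_extra = extra,
                                             robust = robust)),
      behavior = fit_mixed_model(bl, model_spec("dv", "prev_outcome", between,
                                                robust = robust)))
  }

  list(cohort = cohort, trials = trials, behavior = behavior,
       erps = erps, surfaces = surfaces,
       pca = list(delta = pca_delta, theta = pca_theta),
       selected = list(delta = cd, theta = ct),
       scores = list(delta = sc_delta, theta = sc_theta),
       age_screen = age_screen, models = models,
       truth = amplitude_truth(cohort, config))
}
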