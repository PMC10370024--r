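# Replicate-level simulation studies: effect-sign recovery through the full
# EEG pipeline, type-I calibration and robustness of the mixed-model stage.

#' Scaled-down generator configuration for replicate studies
#'
#' The reference study conditions with the EEG rendering shrunk to
#' replicate scale: 96 trials, 6 EEG + 1 EOG channels, 128 Hz acquisition.
#' Effect coefficients and noise are unchanged.
#'
#' @param n_subjects cohort size per replicate.
#' @param ... overrides forwarded to [generator_config()].
#' @return a `generator_config`.
#' @export
replicate_config <- function(n_subjects = 80L, ...) {
  generator_config(n_subjects = n_subjects, n_trials = 96L,
                   sampling_rate = 128, n_eeg = 6L, n_eog = 1L, ...)
}

#' Effect-sign recovery study through the full pipeline
#'
#' Runs the complete chain (simulate, preprocess, transform, decompose,
#' score, robust mixed model with Outcome x covariate interactions and age
#' covariate handling) on independent replicate cohorts, and extracts the
#' post-hoc loss-condition simple slopes for reexperiencing and AUDIT-C on
#' the theta-FRN score.
#'
#' @param n_reps number of replicate cohorts.
#' @param seed master seed; replicate r uses `child_seed(seed, "rep", r)`.
#' @param config generator configuration per replicate
#'   (default [replicate_config()]).
#' @param bands band/TF configuration (default: analysis at 64 Hz with
#'   33 frequency bins, matching the reduced acquisition rate).
#' @return data.frame per replicate: loss-condition slope estimate and p
#'   for reexperiencing and AUDIT-C.
#' @export
effect_sign_study <- function(n_reps = 20L, seed = 1L,
                              config = replicate_config(),
                              bands = band_config(downsample_to = 64,
                                                  n_freq_bins = 33L)) {
  rows <- lapply(seq_len(n_reps), function(r) {
    st <- run_study(config, seed = child_seed(seed, "rep", r), bands = bands,
                    min_epochs = 5L, fit_models = FALSE,
                    which_bands = "theta")
    cohort <- st$cohort
    tl <- scores_long(st$scores$theta, cohort)
    extra <- if (st$age_screen$include_age) "age" else character()
    fit <- fit_mixed_model(
      tl, model_spec("dv", "outcome",
                     c("reexperiencing", "avoidance", "dysphoria",
                       "hyperarousal", "audit_c", "mtbi_severity"),
                     covariates_extra = extra, robust = TRUE))
    ss_re <- simple_slopes(fit, "reexperiencing")
    ss_au <- simple_slopes(fit, "audit_c")
    data.frame(rep = r,
               reexp_loss_slope = ss_re$slope[ss_re$level == "loss"],
               reexp_loss_p = ss_re$p[ss_re$level == "loss"],
               audit_loss_slope = ss_au$slope[ss_au$level == "loss"],
               audit_loss_p = ss_au$p[ss_au$level == "loss"])
  })
  do.call(rbind, rows)
}

#' Condition-mean amplitude DVs from the generative chain
#'
#' Cohort, trials and per-trial component amplitudes, averaged per subject
#' and feedback condition and merged with the covariates — the
#' statistics-level view of the generator's ground truth, without the EEG
#' rendering step. Used by the calibration and robustness studies.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param component `"A_theta"` or `"A_delta"`.
#' @return long data.frame: subject_id, outcome, `dv`, covariates.
#' @export
amplitude_condition_means <- function(config, seed, component = "A_theta") {
  cohort <- simulate_cohort(config$n_subjects, config, seed)
  trials <- simulate_behavior(cohort, config, seed)
  trials <- simulate_trial_amplitudes(cohort, trials, config, seed)
  agg <- aggregate(trials[[component]],
                   list(subject_id = trials$subject_id,
                        outcome = trials$outcome), mean)
  names(agg)[3] <- "dv"
  merge(agg, cohort, by = "subject_id")
}

#' Type-I error calibration of the covariate tests
#'
#' With every covariate coefficient of the generator set to zero, fits the
#' dimensional mixed model on replicate cohorts (condition-mean amplitude
#' DVs from the generative chain) and returns the rejection rate of the
#' covariate main-effect and interaction terms at the nominal 0.05 level.
#'
#' @param n_reps replicate count.
#' @param n_subjects subjects per replicate.
#' @param seed master seed.
#' @param robust robust fitting (the default analysis).
#' @return list: `rate` (pooled rejection proportion), `n_tests`, and the
#'   per-replicate p-value matrix.
#' @export
null_calibration_study <- function(n_reps = 200L, n_subjects = 40L, seed = 1L,
                                   robust = TRUE) {
  config <- generator_config(
    n_subjects = n_subjects,
    amplitudes = list(a_audit = 0, a_age = 0, c_reexp = 0, c_audit = 0,
                      c_age = 0))
  between <- c("reexperiencing", "audit_c", "mtbi_severity")
  pv <- lapply(seq_len(n_reps), function(r) {
    long <- amplitude_condition_means(config, child_seed(seed, "null", r))
    fit <- fit_mixed_model(long, model_spec("dv", "outcome", between,
                                            robust = robust))
    tab <- fit$coefficients
    keep <- grepl(paste(between, collapse = "|"), rownames(tab))
    tab$p[keep]
  })
  pm <- do.call(rbind, pv)
  list(rate = mean(pm < 0.05), n_tests = length(pm), p_values = pm)
}

#' Robust versus non-robust estimation under contamination
#'
#' On each replicate, fits the Outcome x reexperiencing model twice (Huber
#' IRLS and plain ML) on condition-mean amplitude DVs; in the contaminated
#' arm a fraction of observations is replaced by gross outliers. Bias is
#' measured on the within-factor (Outcome) coefficient against the planted
#' standardized effect, computed from the clean replicate data.
#'
#' @param n_reps replicate count.
#' @param n_subjects subjects per replicate.
#' @param contamination fraction of rows receiving gross outliers.
#' @param outlier_sd SD multiplier of the injected outliers.
#' @param seed master seed.
#' @return data.frame per replicate: robust / nonrobust Outcome estimates
#'   under contamination, the clean-data reference estimates of both
#'   fitters, and the planted standardized effect.
#' @export
robustness_study <- function(n_reps = 50L, n_subjects = 40L,
                             contamination = 0.1, outlier_sd = 8, seed = 1L) {
  config <- generator_config(n_subjects = n_subjects)
  between <- c("reexperiencing", "audit_c")
  spec_r <- model_spec("dv", "outcome", between, robust = TRUE, zscore = FALSE)
  spec_n <- model_spec("dv", "outcome", between, robust = FALSE, zscore = FALSE)
  rows <- lapply(seq_len(n_reps), function(r) {
    long <- amplitude_condition_means(config, child_seed(seed, "robust", r))
    planted <- config$amplitudes$c_loss
    clean_r <- fit_mixed_model(long, spec_r)
    clean_n <- fit_mixed_model(long, spec_n)
    set.seed(child_seed(seed, "contam", r))
    bad <- sample(nrow(long), round(contamination * nrow(long)))
    long$dv[bad] <- long$dv[bad] +
      sample(c(-1, 1), length(bad), TRUE) * outlier_sd * sd(long$dv)
    cont_r <- fit_mixed_model(long, spec_r)
    cont_n <- fit_mixed_model(long, spec_n)
    est <- function(f) f$coefficients[".withinloss", "estimate"]
    data.frame(rep = r, planted = planted,
               clean_robust = est(clean_r), clean_ml = est(clean_n),
               contaminated_robust = est(cont_r),
               contaminated_ml = est(cont_n))
  })
  do.call(rbind, rows)
}
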