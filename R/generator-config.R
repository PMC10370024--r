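#' Configuration for the synthetic study generator
#'
#' Bundles every tunable of the synthetic cohort: task size, EEG geometry,
#' component templates, effect coefficients, and noise model. The defaults
#' define the package's reference study conditions: a 256-trial two-option
#' gambling task (5/25-cent pairs, equiprobable, fair gain/loss feedback, 8
#' blocks), feedback-locked epochs from -1000 to 2000 ms, a centro-parietal
#' delta deflection larger for gains, a mediofrontal 6-Hz theta burst larger
#' for losses, 1/f background noise, and blink artifacts entering the EEG
#' through fixed propagation coefficients.
#'
#' @param n_subjects cohort size.
#' @param n_trials gambling trials per subject (divided into `n_blocks`).
#' @param n_blocks task blocks.
#' @param sampling_rate EEG sampling rate in Hz.
#' @param n_eeg,n_eog EEG / EOG channel counts (see [default_montage()]).
#' @param epoch_window_ms two-element ms window around feedback onset.
#' @param covariates list: gamma marginals for the four symptom subscales
#'   (`symptom_shape`, `symptom_scale`), their pairwise latent correlation
#'   `symptom_corr` (calibrated so the *Pearson* correlation of the generated
#'   scores matches it), AUDIT-C binomial probability `audit_prob` on 0-12,
#'   mTBI gamma parameters, age range in years, male proportion, and
#'   diagnosis thresholds.
#' @param behavior list: logistic choice model on mixed 5/25 offers,
#'   `P(choose 25) = plogis(b0 + b_prevloss*I(prev loss) + b_audit*audit_z)`.
#' @param amplitudes list of linear models for per-trial component
#'   amplitudes (arbitrary units, ~1):
#'   `A_delta = a0 + a_gain*I(gain) + a_audit*audit_z + a_age*age_z + u_d + e`,
#'   `A_theta = c0 + c_loss*I(loss) + (c_reexp*reexp_z + c_audit*audit_z)*I(loss)
#'              + c_age*age_z + u_t + e`,
#'   with subject traits `u` (sd `subject_sd`) and trial noise `e` (sd
#'   `trial_sd`). Default signs mirror the effects the analysis is built to
#'   detect: gains boost delta, losses boost theta, reexperiencing amplifies
#'   loss-theta, alcohol use dampens both, age mildly lowers theta.
#' @param templates list: delta Gaussian deflection (peak µV, center ms,
#'   width ms) maximal at Cz; theta Gaussian-windowed burst (peak µV, Hz,
#'   center ms, width ms) maximal at FCz; topography width `topo_sigma` in
#'   head-radius units.
#' @param noise list: `exponent` of the 1/f spectrum, `amplitude` (µV RMS
#'   per channel), blink `rate` (events/s), blink amplitude mean/sd (µV) and
#'   duration (ms).
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 40L,
                             n_trials = 256L,
                             n_blocks = 8L,
                             sampling_rate = 256,
                             n_eeg = 16L,
                             n_eog = 2L,
                             epoch_window_ms = c(-1000, 2000),
                             covariates = list(),
                             behavior = list(),
                             amplitudes = list(),
                             templates = list(),
                             noise = list()) {
  covariates <- modifyList(list(
    symptom_corr = 0.5, symptom_shape = 2, symptom_scale = 6,
    audit_prob = 0.35, mtbi_shape = 1.5, mtbi_scale = 2,
    age_range = c(22, 59), prop_male = 0.85,
    ptsd_total_cutoff = 60, ad_audit_cutoff = 7, mtbi_cutoff = 4
  ), covariates)
  behavior <- modifyList(list(b0 = 0, b_prevloss = 0.5, b_audit = 0.15),
                         behavior)
  amplitudes <- modifyList(list(
    a0 = 1, a_gain = 0.5, a_audit = -0.15, a_age = 0,
    c0 = 1, c_loss = 0.8, c_reexp = 0.3, c_audit = -0.15, c_age = -0.1,
    subject_sd = 0.3, trial_sd = 0.5
  ), amplitudes)
  templates <- modifyList(list(
    delta_peak_uv = 8, delta_center_ms = 350, delta_sd_ms = 80,
    delta_channel = "Cz",
    theta_peak_uv = 6, theta_freq_hz = 6, theta_center_ms = 325,
    theta_sd_ms = 55, theta_channel = "FCz",
    topo_sigma = 0.45
  ), templates)
  noise <- modifyList(list(
    exponent = 1, amplitude = 8,
    blink_rate = 0.25, blink_amp_uv = 120, blink_amp_sd = 20,
    blink_dur_ms = 400
  ), noise)

  cfg <- list(n_subjects = as.integer(n_subjects),
              n_trials = as.integer(n_trials),
              n_blocks = as.integer(n_blocks),
              sampling_rate = sampling_rate,
              n_eeg = as.integer(n_eeg), n_eog = as.integer(n_eog),
              epoch_window_ms = epoch_window_ms,
              covariates = covariates, behavior = behavior,
              amplitudes = amplitudes, templates = templates, noise = noise)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1L, cfg$n_trials >= 1L, cfg$n_blocks >= 1L,
            cfg$sampling_rate > 0, length(cfg$epoch_window_ms) == 2L,
            diff(cfg$epoch_window_ms) > 0)
  cv <- cfg$covariates
  if (cv$symptom_corr < 0 || cv$symptom_corr >= 1)
    stop("symptom_corr must be in [0, 1): correlation matrix would not be positive-definite")
  if (cv$audit_prob < 0 || cv$audit_prob > 1) stop("audit_prob must be in [0, 1]")
  for (f in c("amplitude", "blink_rate", "blink_amp_uv", "blink_dur_ms"))
    if (cfg$noise[[f]] < 0) stop("noise field must be nonnegative: ", f)
  tp <- cfg$templates
  if (tp$delta_peak_uv < 0 || tp$theta_peak_uv < 0)
    stop("template peak amplitudes must be nonnegative")
  w <- cfg$epoch_window_ms
  for (ctr in c(tp$delta_center_ms, tp$theta_center_ms))
    if (ctr < w[1] || ctr > w[2])
      stop("template window outside epoch span [", w[1], ", ", w[2], "] ms")
  invisible(cfg)
}

#' Component templates and scalp weights implied by a generator config
#'
#' Exposes the analytic building blocks of the forward model so that tests
#' and users can reconstruct a noise-free epoch exactly: unit-peak delta and
#' theta time courses on the epoch time axis, their Gaussian scalp weights,
#' and the blink propagation vector.
#'
#' @param config a [generator_config()].
#' @return list with `time_ms`, `delta`, `theta` (waveforms in µV at their
#'   peak channel), `w_delta`, `w_theta`, `blink_prop`, and the `montage`.
#' @export
component_templates <- function(config) {
  fs <- config$sampling_rate
  w <- config$epoch_window_ms
  n <- round(diff(w) / 1000 * fs)
  time_ms <- w[1] + (seq_len(n) - 1) / fs * 1000
  tp <- config$templates
  delta <- tp$delta_peak_uv *
    exp(-(time_ms - tp$delta_center_ms)^2 / (2 * tp$delta_sd_ms^2))
  theta <- tp$theta_peak_uv *
    cos(2 * pi * tp$theta_freq_hz * (time_ms - tp$theta_center_ms) / 1000) *
    exp(-(time_ms - tp$theta_center_ms)^2 / (2 * tp$theta_sd_ms^2))
  montage <- default_montage(config$n_eeg, config$n_eog)
  list(time_ms = time_ms,
       delta = delta, theta = theta,
       w_delta = topography_weights(montage, tp$delta_channel, tp$topo_sigma),
       w_theta = topography_weights(montage, tp$theta_channel, tp$topo_sigma),
       blink_prop = blink_propagation(montage),
       montage = montage)
}
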