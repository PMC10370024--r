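#' Simulate a veteran-like cohort of subject covariates
#'
#' Draws `n` subjects from a Gaussian copula and maps the latent normals to
#' the configured marginals: four gamma-distributed PTSD symptom subscale
#' severities (reexperiencing, avoidance, dysphoria, hyperarousal) with a
#' common pairwise correlation, an integer AUDIT-C score on 0-12 (binomial
#' quantile map), a gamma mTBI severity, uniform age over the configured
#' range, and sex. The latent symptom correlation is calibrated by
#' Gauss-Hermite quadrature so the *Pearson* correlation of the generated
#' scores matches `symptom_corr` at large n. Diagnosis flags are thresholds
#' on the continuous scores. Two latent neural traits (`re_delta`,
#' `re_theta`, the subject random effects of the amplitude model) are drawn
#' here so that downstream stages share a single ground truth.
#'
#' @param n number of subjects (>= 1).
#' @param config a [generator_config()].
#' @param seed integer seed; fully determines the output.
#' @return data.frame, one row per subject.
#' @export
simulate_cohort <- function(n, config = generator_config(), seed = 1L) {
  stopifnot(n >= 1)
  validate_generator_config(config)
  cv <- config$covariates
  set.seed(child_seed(seed, "cohort"))

  qsym <- function(u) qgamma(u, shape = cv$symptom_shape, scale = cv$symptom_scale)
  rho <- latent_symptom_corr(cv$symptom_corr, qsym)
  R <- diag(4); R[upper.tri(R)] <- rho; R[lower.tri(R)] <- rho
  z <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = R)
  if (n == 1L) z <- matrix(z, nrow = 1)
  sym <- apply(z, 2, function(col) qsym(pnorm(col)))
  if (n == 1L) sym <- matrix(sym, nrow = 1)

  audit <- qbinom(pnorm(rnorm(n)), size = 12L, prob = cv$audit_prob)
  mtbi <- qgamma(pnorm(rnorm(n)), shape = cv$mtbi_shape, scale = cv$mtbi_scale)
  age <- runif(n, cv$age_range[1], cv$age_range[2])
  sex <- ifelse(runif(n) < cv$prop_male, "male", "female")

  total <- rowSums(sym)
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    reexperiencing = sym[, 1], avoidance = sym[, 2],
    dysphoria = sym[, 3], hyperarousal = sym[, 4],
    audit_c = as.integer(audit), mtbi_severity = mtbi,
    age = age, sex = sex,
    diag_ptsd = total >= cv$ptsd_total_cutoff,
    diag_ad = audit >= cv$ad_audit_cutoff,
    diag_mtbi = mtbi >= cv$mtbi_cutoff,
    re_delta = rnorm(n, 0, config$amplitudes$subject_sd),
    re_theta = rnorm(n, 0, config$amplitudes$subject_sd),
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$audit_c >= 0L), all(out$audit_c <= 12L))
  out
}

# Gauss-Hermite nodes/weights (Golub-Welsch on the Jacobi matrix),
# physicists' convention: integral f(x) exp(-x^2) dx = sum w f(x).
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Latent bivariate-normal correlation whose copula, pushed through the
# marginal quantile map qfun, yields the target Pearson correlation.
latent_symptom_corr <- function(target, qfun, n_nodes = 40) {
  if (target == 0) return(0)
  gh <- gauss_hermite(n_nodes)
  g <- function(z) qfun(pmin(pmax(pnorm(z), 1e-15), 1 - 1e-15))
  zs <- sqrt(2) * gh$x
  wn <- gh$w / sqrt(pi)
  m1 <- sum(wn * g(zs))
  v1 <- sum(wn * g(zs)^2) - m1^2
  pearson_of <- function(rho) {
    # E[g(Z1) g(rho Z1 + sqrt(1-rho^2) W)] on the 2-D tensor grid
    gz2 <- outer(zs, zs, function(z1, w) g(rho * z1 + sqrt(1 - rho^2) * w))
    e12 <- sum((wn %o% wn) * (g(zs) * gz2))
    (e12 - m1^2) / v1
  }
  stats::uniroot(function(r) pearson_of(r) - target,
                 interval = c(1e-6, 0.9999), tol = 1e-6)$root
}

#' Simulate gambling-task behavior
#'
#' Generates the trial table of the 256-trial two-option task: offered
#' pairs drawn uniformly from \{5/5, 5/25, 25/25\} cents, gain/loss feedback
#' by fair coin independent of choice, and choices on mixed offers following
#' `P(choose 25) = plogis(b0 + b_prevloss*I(previous loss) + b_audit*audit_z)`.
#' `prev_outcome` is `none` on the first trial of the session (by default it
#' does not reset at block breaks; set `reset_at_block` to change that).
#'
#' @param covariates cohort table from [simulate_cohort()].
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param reset_at_block logical; reset the previous-outcome marker at block
#'   boundaries.
#' @return data.frame of trial records.
#' @export
simulate_behavior <- function(covariates, config = generator_config(),
                              seed = 1L, reset_at_block = FALSE) {
  stopifnot(nrow(covariates) >= 1)
  validate_generator_config(config)
  set.seed(child_seed(seed, "behavior"))
  bh <- config$behavior
  nt <- config$n_trials
  ns <- nrow(covariates)
  per_block <- ceiling(nt / config$n_blocks)
  audit_z <- as.numeric(scale(covariates$audit_c))
  if (ns == 1L) audit_z <- 0

  pairs <- matrix(c(5, 5, 5, 25, 25, 25), ncol = 2, byrow = TRUE)
  rows <- vector("list", ns)
  for (s in seq_len(ns)) {
    pair_idx <- sample.int(3, nt, replace = TRUE)
    offer <- pairs[pair_idx, , drop = FALSE]
    flip <- runif(nt) < 0.5          # which side shows the first listed value
    offer_left <- ifelse(flip, offer[, 1], offer[, 2])
    offer_right <- ifelse(flip, offer[, 2], offer[, 1])
    outcome <- ifelse(runif(nt) < 0.5, "gain", "loss")
    block <- rep(seq_len(config$n_blocks), each = per_block)[seq_len(nt)]
    prev <- c("none", outcome[-nt])
    if (reset_at_block) prev[c(TRUE, diff(block) != 0)[seq_len(nt)]] <- "none"

    p25 <- plogis(bh$b0 + bh$b_prevloss * (prev == "loss") +
                    bh$b_audit * audit_z[s])
    mixed <- offer_left != offer_right
    choose25 <- runif(nt) < p25
    chosen_value <- ifelse(mixed, ifelse(choose25, 25, 5), offer_left)
    chosen_side <- ifelse(mixed,
                          ifelse((offer_left == 25) == choose25, "left", "right"),
                          ifelse(runif(nt) < 0.5, "left", "right"))
    rows[[s]] <- data.frame(
      subject_id = covariates$subject_id[s],
      block = block, trial = seq_len(nt),
      offer_left = offer_left, offer_right = offer_right,
      chosen_side = chosen_side, chosen_value = chosen_value,
      outcome = outcome,
      delta_score = ifelse(outcome == "gain", chosen_value, -chosen_value),
      prev_outcome = prev,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Per-trial component amplitudes (generator ground truth)
#'
#' Draws the latent single-trial amplitudes of the delta and theta
#' components for every trial, following the linear models documented in
#' [generator_config()]. These are the quantities the EEG rendering step
#' multiplies into the component templates, and they double as ground truth
#' for recovery tests and for statistics-level simulation studies that do
#' not need the EEG rendering itself.
#'
#' @param covariates cohort table (provides `audit_z`, `reexp_z`, `age_z`
#'   via within-cohort z-scoring, and the latent traits `re_delta`,
#'   `re_theta`).
#' @param trials trial table from [simulate_behavior()].
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return the trial table with columns `A_delta`, `A_theta` appended.
#' @export
simulate_trial_amplitudes <- function(covariates, trials,
                                      config = generator_config(), seed = 1L) {
  validate_generator_config(config)
  set.seed(child_seed(seed, "amplitudes"))
  am <- config$amplitudes
  zcol <- function(x) if (length(x) > 1 && sd(x) > 0) as.numeric(scale(x)) else rep(0, length(x))
  cz <- data.frame(subject_id = covariates$subject_id,
                   audit_z = zcol(covariates$audit_c),
                   reexp_z = zcol(covariates$reexperiencing),
                   age_z = zcol(covariates$age),
                   re_delta = covariates$re_delta,
                   re_theta = covariates$re_theta)
  i <- match(trials$subject_id, cz$subject_id)
  gain <- trials$outcome == "gain"
  loss <- !gain
  n <- nrow(trials)
  trials$A_delta <- am$a0 + am$a_gain * gain + am$a_audit * cz$audit_z[i] +
    am$a_age * cz$age_z[i] + cz$re_delta[i] + rnorm(n, 0, am$trial_sd)
  trials$A_theta <- am$c0 + am$c_loss * loss +
    (am$c_reexp * cz$reexp_z[i] + am$c_audit * cz$audit_z[i]) * loss +
    am$c_age * cz$age_z[i] + cz$re_theta[i] + rnorm(n, 0, am$trial_sd)
  trials
}

#' Expected (noise-free) per-subject condition amplitudes
#'
#' The conditional expectation of the amplitude model given covariates and
#' latent traits, per subject and feedback condition — the planted values
#' that recovered component scores are validated against.
#'
#' @inheritParams simulate_trial_amplitudes
#' @return data.frame: subject_id, condition, A_delta, A_theta.
#' @export
amplitude_truth <- function(covariates, config = generator_config()) {
  am <- config$amplitudes
  zcol <- function(x) if (length(x) > 1 && sd(x) > 0) as.numeric(scale(x)) else rep(0, length(x))
  audit_z <- zcol(covariates$audit_c)
  reexp_z <- zcol(covariates$reexperiencing)
  age_z <- zcol(covariates$age)
  base_d <- am$a0 + am$a_audit * audit_z + am$a_age * age_z + covariates$re_delta
  base_t <- am$c0 + am$c_age * age_z + covariates$re_theta
  rbind(
    data.frame(subject_id = covariates$subject_id, condition = "gain",
               A_delta = base_d + am$a_gain, A_theta = base_t,
               stringsAsFactors = FALSE),
    data.frame(subject_id = covariates$subject_id, condition = "loss",
               A_delta = base_d,
               A_theta = base_t + am$c_loss + am$c_reexp * reexp_z +
                 am$c_audit * audit_z,
               stringsAsFactors = FALSE)
  )
}

# 1/f noise: white Gaussian spectra shaped by |f|^(-alpha/2), gains
# normalized so the output RMS equals `amplitude` in expectation.
oneoverf_noise <- function(n_samples, n_series, fs, exponent, amplitude) {
  if (amplitude == 0) return(matrix(0, n_samples, n_series))
  f <- seq(0, fs, length.out = n_samples + 1)[seq_len(n_samples)]
  f <- pmin(f, fs - f)                      # alias frequency for upper half
  g <- pmax(f, 0.5)^(-exponent / 2)
  g[1] <- 0                                 # no DC drift
  g <- g / sqrt(mean(g^2))
  w <- matrix(rnorm(n_samples * n_series), n_samples, n_series)
  x <- Re(stats::mvfft(stats::mvfft(w) * g, inverse = TRUE)) / n_samples
  # filtered white noise has RMS sqrt(mean(g^2)); rescale to `amplitude`
  x * (amplitude / sqrt(mean(g^2)))
}

#' Simulate feedback-locked EEG epochs for one subject
#'
#' Renders the forward model for one subject: for each trial, the delta and
#' theta templates are scaled by that trial's latent amplitude, spread over
#' the scalp by their Gaussian topographies, and summed with 1/f noise on
#' every channel and blink artifacts that appear on the EOG channels and
#' leak into the EEG through fixed propagation coefficients.
#'
#' @param cov_row single-row cohort data.frame for the subject.
#' @param sub_trials this subject's rows of the amplitude-annotated trial
#'   table ([simulate_trial_amplitudes()]).
#' @param config a [generator_config()].
#' @param seed integer seed (per subject; the multi-subject wrapper derives
#'   child seeds).
#' @return an [epoch_set()].
#' @export
simulate_subject_epochs <- function(cov_row, sub_trials,
                                    config = generator_config(), seed = 1L) {
  stopifnot(nrow(cov_row) == 1L, nrow(sub_trials) >= 1L,
            all(c("A_delta", "A_theta") %in% names(sub_trials)))
  validate_generator_config(config)
  set.seed(seed)
  tpl <- component_templates(config)
  fs <- config$sampling_rate
  n_samp <- length(tpl$time_ms)
  n_ch <- nrow(tpl$montage)
  n_ep <- nrow(sub_trials)

  data <- sub_trials$A_delta %o% tpl$w_delta %o% tpl$delta +
    sub_trials$A_theta %o% tpl$w_theta %o% tpl$theta

  nz <- config$noise
  if (nz$amplitude > 0) {
    noise <- oneoverf_noise(n_samp, n_ep * n_ch, fs, nz$exponent, nz$amplitude)
    data <- data + aperm(array(noise, dim = c(n_samp, n_ep, n_ch)), c(2, 3, 1))
  }
  if (nz$blink_rate > 0) {
    dur_s <- nz$blink_dur_ms / 1000
    n_blink_samp <- round(dur_s * fs)
    shape <- (1 - cos(2 * pi * seq_len(n_blink_samp) / n_blink_samp)) / 2
    n_events <- rpois(n_ep, nz$blink_rate * n_samp / fs)
    for (e in which(n_events > 0)) {
      for (b in seq_len(n_events[e])) {
        onset <- sample.int(n_samp - n_blink_samp, 1)
        amp <- rnorm(1, nz$blink_amp_uv, nz$blink_amp_sd)
        idx <- onset + seq_len(n_blink_samp) - 1
        data[e, , idx] <- data[e, , idx] +
          (amp * tpl$blink_prop) %o% shape
      }
    }
  }
  epoch_set(data = data, time_ms = tpl$time_ms, sampling_rate = fs,
            montage = tpl$montage,
            condition = sub_trials$outcome,
            subject_id = cov_row$subject_id)
}

#' Simulate epochs for a whole cohort
#'
#' Convenience wrapper over [simulate_subject_epochs()]; derives one child
#' seed per subject so any subject's epochs can be regenerated in isolation.
#' For large cohorts prefer streaming subject-by-subject (as
#' [run_study()] does) — a full 40-subject set of raw epochs occupies ~1 GB.
#'
#' @inheritParams simulate_trial_amplitudes
#' @return named list of [epoch_set()] objects, one per subject.
#' @export
simulate_epochs <- function(covariates, trials, config = generator_config(),
                            seed = 1L) {
  if (!all(c("A_delta", "A_theta") %in% names(trials)))
    trials <- simulate_trial_amplitudes(covariates, trials, config, seed)
  out <- lapply(seq_len(nrow(covariates)), function(s) {
    simulate_subject_epochs(covariates[s, ],
                            trials[trials$subject_id == covariates$subject_id[s], ],
                            config, seed = child_seed(seed, "epochs", s))
  })
  names(out) <- covariates$subject_id
  out
}
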