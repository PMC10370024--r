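# Small in-code fixtures shared across test files.

# epoch_set with fully controlled content
make_epochs <- function(data, fs = 256, t0 = -1000, montage = NULL,
                        condition = NULL) {
  d <- dim(data)
  if (is.null(montage)) montage <- default_montage(min(d[2], 16L),
                                                   max(0L, d[2] - 16L))
  if (is.null(condition))
    condition <- rep(c("gain", "loss"), length.out = d[1])
  epoch_set(data, time_ms = t0 + (seq_len(d[3]) - 1) / fs * 1000,
            sampling_rate = fs, montage = montage[seq_len(d[2]), ],
            condition = condition)
}

# quiet generator: no noise, no blinks, no trial/subject variability
quiet_config <- function(...) {
  generator_config(noise = list(amplitude = 0, blink_rate = 0),
                   amplitudes = list(subject_sd = 0, trial_sd = 0), ...)
}

# planted single-template data matrix with TF axes
planted_matrix <- function(template_tf, amplitudes, noise_sd = 1e-5,
                           seed = 1) {
  set.seed(seed)
  v <- as.vector(template_tf)
  X <- outer(amplitudes, v) +
    matrix(rnorm(length(amplitudes) * length(v), 0, noise_sd),
           length(amplitudes))
  attr(X, "time_ms") <- as.numeric(seq_len(nrow(template_tf)))
  attr(X, "freq_hz") <- as.numeric(seq_len(ncol(template_tf)))
  X
}

# a small Gaussian TF blob centred at (t0, f0)
tf_blob <- function(n_time, n_freq, t0, f0, st = 4, sf = 2) {
  outer(exp(-(seq_len(n_time) - t0)^2 / (2 * st^2)),
        exp(-(seq_len(n_freq) - f0)^2 / (2 * sf^2)))
}

# mixed-offer trial fixture with known hand-counted proportions:
# after gain the chosen values on mixed offers are 25,5,25,5 (0.50),
# after loss they are 25,25,25 (1.00)
hand_fixture_trials <- function() {
  data.frame(
    subject_id = "S001",
    block = 1L, trial = 1:10,
    offer_left = c(5, 5, 5, 5, 5, 5, 5, 5, 5, 25),
    offer_right = c(25, 25, 25, 25, 25, 25, 25, 25, 5, 25),
    chosen_side = "right",
    chosen_value = c(25, 25, 5, 25, 5, 25, 25, 25, 5, 25),
    outcome = c("gain", "gain", "gain", "gain", "loss",
                "loss", "loss", "loss", "gain", "gain"),
    delta_score = 0,
    prev_outcome = c("none", "gain", "gain", "gain", "gain",
                     "loss", "loss", "loss", "loss", "gain"),
    stringsAsFactors = FALSE)
}
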