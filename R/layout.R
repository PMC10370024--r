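#' Default electrode montage
#'
#' A flattened 2-D layout (head radius ~1, +y anterior, +x right) for a
#' 16-channel 10-20 subset plus two periocular EOG channels. Scalp
#' topographies in the generator are Gaussians over these coordinates, and
#' the two most frontal EEG channels are the default artifact monitors.
#'
#' @param n_eeg number of EEG channels (must be <= 16; the first `n_eeg`
#'   rows of the standard set are used, ordered so midline channels come
#'   first).
#' @param n_eog number of EOG channels (0, 1 or 2).
#' @return data.frame with columns `name`, `x`, `y`, `type` ("eeg"/"eog").
#' @export
default_montage <- function(n_eeg = 16L, n_eog = 2L) {
  eeg <- data.frame(
    name = c("FCz", "Cz", "Fz", "CPz", "Pz",
             "FC3", "FC4", "C3", "C4", "CP3", "CP4",
             "F3", "F4", "P3", "P4", "Oz"),
    x = c(0, 0, 0, 0, 0,
          -0.40, 0.40, -0.45, 0.45, -0.40, 0.40,
          -0.35, 0.35, -0.35, 0.35, 0),
    y = c(0.25, 0, 0.50, -0.25, -0.50,
          0.25, 0.25, 0, 0, -0.25, -0.25,
          0.50, 0.50, -0.50, -0.50, -1.00),
    type = "eeg",
    stringsAsFactors = FALSE
  )
  eog <- data.frame(
    name = c("VEOG", "HEOG"),
    x = c(-0.10, 0.12),
    y = c(1.10, 1.10),
    type = "eog",
    stringsAsFactors = FALSE
  )
  stopifnot(n_eeg >= 1L, n_eeg <= nrow(eeg), n_eog >= 0L, n_eog <= 2L)
  out <- rbind(eeg[seq_len(n_eeg), ], eog[seq_len(n_eog), , drop = FALSE])
  rownames(out) <- NULL
  out
}

# Gaussian scalp weight centred at a named channel; EOG channels get 0.
topography_weights <- function(montage, center, sigma) {
  i <- match(center, montage$name)
  if (is.na(i)) stop("unknown topography center channel: ", center)
  d2 <- (montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2
  w <- exp(-d2 / (2 * sigma^2))
  w[montage$type != "eeg"] <- 0
  w
}

# Blink propagation coefficients: exponential fall-off with distance to the
# eyes (0, 1.1). EOG channels carry the blink at unit (VEOG) / reduced
# (HEOG) gain; these are fixed, known ground truth for the ocular
# regression tests.
blink_propagation <- function(montage, gain = 0.35, scale = 0.8) {
  d <- sqrt(montage$x^2 + (montage$y - 1.1)^2)
  p <- gain * exp(-d / scale)
  p[montage$type == "eog"] <- c(1, 0.6)[seq_len(sum(montage$type == "eog"))]
  p
}
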