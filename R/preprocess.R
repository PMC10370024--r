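#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' (default -150..0 ms, closed interval at both endpoints).
#'
#' @param epochs an [epoch_set()].
#' @param window two-element ms interval contained in the epoch span.
#' @return the corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, window = c(-150, 0)) {
  t <- epochs$time_ms
  if (window[1] < min(t) || window[2] > max(t))
    stop(sprintf("baseline window [%g, %g] ms outside epoch span [%g, %g] ms",
                 window[1], window[2], min(t), max(t)))
  idx <- which(t >= window[1] & t <= window[2])
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)   # recycles over samples
  append_log(epochs, sprintf("baseline_correct [%g, %g] ms", window[1], window[2]))
}

#' Remove ocular artifacts by regression
#'
#' For each EEG channel, estimates one propagation coefficient per EOG
#' channel by least squares over all concatenated epochs of the subject
#' (no intercept; signals are baseline-corrected), and subtracts the fitted
#' EOG contribution. EOG channels themselves are returned unmodified.
#'
#' @param epochs an [epoch_set()].
#' @param eog_channels channel names used as regressors (default: all
#'   channels of montage type `"eog"`).
#' @return the cleaned [epoch_set()]; the estimated coefficient matrix
#'   (EEG channel x EOG channel) is attached as attribute
#'   `"ocular_coefficients"`.
#' @export
regress_ocular <- function(epochs, eog_channels = NULL) {
  mont <- epochs$montage
  if (is.null(eog_channels)) eog_channels <- mont$name[mont$type == "eog"]
  if (length(eog_channels) < 1L) stop("at least one EOG channel required")
  ie <- match(eog_channels, mont$name)
  if (anyNA(ie)) stop("unknown EOG channel(s): ",
                      paste(eog_channels[is.na(ie)], collapse = ", "))
  ieeg <- setdiff(seq_len(nrow(mont)), ie)
  d <- dim(epochs$data)
  # concatenate epochs: channels x (epochs*samples)
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = d[2])
  E <- t(flat[ie, , drop = FALSE])
  if (any(apply(E, 2, var) < 1e-20))
    stop("EOG channel has zero variance; cannot regress")
  Y <- t(flat[ieeg, , drop = FALSE])
  B <- qr.solve(E, Y)                        # n_eog x n_eeg
  flat[ieeg, ] <- t(Y - E %*% B)
  epochs$data <- aperm(array(flat, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  coefs <- t(B)
  dimnames(coefs) <- list(mont$name[ieeg], eog_channels)
  epochs <- append_log(epochs, sprintf("regress_ocular on %s",
                                       paste(eog_channels, collapse = "+")))
  attr(epochs, "ocular_coefficients") <- coefs
  epochs
}

#' Reject epochs exceeding an amplitude threshold
#'
#' Drops every epoch whose absolute amplitude exceeds `threshold_uv` on any
#' monitored channel within the prestimulus window `[-pre_window_ms, 0]` or
#' the poststimulus window `[0, post_window_ms]`. Samples outside those
#' windows never trigger rejection. An optional list of epoch indices can
#' be dropped unconditionally (stand-in for a visual-inspection pass).
#'
#' @param epochs an [epoch_set()].
#' @param channels monitored channel names (default: the two most frontal
#'   EEG channels, i.e. largest montage `y`).
#' @param threshold_uv rejection threshold (µV).
#' @param post_window_ms,pre_window_ms window bounds (ms).
#' @param drop_epochs integer indices to drop unconditionally.
#' @return the [epoch_set()] with `kept` updated; the rejection report
#'   (data.frame epoch/channel/sample/time_ms/value) is attached as
#'   attribute `"rejection_report"`.
#' @export
reject_artifacts <- function(epochs, channels = NULL, threshold_uv = 100,
                             post_window_ms = 1500, pre_window_ms = 800,
                             drop_epochs = integer()) {
  mont <- epochs$montage
  if (is.null(channels)) {
    eeg <- mont[mont$type == "eeg", ]
    channels <- eeg$name[order(-eeg$y)][1:2]
  }
  ic <- match(channels, mont$name)
  if (anyNA(ic)) stop("unknown channel(s): ",
                      paste(channels[is.na(ic)], collapse = ", "))
  t <- epochs$time_ms
  win <- (t >= -pre_window_ms & t <= 0) | (t >= 0 & t <= post_window_ms)
  d <- dim(epochs$data)
  report <- list()
  for (e in seq_len(d[1])) {
    if (e %in% drop_epochs) {
      report[[length(report) + 1]] <- data.frame(
        epoch = e, channel = NA_character_, sample = NA_integer_,
        time_ms = NA_real_, value = NA_real_, reason = "manual")
      next
    }
    seg <- abs(epochs$data[e, ic, win, drop = FALSE])
    if (any(seg > threshold_uv)) {
      hit <- which(seg == max(seg), arr.ind = TRUE)[1, ]
      s <- which(win)[hit[3]]
      report[[length(report) + 1]] <- data.frame(
        epoch = e, channel = channels[hit[2]], sample = s,
        time_ms = t[s], value = epochs$data[e, ic[hit[2]], s],
        reason = "threshold")
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(epoch = integer(), channel = character(), sample = integer(),
               time_ms = numeric(), value = numeric(), reason = character())
  epochs$kept <- epochs$kept & !(seq_len(d[1]) %in% report$epoch)
  for (cond in unique(epochs$condition))
    if (!any(epochs$kept & epochs$condition == cond))
      stop("insufficient data: all '", cond, "' epochs rejected")
  epochs <- append_log(epochs, sprintf(
    "reject_artifacts >%g uV on %s in [-%g, %g] ms: dropped %d/%d",
    threshold_uv, paste(channels, collapse = "+"),
    pre_window_ms, post_window_ms, nrow(report), d[1]))
  attr(epochs, "rejection_report") <- report
  epochs
}

#' Condition-averaged ERPs
#'
#' Arithmetic mean over kept epochs, per condition and channel.
#'
#' @param epochs an [epoch_set()].
#' @param min_epochs minimum kept epochs required per condition.
#' @return an `erp_set`: list with `erp` (condition x channel x sample
#'   array), `n_epochs` per condition, `time_ms`, `sampling_rate`,
#'   `montage`, `subject_id`, `log`.
#' @export
average_erp <- function(epochs, min_epochs = 10L) {
  conds <- sort(unique(epochs$condition))
  n <- vapply(conds, function(cc) sum(epochs$kept & epochs$condition == cc), 0L)
  low <- n < min_epochs
  if (any(low))
    stop(sprintf("condition '%s' has %d kept epochs (< %d required)",
                 conds[low][1], n[low][1], min_epochs))
  d <- dim(epochs$data)
  erp <- array(0, dim = c(length(conds), d[2], d[3]),
               dimnames = list(conds, epochs$montage$name, NULL))
  for (k in seq_along(conds)) {
    sel <- epochs$kept & epochs$condition == conds[k]
    erp[k, , ] <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  }
  structure(list(erp = erp, n_epochs = n, time_ms = epochs$time_ms,
                 sampling_rate = epochs$sampling_rate,
                 montage = epochs$montage, subject_id = epochs$subject_id,
                 log = c(epochs$log, sprintf("average_erp (min %d)", min_epochs))),
            class = "erp_set")
}

#' Standard preprocessing chain
#'
#' Baseline correction, ocular regression, amplitude-based artifact
#' rejection, condition averaging — in that fixed order.
#'
#' @param epochs an [epoch_set()].
#' @param baseline_window ms interval for [baseline_correct()].
#' @param eog_channels regressors for [regress_ocular()] (NULL = montage
#'   EOG channels; NA = skip the stage, e.g. montages without EOG).
#' @param monitor_channels,threshold_uv,post_window_ms,pre_window_ms,drop_epochs
#'   passed to [reject_artifacts()].
#' @param min_epochs passed to [average_erp()].
#' @return an `erp_set`.
#' @export
preprocess_epochs <- function(epochs, baseline_window = c(-150, 0),
                              eog_channels = NULL, monitor_channels = NULL,
                              threshold_uv = 100, post_window_ms = 1500,
                              pre_window_ms = 800, drop_epochs = integer(),
                              min_epochs = 10L) {
  epochs <- baseline_correct(epochs, baseline_window)
  if (!(length(eog_channels) == 1L && is.na(eog_channels[1])) &&
      any(epochs$montage$type == "eog"))
    epochs <- regress_ocular(epochs, eog_channels)
  epochs <- reject_artifacts(epochs, monitor_channels, threshold_uv,
                             post_window_ms, pre_window_ms, drop_epochs)
  average_erp(epochs, min_epochs)
}
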