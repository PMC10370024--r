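#' Feedback-locked EEG epoch container
#'
#' Holds one subject's epoched multichannel EEG in µV: an epochs x channels
#' x samples array, a uniform time axis in ms relative to feedback onset,
#' per-epoch condition labels (gain/loss), the montage, a kept/rejected
#' mask, and a provenance log that each preprocessing stage appends to.
#'
#' @param data numeric array `[epochs, channels, samples]` (µV).
#' @param time_ms strictly increasing, uniform time axis (ms).
#' @param sampling_rate Hz.
#' @param montage data.frame with `name`, `x`, `y`, `type` per channel.
#' @param condition character/factor per epoch, `"gain"` or `"loss"`.
#' @param subject_id identifier.
#' @param kept logical per epoch (default all `TRUE`).
#' @param log character vector of provenance entries.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, time_ms, sampling_rate, montage, condition,
                      subject_id = "S001", kept = NULL, log = character()) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[2] == nrow(montage),
            dim(data)[3] == length(time_ms),
            dim(data)[1] == length(condition))
  dt <- diff(time_ms)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
    stop("time axis must be strictly increasing and uniform")
  if (is.null(kept)) kept <- rep(TRUE, dim(data)[1])
  structure(list(data = data, time_ms = time_ms,
                 sampling_rate = sampling_rate, montage = montage,
                 condition = as.character(condition),
                 subject_id = subject_id, kept = kept, log = log),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set %s: %d epochs (%d kept) x %d channels x %d samples, %g Hz, %g..%g ms>\n",
              x$subject_id, d[1], sum(x$kept), d[2], d[3],
              x$sampling_rate, min(x$time_ms), max(x$time_ms)))
  if (length(x$log)) cat(paste0("  - ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

append_log <- function(epochs, entry) {
  epochs$log <- c(epochs$log, entry)
  epochs
}

#' Write / read an epoch set as HDF5
#'
#' Layout: dataset `/data` (epochs x channels x samples, float µV),
#' `/time_ms`, `/condition`, `/kept`, `/channel_names`, `/channel_xy`,
#' `/channel_type`, `/log`, and root attributes `sampling_rate` and
#' `subject_id`. A JSON sidecar (same path + `.json`) can carry the
#' generator config and seed when written by the pipeline.
#'
#' @param epochs an [epoch_set()].
#' @param path file path (`.h5`).
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns
#'   an [epoch_set()].
#' @export
write_epochs <- function(epochs, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(epochs$data, path, "data")
  rhdf5::h5write(epochs$time_ms, path, "time_ms")
  rhdf5::h5write(epochs$condition, path, "condition")
  rhdf5::h5write(as.integer(epochs$kept), path, "kept")
  rhdf5::h5write(epochs$montage$name, path, "channel_names")
  rhdf5::h5write(cbind(epochs$montage$x, epochs$montage$y), path, "channel_xy")
  rhdf5::h5write(epochs$montage$type, path, "channel_type")
  rhdf5::h5write(if (length(epochs$log)) epochs$log else "", path, "log")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(epochs$sampling_rate, fid, "sampling_rate")
  rhdf5::h5writeAttribute(epochs$subject_id, fid, "subject_id")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  xy <- rhdf5::h5read(path, "channel_xy")
  montage <- data.frame(name = as.character(rhdf5::h5read(path, "channel_names")),
                        x = xy[, 1], y = xy[, 2],
                        type = as.character(rhdf5::h5read(path, "channel_type")),
                        stringsAsFactors = FALSE)
  fid <- rhdf5::H5Fopen(path)
  fs <- rhdf5::h5readAttributes(fid, "/")$sampling_rate
  sid <- rhdf5::h5readAttributes(fid, "/")$subject_id
  rhdf5::H5Fclose(fid)
  logv <- as.character(rhdf5::h5read(path, "log"))
  epoch_set(data = rhdf5::h5read(path, "data"),
            time_ms = as.numeric(rhdf5::h5read(path, "time_ms")),
            sampling_rate = as.numeric(fs),
            montage = montage,
            condition = as.character(rhdf5::h5read(path, "condition")),
            subject_id = as.character(sid),
            kept = as.logical(rhdf5::h5read(path, "kept")),
            log = logv[nzchar(logv)])
}
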