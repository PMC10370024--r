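# HDF5 / JSON persistence for ERP sets, TF stacks and tf-PCA models.

#' Write / read a list of per-subject ERP sets as HDF5
#'
#' Layout: `/erp` (subject x condition x channel x sample, µV), `/time_ms`,
#' `/subjects`, `/conditions`, `/channel_names`, `/channel_xy`,
#' `/channel_type`, `/n_epochs` (subject x condition), attribute
#' `sampling_rate`.
#'
#' @param erps list of `erp_set` objects sharing axes and montage.
#' @param path file path.
#' @return `write_erps` returns `path` invisibly; `read_erps` the list.
#' @export
write_erps <- function(erps, path) {
  if (file.exists(path)) unlink(path)
  conds <- rownames(erps[[1]]$erp)
  d <- dim(erps[[1]]$erp)
  arr <- array(0, dim = c(length(erps), d))
  ne <- matrix(0L, length(erps), length(conds))
  for (s in seq_along(erps)) {
    arr[s, , , ] <- erps[[s]]$erp
    ne[s, ] <- erps[[s]]$n_epochs[conds]
  }
  rhdf5::h5createFile(path)
  rhdf5::h5write(arr, path, "erp")
  rhdf5::h5write(erps[[1]]$time_ms, path, "time_ms")
  rhdf5::h5write(vapply(erps, function(e) e$subject_id, ""), path, "subjects")
  rhdf5::h5write(conds, path, "conditions")
  rhdf5::h5write(erps[[1]]$montage$name, path, "channel_names")
  rhdf5::h5write(cbind(erps[[1]]$montage$x, erps[[1]]$montage$y), path,
                 "channel_xy")
  rhdf5::h5write(erps[[1]]$montage$type, path, "channel_type")
  rhdf5::h5write(ne, path, "n_epochs")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(erps[[1]]$sampling_rate, fid, "sampling_rate")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_erps
#' @export
read_erps <- function(path) {
  arr <- rhdf5::h5read(path, "erp")
  xy <- rhdf5::h5read(path, "channel_xy")
  montage <- data.frame(name = as.character(rhdf5::h5read(path, "channel_names")),
                        x = xy[, 1], y = xy[, 2],
                        type = as.character(rhdf5::h5read(path, "channel_type")),
                        stringsAsFactors = FALSE)
  subjects <- as.character(rhdf5::h5read(path, "subjects"))
  conds <- as.character(rhdf5::h5read(path, "conditions"))
  ne <- rhdf5::h5read(path, "n_epochs")
  fid <- rhdf5::H5Fopen(path)
  fs <- as.numeric(rhdf5::h5readAttributes(fid, "/")$sampling_rate)
  rhdf5::H5Fclose(fid)
  tms <- as.numeric(rhdf5::h5read(path, "time_ms"))
  lapply(seq_along(subjects), function(s) {
    erp <- array(arr[s, , , ], dim = dim(arr)[-1],
                 dimnames = list(conds, montage$name, NULL))
    structure(list(erp = erp, n_epochs = setNames(as.integer(ne[s, ]), conds),
                   time_ms = tms, sampling_rate = fs, montage = montage,
                   subject_id = subjects[s], log = character()),
              class = "erp_set")
  })
}

#' Write / read a TF surface stack as HDF5
#'
#' Layout: `/tf` (row x time x freq), `/time_ms`, `/freq_hz`, row-index
#' datasets `/subject`, `/condition`, `/channel`, attribute `band`.
#'
#' @param stack a `tf_stack`.
#' @param path file path.
#' @return `write_tf_stack` returns `path` invisibly; `read_tf_stack` the
#'   stack.
#' @export
write_tf_stack <- function(stack, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(stack$values, path, "tf")
  rhdf5::h5write(stack$time_ms, path, "time_ms")
  rhdf5::h5write(stack$freq_hz, path, "freq_hz")
  for (col in c("subject", "condition", "channel"))
    rhdf5::h5write(stack$index[[col]], path, col)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(stack$band, fid, "band")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_tf_stack
#' @export
read_tf_stack <- function(path) {
  fid <- rhdf5::H5Fopen(path)
  band <- as.character(rhdf5::h5readAttributes(fid, "/")$band)
  rhdf5::H5Fclose(fid)
  structure(list(values = rhdf5::h5read(path, "tf"),
                 index = data.frame(
                   subject = as.character(rhdf5::h5read(path, "subject")),
                   condition = as.character(rhdf5::h5read(path, "condition")),
                   channel = as.character(rhdf5::h5read(path, "channel")),
                   stringsAsFactors = FALSE),
                 time_ms = as.numeric(rhdf5::h5read(path, "time_ms")),
                 freq_hz = as.numeric(rhdf5::h5read(path, "freq_hz")),
                 band = band),
            class = "tf_stack")
}

#' Persist a fitted tf-PCA model
#'
#' HDF5 carries the numeric state (eigenvalues, loadings, rotation, center,
#' axes, row index); the JSON summary carries variance explained, the
#' selected component and the band tag.
#'
#' @param model a `tfpca_model`.
#' @param selected selected component index.
#' @param h5_path,json_path output paths.
#' @return `h5_path` invisibly.
#' @export
write_tfpca_model <- function(model, selected, h5_path, json_path = NULL) {
  if (file.exists(h5_path)) unlink(h5_path)
  rhdf5::h5createFile(h5_path)
  rhdf5::h5write(model$eigenvalues, h5_path, "eigenvalues")
  rhdf5::h5write(model$loadings, h5_path, "loadings")
  rhdf5::h5write(model$rotation, h5_path, "rotation")
  rhdf5::h5write(model$center, h5_path, "center")
  rhdf5::h5write(model$var_explained, h5_path, "var_explained")
  rhdf5::h5write(model$time_ms, h5_path, "time_ms")
  rhdf5::h5write(model$freq_hz, h5_path, "freq_hz")
  for (col in c("subject", "condition", "channel"))
    rhdf5::h5write(model$index[[col]], h5_path, col)
  fid <- rhdf5::H5Fopen(h5_path)
  rhdf5::h5writeAttribute(if (is.null(model$band)) "" else model$band, fid, "band")
  rhdf5::h5writeAttribute(as.integer(selected), fid, "selected")
  rhdf5::H5Fclose(fid)
  if (!is.null(json_path))
    jsonlite::write_json(list(band = model$band,
                              n_retained = model$n_retained,
                              var_explained = model$var_explained,
                              selected = selected),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(h5_path)
}

#' @rdname write_tfpca_model
#' @export
read_tfpca_model <- function(h5_path) {
  fid <- rhdf5::H5Fopen(h5_path)
  at <- rhdf5::h5readAttributes(fid, "/")
  rhdf5::H5Fclose(fid)
  L <- rhdf5::h5read(h5_path, "loadings")
  tm <- as.numeric(rhdf5::h5read(h5_path, "time_ms"))
  fq <- as.numeric(rhdf5::h5read(h5_path, "freq_hz"))
  model <- structure(list(
    band = if (nzchar(at$band)) as.character(at$band) else NULL,
    eigenvalues = as.numeric(rhdf5::h5read(h5_path, "eigenvalues")),
    var_explained = as.numeric(rhdf5::h5read(h5_path, "var_explained")),
    loadings = L,
    loadings_tf = lapply(seq_len(ncol(L)), function(j)
      unflatten_tf(L[, j], tm, fq)),
    rotation = rhdf5::h5read(h5_path, "rotation"),
    center = as.numeric(rhdf5::h5read(h5_path, "center")),
    n_retained = ncol(L),
    index = data.frame(
      subject = as.character(rhdf5::h5read(h5_path, "subject")),
      condition = as.character(rhdf5::h5read(h5_path, "condition")),
      channel = as.character(rhdf5::h5read(h5_path, "channel")),
      stringsAsFactors = FALSE),
    time_ms = tm, freq_hz = fq), class = "tfpca_model")
  list(model = model, selected = as.integer(at$selected))
}

#' Write a model result as JSON (plus a CSV coefficient table)
#'
#' @param result a `model_result`.
#' @param json_path output JSON path; a sibling `.csv` with the coefficient
#'   table is written alongside.
#' @param extras optional named list merged into the JSON payload.
#' @return `json_path` invisibly.
#' @export
write_model_result <- function(result, json_path, extras = NULL) {
  payload <- c(list(
    coefficients = cbind(term = rownames(result$coefficients),
                         result$coefficients),
    vif = as.list(result$vif),
    random_intercept_var = result$random_intercept_var,
    sigma = result$sigma,
    df_method = result$df_method,
    robust = result$robust,
    iterations = result$iterations,
    n_subjects = result$n_subjects), extras)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  utils::write.csv(cbind(term = rownames(result$coefficients),
                         result$coefficients),
                   sub("\\.json$", ".csv", json_path), row.names = FALSE)
  invisible(json_path)
}
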