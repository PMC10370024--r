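#' Vectorize a stack of TF surfaces into a data matrix
#'
#' One row per (subject, condition, channel); columns are the flattened TF
#' points in fixed column-major order (time index varying fastest, then
#' frequency). The row index travels with the matrix for inverse mapping.
#'
#' @param stack a `tf_stack` from [erp_band_surfaces()].
#' @return matrix with attributes `index` (data.frame), `time_ms`,
#'   `freq_hz`, `band`.
#' @export
build_data_matrix <- function(stack) {
  d <- dim(stack$values)
  X <- matrix(stack$values, nrow = d[1])
  structure(X, index = stack$index, time_ms = stack$time_ms,
            freq_hz = stack$freq_hz, band = stack$band)
}

#' Reshape a flattened loading (or surface row) back to a TF matrix
#'
#' Inverse of the flattening used by [build_data_matrix()].
#'
#' @param v numeric vector of length `n_time * n_freq`.
#' @param time_ms,freq_hz the surface axes.
#' @return time x frequency matrix.
#' @export
unflatten_tf <- function(v, time_ms, freq_hz) {
  matrix(v, nrow = length(time_ms), ncol = length(freq_hz))
}

# largest drop in successive eigenvalue ratios, minimum 1 component
scree_select <- function(lambda, max_scan = 10L) {
  lam <- lambda[lambda > max(lambda) * 1e-12]
  if (length(lam) < 2L) return(1L)
  m <- min(max_scan, length(lam) - 1L)
  ratios <- lam[seq_len(m) + 1L] / lam[seq_len(m)]
  which.min(ratios)
}

#' Varimax rotation
#'
#' Iterative maximization of the varimax criterion (sum over components of
#' the variance of squared loadings) by pairwise-orthogonal planar updates
#' via the SVD formulation; stops when the criterion gain drops below
#' `eps` (relative) or after `max_iter` sweeps. Kaiser row normalization is
#' off by default because TF loadings share units across cells.
#'
#' @param loadings p x k matrix, k >= 1.
#' @param normalize Kaiser-normalize rows before rotating.
#' @param eps relative convergence tolerance on the criterion.
#' @param max_iter sweep cap.
#' @return list `loadings` (rotated), `rotation` (orthogonal k x k),
#'   `criterion` (final value), `iterations`.
#' @export
varimax_rotate <- function(loadings, normalize = FALSE, eps = 1e-8,
                           max_iter = 500L) {
  if (!all(is.finite(loadings))) stop("non-finite loadings")
  L <- as.matrix(loadings)
  p <- nrow(L); k <- ncol(L)
  if (k < 1L) stop("at least one component required")
  if (k == 1L)
    return(list(loadings = L, rotation = matrix(1, 1, 1),
                criterion = varimax_criterion(L), iterations = 0L))
  sc <- rep(1, p)
  if (normalize) {
    sc <- sqrt(rowSums(L^2)); sc[sc == 0] <- 1
    L <- L / sc
  }
  R <- diag(k)
  d_old <- 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Z <- L %*% R
    B <- crossprod(L, Z^3 - Z %*% diag(colSums(Z^2) / p, k))
    sv <- svd(B)
    R <- sv$u %*% t(sv$v)
    d_new <- sum(sv$d)
    if (iter >= max_iter || d_new < d_old * (1 + eps)) break
    d_old <- d_new
  }
  out <- (L * sc) %*% R
  list(loadings = out, rotation = R,
       criterion = varimax_criterion(out), iterations = iter)
}

#' Varimax simplicity criterion
#'
#' `sum_j [ mean(L_j^4) - mean(L_j^2)^2 ]`: the quantity [varimax_rotate()]
#' maximizes over orthogonal rotations.
#'
#' @param loadings p x k matrix.
#' @return scalar criterion value.
#' @export
varimax_criterion <- function(loadings) {
  L2 <- as.matrix(loadings)^2
  sum(colMeans(L2^2) - colMeans(L2)^2)
}

#' Fit a time-frequency PCA model
#'
#' Eigendecomposition of the column covariance matrix of the data matrix
#' (columns mean-centered only), scree-based or explicit retention,
#' optional scaling of retained loadings by the component standard
#' deviation, varimax rotation, and a sign convention that makes each
#' component's largest-magnitude loading cell positive.
#'
#' @param X data matrix from [build_data_matrix()] (rows >= 2).
#' @param n_components `"scree"` (retain the components before the largest
#'   drop in successive eigenvalue ratios, minimum 1) or an explicit count.
#' @param scale_loadings multiply unit eigenvectors by `sqrt(eigenvalue)`
#'   before rotation (component-loading convention).
#' @param rotate apply varimax (identity rotation when `FALSE`).
#' @param normalize Kaiser normalization flag passed to [varimax_rotate()].
#' @return a `tfpca_model`: eigenvalues, `var_explained` of retained
#'   components, rotated `loadings` (p x k), `loadings_tf` (list of TF
#'   matrices), `rotation`, `center`, `n_retained`, axes and row index.
#' @export
fit_tfpca <- function(X, n_components = "scree", scale_loadings = TRUE,
                      rotate = TRUE, normalize = FALSE) {
  n <- nrow(X)
  if (is.null(n) || n < 2L) stop("need at least 2 rows")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  G <- tcrossprod(Xc)
  eg <- eigen(G, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  lambda <- vals / (n - 1)
  rank <- sum(vals > max(vals) * 1e-10)
  k <- if (identical(n_components, "scree")) scree_select(lambda[seq_len(rank)])
       else as.integer(n_components)
  if (k > rank) stop(sprintf("n_components (%d) exceeds rank (%d)", k, rank))
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  V <- crossprod(Xc, U) %*% diag(1 / sqrt(vals[seq_len(k)]), k)  # unit loadings
  if (scale_loadings) V <- V %*% diag(sqrt(lambda[seq_len(k)]), k)
  rot <- if (rotate) varimax_rotate(V, normalize = normalize)
         else list(loadings = V, rotation = diag(k))
  L <- rot$loadings
  R <- rot$rotation
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]
      R[, j] <- -R[, j]
    }
  }
  tm <- attr(X, "time_ms"); fq <- attr(X, "freq_hz")
  ltf <- if (!is.null(tm))
    lapply(seq_len(k), function(j) unflatten_tf(L[, j], tm, fq))
  structure(list(band = attr(X, "band"),
                 eigenvalues = lambda[seq_len(rank)],
                 var_explained = lambda[seq_len(k)] / sum(lambda[seq_len(rank)]),
                 loadings = L, loadings_tf = ltf, rotation = R,
                 center = center, n_retained = k,
                 index = attr(X, "index"), time_ms = tm, freq_hz = fq),
            class = "tfpca_model")
}

#' @export
print.tfpca_model <- function(x, ...) {
  cat(sprintf("<tfpca_model%s: %d retained component(s), variance %s>\n",
              if (is.null(x$band)) "" else paste0(" ", x$band), x$n_retained,
              paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = "/")))
  invisible(x)
}

#' Select the component matching a target template window
#'
#' Returns the retained component with maximum squared-loading energy
#' inside the target's TF window. Defaults: delta-RewP 0.5-3 Hz x
#' 200-500 ms; theta-FRN 4-8 Hz x 250-400 ms. A manual override is honored
#' verbatim, with a warning when it disagrees with the automatic choice.
#'
#' @param model a fitted `tfpca_model` with TF axes.
#' @param target `"delta-RewP"` or `"theta-FRN"`.
#' @param template_window optional list `time_ms`, `freq_hz` (2-element
#'   ranges) replacing the default window.
#' @param override optional explicit component index.
#' @return integer component index.
#' @export
select_component <- function(model, target = c("delta-RewP", "theta-FRN"),
                             template_window = NULL, override = NULL) {
  target <- match.arg(target)
  if (model$n_retained < 1L) stop("model retains no components")
  win <- template_window
  if (is.null(win))
    win <- if (target == "delta-RewP")
      list(time_ms = c(200, 500), freq_hz = c(0.5, 3))
    else list(time_ms = c(250, 400), freq_hz = c(4, 8))
  ti <- model$time_ms >= win$time_ms[1] & model$time_ms <= win$time_ms[2]
  fi <- model$freq_hz >= win$freq_hz[1] & model$freq_hz <= win$freq_hz[2]
  if (!any(ti) || !any(fi)) stop("template window matches no TF cells")
  energy <- vapply(model$loadings_tf,
                   function(m) sum(m[ti, fi, drop = FALSE]^2), 0)
  auto <- which.max(energy)
  if (!is.null(override)) {
    if (override != auto)
      warning(sprintf("override component %d differs from automatic choice %d",
                      override, auto))
    return(as.integer(override))
  }
  as.integer(auto)
}

#' PC-weighted component scores
#'
#' Score = mean over TF points of the elementwise product of a subject/
#' condition/channel surface with the component loading ("PC-weighted TF
#' surface"), evaluated at one designated sensor. `"auto-max"` picks the
#' channel whose grand-average score magnitude is largest; `"all"` returns
#' every channel (used for contrast topographies).
#'
#' @param model fitted `tfpca_model`.
#' @param X raw (uncentered) data matrix from [build_data_matrix()] with
#'   its row index.
#' @param component component index (see [select_component()]).
#' @param sensor channel name, `"auto-max"`, or `"all"`.
#' @param label component label recorded in the output.
#' @return data.frame: subject, condition, channel, component, sensor,
#'   value.
#' @export
pc_weighted_scores <- function(model, X, component, sensor = "auto-max",
                               label = "component") {
  idx <- attr(X, "index")
  stopifnot(!is.null(idx), component >= 1, component <= model$n_retained)
  a <- model$loadings[, component]
  val <- as.numeric(X %*% a) / length(a)
  tab <- cbind(idx, data.frame(component = label, value = val,
                               stringsAsFactors = FALSE))
  if (identical(sensor, "all")) {
    tab$sensor <- tab$channel
    return(tab)
  }
  if (identical(sensor, "auto-max")) {
    gm <- tapply(tab$value, tab$channel, mean)
    sensor <- names(gm)[which.max(abs(gm))]
  }
  if (!sensor %in% tab$channel) stop("unknown sensor name: ", sensor)
  out <- tab[tab$channel == sensor, , drop = FALSE]
  out$sensor <- sensor
  rownames(out) <- NULL
  out[, c("subject", "condition", "component", "sensor", "value")]
}

#' Loss-minus-gain contrast topography of component scores
#'
#' Per channel, mean over subjects of (loss score - gain score); returned
#' with channel positions for plotting.
#'
#' @param scores all-channel score table from
#'   `pc_weighted_scores(..., sensor = "all")`.
#' @param montage optional montage data.frame supplying `x`, `y`.
#' @return data.frame: channel, contrast (loss - gain), and positions if a
#'   montage was given.
#' @export
condition_contrast_topography <- function(scores, montage = NULL) {
  if (!all(c("gain", "loss") %in% scores$condition))
    stop("both conditions (gain, loss) must be present")
  m <- aggregate(value ~ channel + condition, scores, mean)
  wide <- merge(m[m$condition == "loss", c("channel", "value")],
                m[m$condition == "gain", c("channel", "value")],
                by = "channel", suffixes = c("_loss", "_gain"))
  out <- data.frame(channel = wide$channel,
                    contrast = wide$value_loss - wide$value_gain,
                    stringsAsFactors = FALSE)
  if (!is.null(montage))
    out <- merge(out, montage[, c("name", "x", "y")],
                 by.x = "channel", by.y = "name", sort = FALSE)
  out
}

#' Tucker congruence coefficient
#'
#' Similarity of two loading vectors/matrices:
#' `sum(a*b) / sqrt(sum(a^2) * sum(b^2))`.
#'
#' @param a,b numeric vectors or matrices of equal length.
#' @return scalar in `[-1, 1]`.
#' @export
tucker_congruence <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
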