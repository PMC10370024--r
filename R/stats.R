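#' Z-score columns of a table
#'
#' Standardizes the named columns to mean 0, SD 1 (denominator n-1) and
#' records the scaling parameters so the transform can be reverted.
#'
#' @param table data.frame.
#' @param columns character vector of numeric columns.
#' @return the table with columns standardized; attribute `"scaling"` holds
#'   a data.frame (column, mean, sd).
#' @export
zscore_table <- function(table, columns) {
  sc <- data.frame(column = columns, mean = NA_real_, sd = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_along(columns)) {
    cl <- columns[i]
    x <- table[[cl]]
    if (!is.numeric(x)) stop("column not numeric: ", cl)
    s <- sd(x)
    if (!is.finite(s) || s == 0) stop("zero-variance column: ", cl)
    sc$mean[i] <- mean(x); sc$sd[i] <- s
    table[[cl]] <- (x - sc$mean[i]) / s
  }
  attr(table, "scaling") <- sc
  table
}

#' Revert a z-scored table to its original scale
#'
#' @param table a table produced by [zscore_table()] (carrying its
#'   `"scaling"` attribute), or any table plus an explicit `scaling` frame.
#' @param scaling optional scaling data.frame (column, mean, sd).
#' @return the table on the original scale.
#' @export
zscore_revert <- function(table, scaling = attr(table, "scaling")) {
  if (is.null(scaling)) stop("no scaling record found")
  for (i in seq_len(nrow(scaling)))
    table[[scaling$column[i]]] <-
      table[[scaling$column[i]]] * scaling$sd[i] + scaling$mean[i]
  attr(table, "scaling") <- NULL
  table
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on all the others
#' (with intercept). Predictors with VIF at or above `flag_at` (default 5,
#' the screening criterion) are listed in the `"flagged"` attribute.
#'
#' @param design data.frame or matrix of numeric predictors (>= 2 columns,
#'   more rows than columns).
#' @param flag_at flagging threshold.
#' @return named numeric vector of VIFs with attribute `"flagged"`.
#' @export
compute_vif <- function(design, flag_at = 5) {
  X <- as.matrix(as.data.frame(design))
  p <- ncol(X)
  if (p < 2L) stop("need at least two predictors")
  if (nrow(X) <= p) stop("need more observations than predictors")
  if (qr(cbind(1, X))$rank < p + 1L) stop("singular design matrix")
  vif <- vapply(seq_len(p), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    1 / (1 - r2)
  }, 0)
  names(vif) <- colnames(X)
  attr(vif, "flagged") <- names(vif)[vif >= flag_at]
  vif
}

#' Screen a dependent variable for an age association
#'
#' Pearson correlation between the subject-mean DV and age; age is flagged
#' for inclusion as a covariate when the correlation is significant at the
#' configured threshold.
#'
#' @param scores score table with `subject` (or `subject_id`) and `value`.
#' @param covariates cohort table with `subject_id` and `age`.
#' @param threshold inclusion p-value threshold.
#' @return list: `r`, `p`, `include_age`, `n`.
#' @export
screen_age <- function(scores, covariates, threshold = 0.05) {
  sid <- if ("subject" %in% names(scores)) scores$subject else scores$subject_id
  m <- aggregate(list(value = scores$value), list(subject_id = sid), mean)
  m <- merge(m, covariates[, c("subject_id", "age")], by = "subject_id")
  if (nrow(m) < 3L) stop("need at least 3 subjects")
  if (sd(m$value) == 0 || sd(m$age) == 0) stop("constant input")
  ct <- cor.test(m$value, m$age)
  list(r = unname(ct$estimate), p = ct$p.value,
       include_age = ct$p.value < threshold, n = nrow(m))
}

#' Specification of a mixed-effects analysis
#'
#' Fixed effects: the within-subject factor, each between-subject term, and
#' the within x between interactions (never between x between), plus any
#' extra covariates (e.g. age) entered as main effects only; random
#' intercept per subject.
#'
#' @param dependent response column name.
#' @param within within-subject factor column (two levels; the
#'   alphabetically first level — `gain` — is the reference).
#' @param between between-subject term names (continuous covariates or
#'   binary diagnosis flags).
#' @param covariates_extra additional main-effect covariates.
#' @param robust use Huber-weighted iterative fitting.
#' @param zscore standardize the DV and all continuous predictors before
#'   fitting (binary terms are left as 0/1).
#' @param subject grouping column for the random intercept.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(dependent, within, between = character(),
                       covariates_extra = character(), robust = TRUE,
                       zscore = TRUE, subject = "subject_id") {
  terms <- c(dependent, within, between, covariates_extra, subject)
  if (anyDuplicated(c(within, between, covariates_extra)))
    stop("duplicate model terms")
  structure(list(dependent = dependent, within = within, between = between,
                 covariates_extra = covariates_extra, robust = robust,
                 zscore = zscore, subject = subject), class = "model_spec")
}

huber_weights <- function(r, k = 1.345) {
  s <- mad(r, center = 0)
  if (s <= .Machine$double.eps^0.5) return(rep(1, length(r)))
  u <- abs(r / s)
  ifelse(u <= k, 1, k / u)
}

#' Fit a (robust) linear mixed-effects model
#'
#' Fits `dv ~ within + between terms + within:between + extras` with a
#' subject random intercept via lme4. With `robust = TRUE` the fit is
#' iteratively reweighted: residuals from the current fit receive Huber
#' weights (tuning constant 1.345 on MAD-scaled residuals) and the model is
#' refit until the weights stabilize — an M-estimation scheme that bounds
#' the influence of gross outliers at the observation level. Inference uses
#' t-statistics from the final (weighted) fit with Kenward-Roger
#' approximate degrees of freedom; when the Kenward-Roger computation is
#' unavailable for a fit, Satterthwaite df are used and the method is
#' recorded in the diagnostics.
#'
#' @param data long-format data.frame: one row per subject x within-level
#'   (or trial stratum), containing all spec columns.
#' @param spec a [model_spec()].
#' @param huber_k Huber tuning constant.
#' @param max_iter,tol IRLS iteration cap and max weight-change tolerance.
#' @return a `model_result`: `coefficients` (estimate, se, df, t, p,
#'   ci_lo, ci_hi), `vif`, `random_intercept_var`, `sigma`, `df_method`,
#'   `robust`, `weights`, `converged`, `n_subjects`, plus the underlying
#'   `fit`, `spec` and `data` for post-hoc contrasts.
#' @export
fit_mixed_model <- function(data, spec, huber_k = 1.345, max_iter = 25L,
                            tol = 1e-3) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c(spec$dependent, spec$within, spec$between, spec$covariates_extra,
            spec$subject)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- data[, need, drop = FALSE]
  names(df)[names(df) == spec$dependent] <- ".dv"
  df$.within <- factor(df[[spec$within]])
  df$.subject <- factor(df[[spec$subject]])
  if (nlevels(df$.within) != 2L) stop("within factor must have two levels")

  is_binary <- vapply(c(spec$between, spec$covariates_extra), function(v) {
    x <- df[[v]]
    is.logical(x) || all(x %in% c(0, 1))
  }, TRUE)
  cont <- c(spec$between, spec$covariates_extra)[!is_binary]
  for (v in names(is_binary)[is_binary]) df[[v]] <- as.numeric(df[[v]])
  if (spec$zscore) df <- zscore_table(df, c(".dv", cont))

  rhs <- ".within"
  for (b in spec$between) rhs <- c(rhs, b, paste0(".within:", b))
  rhs <- c(rhs, spec$covariates_extra)
  fml <- stats::as.formula(paste(".dv ~", paste(rhs, collapse = " + "),
                                 "+ (1 | .subject)"))

  fit_once <- function(w) {
    df$.w <- w
    suppressMessages(lmerTest::lmer(fml, data = df, weights = .w,
                                    control = lme4::lmerControl(
                                      check.conv.singular = "ignore")))
  }
  w <- rep(1, nrow(df))
  fit <- fit_once(w)
  iterations <- 0L
  if (spec$robust) {
    for (it in seq_len(max_iter)) {
      iterations <- it
      w_new <- huber_weights(resid(fit), huber_k)
      delta <- max(abs(w_new - w))
      w <- w_new
      fit <- fit_once(w)
      if (delta < tol) break
    }
  }
  if (length(lme4::fixef(fit)) < length(attr(stats::terms(fml), "term.labels")))
    stop("rank-deficient fixed-effect design")

  kr_failed <- FALSE
  sm <- tryCatch(
    withCallingHandlers(
      list(tab = stats::coef(summary(fit, ddf = "Kenward-Roger")),
           method = "Kenward-Roger"),
      warning = function(w) {
        if (grepl("Kenward-Roger", conditionMessage(w))) kr_failed <<- TRUE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(sm) || kr_failed)
    sm <- list(tab = stats::coef(summary(fit, ddf = "Satterthwaite")),
               method = "Satterthwaite")
  tab <- as.data.frame(sm$tab)
  names(tab) <- c("estimate", "se", "df", "t", "p")
  tab$ci_lo <- tab$estimate - qt(0.975, tab$df) * tab$se
  tab$ci_hi <- tab$estimate + qt(0.975, tab$df) * tab$se

  vif <- NULL
  preds <- c(spec$between, spec$covariates_extra)
  if (length(preds) >= 2L) {
    sub <- df[!duplicated(df$.subject), preds, drop = FALSE]
    vif <- tryCatch(compute_vif(sub), error = function(e) NULL)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = tab,
                 vif = vif,
                 random_intercept_var = vc$vcov[vc$grp == ".subject"][1],
                 sigma = stats::sigma(fit),
                 df_method = sm$method,
                 robust = spec$robust,
                 iterations = iterations,
                 weights = w,
                 converged = TRUE,
                 n_subjects = nlevels(df$.subject),
                 within_levels = levels(df$.within),
                 fit = fit, spec = spec, data = df),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result: %s fit, %d subjects, %s df>\n",
              if (x$robust) "robust (Huber-IRLS)" else "ML",
              x$n_subjects, x$df_method))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Simple slopes of a covariate at each within-factor level
#'
#' Post-hoc characterization of a within x covariate interaction: the
#' covariate slope at each level of the within factor as a linear
#' combination of fixed effects (main effect, plus the interaction
#' coefficient at the non-reference level), with SE from the coefficient
#' covariance and the model's approximate-df method.
#'
#' @param result a `model_result` from [fit_mixed_model()].
#' @param covariate covariate name (must have a within-interaction in the
#'   model).
#' @return data.frame per within level: slope, se, df, t, p, ci_lo, ci_hi.
#' @export
simple_slopes <- function(result, covariate) {
  fit <- result$fit
  cn <- names(lme4::fixef(fit))
  if (!covariate %in% cn) stop("no main effect for covariate: ", covariate)
  lv <- result$within_levels
  int_name <- intersect(
    c(paste0(".within", lv[2], ":", covariate),
      paste0(covariate, ":.within", lv[2])), cn)
  if (!length(int_name)) stop("missing interaction term for: ", covariate)
  ddf <- result$df_method
  rows <- lapply(seq_along(lv), function(i) {
    L <- setNames(rep(0, length(cn)), cn)
    L[covariate] <- 1
    if (i == 2L) L[int_name] <- 1
    ct <- tryCatch(lmerTest::contest1D(fit, L, ddf = ddf),
                   error = function(e) lmerTest::contest1D(fit, L,
                                                           ddf = "Satterthwaite"))
    data.frame(level = lv[i], slope = ct$Estimate, se = ct$`Std. Error`,
               df = ct$df, t = ct$`t value`, p = ct$`Pr(>|t|)`,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ci_lo <- out$slope - qt(0.975, out$df) * out$se
  out$ci_hi <- out$slope + qt(0.975, out$df) * out$se
  out
}
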