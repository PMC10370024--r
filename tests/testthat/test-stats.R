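test_that("z-scoring is exact, idempotent, and reversible", {
  df <- data.frame(a = c(1, 2, 3), b = c(10, 20, 40))
  z <- zscore_table(df, c("a", "b"))
  expect_equal(z$a, c(-1, 0, 1))
  z2 <- zscore_table(z, "a")
  expect_equal(z2$a, z$a, tolerance = 1e-12)
  back <- zscore_revert(z)
  expect_equal(back$a, df$a, tolerance = 1e-12)
  expect_equal(back$b, df$b, tolerance = 1e-12)
  expect_error(zscore_table(data.frame(a = c(2, 2, 2)), "a"),
               "zero-variance column: a")
})

test_that("VIFs match the closed-form inverse-correlation oracle", {
  set.seed(30)
  X <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
  v <- compute_vif(X)
  # orthogonal-in-expectation predictors: VIF ~ 1
  expect_equal(as.vector(v), rep(1, 2), tolerance = 0.1)
  # near-duplicate predictor is flagged
  Xc <- data.frame(x1 = X$x1, x2 = X$x1 + rnorm(100, 0, 1e-4), x3 = X$x2)
  vc <- compute_vif(Xc)
  expect_gt(vc["x2"], 5)
  expect_true("x2" %in% attr(vc, "flagged"))
  # known correlation 0.5: diagonal of the inverse correlation matrix
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  Z <- MASS::mvrnorm(500, rep(0, 3), S, empirical = TRUE)
  colnames(Z) <- paste0("z", 1:3)
  vz <- compute_vif(Z)
  oracle <- diag(solve(stats::cor(Z)))
  expect_equal(as.vector(vz), unname(oracle), tolerance = 1e-6)
  expect_error(compute_vif(data.frame(a = X$x1, b = 2 * X$x1)), "singular")
})

test_that("age screening recovers planted correlations", {
  co <- data.frame(subject_id = sprintf("S%03d", 1:50), age = seq(22, 59,
                                                                  length.out = 50))
  sc <- data.frame(subject = rep(co$subject_id, 2),
                   condition = rep(c("gain", "loss"), each = 50),
                   value = rep(-co$age, 2))
  out <- screen_age(sc, co)
  expect_equal(out$r, -1)
  expect_true(out$include_age)
  # independent dv: no inclusion at large n
  set.seed(31)
  co2 <- data.frame(subject_id = sprintf("S%04d", 1:5000),
                    age = runif(5000, 22, 59))
  sc2 <- data.frame(subject = co2$subject_id, value = rnorm(5000))
  out2 <- screen_age(sc2, co2)
  expect_lt(abs(out2$r), 0.05)
  expect_false(out2$include_age)
  # generator with a negative age coefficient yields a negative recovered r
  cfg <- generator_config(n_subjects = 300,
                          amplitudes = list(c_age = -0.3))
  co3 <- simulate_cohort(300, cfg, seed = 32)
  tru <- amplitude_truth(co3, cfg)
  sc3 <- data.frame(subject = tru$subject_id, value = tru$A_theta)
  expect_lt(screen_age(sc3, co3)$r, 0)
  expect_error(screen_age(data.frame(subject = "a", value = 1),
                          data.frame(subject_id = "a", age = 30)),
               "at least 3")
})

test_that("mixed model recovers a planted generative model exactly without noise", {
  set.seed(33)
  n <- 50
  u <- rnorm(n, 0, 0.6)
  long <- do.call(rbind, lapply(c("gain", "loss"), function(w)
    data.frame(subject_id = sprintf("S%02d", 1:n), outcome = w,
               dv = 2 + 1 * (w == "loss") + u)))
  r <- suppressWarnings(fit_mixed_model(
    long, model_spec("dv", "outcome", robust = FALSE, zscore = FALSE)))
  expect_equal(r$coefficients[".withinloss", "estimate"], 1, tolerance = 1e-6)
  # variance partition needs a nondegenerate residual
  long$dv <- long$dv + rnorm(2 * n, 0, 0.05)
  r2 <- suppressWarnings(fit_mixed_model(
    long, model_spec("dv", "outcome", robust = FALSE, zscore = FALSE)))
  expect_equal(r2$random_intercept_var, var(u), tolerance = 0.2)
  expect_error(fit_mixed_model(long, model_spec("dv", "outcome", "nope")),
               "missing columns")
})

test_that("simple slopes reproduce linear combinations of fixed effects", {
  set.seed(34)
  n <- 80
  x <- rnorm(n); u <- rnorm(n, 0, 0.4)
  long <- do.call(rbind, lapply(c("gain", "loss"), function(w)
    data.frame(subject_id = sprintf("S%02d", 1:n), outcome = w, x = x,
               dv = 0.3 * x + 0.5 * (w == "loss") + u +
                 rnorm(n, 0, 0.2))))
  r <- fit_mixed_model(long, model_spec("dv", "outcome", "x",
                                        robust = FALSE, zscore = FALSE))
  ss <- simple_slopes(r, "x")
  b <- r$coefficients
  # with the interaction in the model, slopes are exact coefficient sums
  expect_equal(ss$slope[ss$level == "gain"], b["x", "estimate"],
               tolerance = 1e-8)
  expect_equal(ss$slope[ss$level == "loss"],
               b["x", "estimate"] + b[".withinloss:x", "estimate"],
               tolerance = 1e-8)
  expect_true(all(ss$ci_lo < ss$slope & ss$slope < ss$ci_hi))
  expect_true(all(r$coefficients$ci_lo < r$coefficients$estimate &
                    r$coefficients$estimate < r$coefficients$ci_hi))
  expect_error(simple_slopes(r, "z"), "no main effect")

  # a zero planted interaction keeps both slopes near the main effect
  long$dv <- 0.3 * long$x + rep(u, 2) + rnorm(2 * n, 0, 0.05)
  r0 <- suppressWarnings(fit_mixed_model(
    long, model_spec("dv", "outcome", "x", robust = FALSE, zscore = FALSE)))
  ss0 <- simple_slopes(r0, "x")
  expect_equal(ss0$slope[1], r0$coefficients["x", "estimate"],
               tolerance = 1e-8)
  expect_lt(abs(ss0$slope[2] - ss0$slope[1]), 0.05)  # interaction ~ 0
})

test_that("standardized estimates are invariant to covariate rescaling", {
  set.seed(35)
  n <- 60
  x <- rnorm(n); u <- rnorm(n, 0, 0.4)
  mk <- function(scale_x) do.call(rbind, lapply(c("gain", "loss"), function(w)
    data.frame(subject_id = sprintf("S%02d", 1:n), outcome = w,
               x = x * scale_x,
               dv = 0.4 * x + 0.6 * (w == "loss") + u + rep(rnorm(n, 0, 0.3), 1))))
  set.seed(36); d1 <- mk(1)
  set.seed(36); d2 <- mk(1000)
  spec <- model_spec("dv", "outcome", "x", robust = FALSE)
  r1 <- fit_mixed_model(d1, spec)
  r2 <- fit_mixed_model(d2, spec)
  expect_equal(r1$coefficients$estimate, r2$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("robust weighting leaves clean Gaussian fits essentially unchanged", {
  set.seed(37)
  long <- amplitude_condition_means(generator_config(n_subjects = 60), 37)
  rr <- fit_mixed_model(long, model_spec("dv", "outcome", "audit_c",
                                         robust = TRUE, zscore = FALSE))
  rn <- fit_mixed_model(long, model_spec("dv", "outcome", "audit_c",
                                         robust = FALSE, zscore = FALSE))
  expect_lt(abs(rr$coefficients[".withinloss", "estimate"] -
                  rn$coefficients[".withinloss", "estimate"]) /
              abs(rn$coefficients[".withinloss", "estimate"]), 0.05)
  expect_equal(rr$df_method %in% c("Kenward-Roger", "Satterthwaite"), TRUE)
  expect_true(all(rr$weights > 0 & rr$weights <= 1))
})
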