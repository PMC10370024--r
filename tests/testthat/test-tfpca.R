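test_that("data matrix bookkeeping: dimensions, round trip, stable order", {
  set.seed(1)
  vals <- array(rnorm(12 * 10 * 8), c(12, 10, 8))
  idx <- expand.grid(channel = c("Fz", "Cz", "Pz"),
                     condition = c("gain", "loss"),
                     subject = c("S001", "S002"),
                     stringsAsFactors = FALSE)[, 3:1]
  stack <- structure(list(values = vals, index = idx,
                          time_ms = as.numeric(1:10),
                          freq_hz = as.numeric(1:8), band = "delta"),
                     class = "tf_stack")
  X <- build_data_matrix(stack)
  expect_equal(dim(X), c(12L, 80L))
  # unflatten(flatten(surface)) is exact
  expect_identical(unflatten_tf(X[5, ], stack$time_ms, stack$freq_hz),
                   vals[5, , ])
  # column order is deterministic across runs
  X2 <- build_data_matrix(stack)
  expect_identical(digest::digest(as.vector(X)), digest::digest(as.vector(X2)))
})

test_that("planted templates are recovered by the covariance PCA", {
  set.seed(2)
  t1 <- tf_blob(30, 20, 10, 5)
  X <- planted_matrix(t1, runif(50, 0.5, 2))
  m <- fit_tfpca(X)
  expect_equal(m$n_retained, 1L)
  expect_gt(m$var_explained[1], 0.99)
  expect_gt(abs(tucker_congruence(m$loadings[, 1], as.vector(t1))), 0.99)

  # two templates with disjoint support
  t2 <- tf_blob(30, 20, 24, 15)
  X2 <- planted_matrix(t1, runif(60, 0.5, 2)) +
    planted_matrix(t2, runif(60, 0.5, 2), seed = 3)
  m2 <- fit_tfpca(X2, n_components = 2)
  cg <- abs(outer(1:2, 1:2, Vectorize(function(i, j)
    tucker_congruence(m2$loadings[, i], as.vector(list(t1, t2)[[j]])))))
  expect_gt(max(cg[1, ]), 0.95)
  expect_gt(max(cg[2, ]), 0.95)
  expect_false(which.max(cg[1, ]) == which.max(cg[2, ]))  # distinct matches
  expect_error(fit_tfpca(X2, n_components = 500), "rank")
})

test_that("rotation leaves the retained-subspace reconstruction invariant", {
  set.seed(4)
  X <- matrix(rnorm(40 * 60), 40)
  attr(X, "time_ms") <- as.numeric(1:10); attr(X, "freq_hz") <- as.numeric(1:6)
  rot <- fit_tfpca(X, n_components = 3, rotate = TRUE)
  unrot <- fit_tfpca(X, n_components = 3, rotate = FALSE)
  proj <- function(L) {
    Q <- qr.Q(qr(L))
    Q %*% t(Q)
  }
  expect_equal(proj(rot$loadings), proj(unrot$loadings), tolerance = 1e-8)
  # variance proportions: in (0, 1], non-increasing, summing to <= 1
  expect_true(all(unrot$var_explained > 0 & unrot$var_explained <= 1))
  expect_true(all(diff(unrot$var_explained) <= 1e-12))
  expect_lte(sum(unrot$var_explained), 1 + 1e-12)
})

test_that("varimax maximizes the criterion and matches oracles", {
  # single component: identity rotation
  L1 <- matrix(rnorm(20), 20, 1)
  v1 <- varimax_rotate(L1)
  expect_identical(v1$loadings, L1)
  expect_equal(v1$rotation, matrix(1, 1, 1))
  # already-simple structure is a fixed point up to permutation/sign
  Ls <- cbind(c(rep(2, 10), rep(0, 10)), c(rep(0, 10), rep(3, 10)))
  vs <- varimax_rotate(Ls)
  agree <- abs(crossprod(vs$loadings, Ls)) /
    outer(sqrt(colSums(vs$loadings^2)), sqrt(colSums(Ls^2)))
  expect_equal(sort(apply(agree, 1, max)), c(1, 1), tolerance = 1e-6)
  set.seed(5)
  for (rep in 1:5) {
    L <- matrix(rnorm(60), 30, 2)
    vr <- varimax_rotate(L)
    expect_gte(vr$criterion, varimax_criterion(L) - 1e-12)
    # 2-D rotation-angle grid-search oracle
    ang <- seq(0, pi / 2, length.out = 20001)
    gr <- max(vapply(ang, function(a) varimax_criterion(
      L %*% matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)), 0))
    expect_lt(abs(vr$criterion - gr), 1e-4)
    # orthogonal rotation matrix
    expect_lt(max(abs(crossprod(vr$rotation) - diag(2))), 1e-10)
    # independent implementation agrees on the criterion value
    sv <- stats::varimax(L, normalize = FALSE, eps = 1e-10)
    expect_equal(vr$criterion, varimax_criterion(L %*% sv$rotmat),
                 tolerance = 1e-6)
  }
  expect_error(varimax_rotate(matrix(c(1, NA), 2, 1)), "non-finite")
})

test_that("component selection uses the template window and honors overrides", {
  set.seed(6)
  frn <- tf_blob(40, 33, t0 = 23, f0 = 7, st = 2, sf = 1.5)  # ~6 Hz, ~350 ms
  n1 <- tf_blob(40, 33, t0 = 17, f0 = 7, st = 2, sf = 1.5)   # early theta (N1-like)
  X <- planted_matrix(frn, runif(40, 0.5, 2)) +
    planted_matrix(n1, runif(40, 0.5, 2), seed = 7)
  attr(X, "time_ms") <- seq(-500, 1000, length.out = 40)
  attr(X, "freq_hz") <- seq(0, 32, length.out = 33)
  m <- fit_tfpca(X, n_components = 2)
  sel <- select_component(m, "theta-FRN")
  win_t <- attr(X, "time_ms")[23]
  expect_true(win_t > 250 && win_t < 400)       # the FRN blob is in-window
  cg <- abs(vapply(1:2, function(j)
    tucker_congruence(m$loadings[, j], as.vector(frn)), 0))
  expect_equal(sel, which.max(cg))
  expect_warning(ov <- select_component(m, "theta-FRN",
                                        override = setdiff(1:2, sel)),
                 "differs")
  expect_equal(ov, setdiff(1:2, sel))
  # single retained component: always index 1
  m1 <- fit_tfpca(planted_matrix(frn, runif(30, 0.5, 2)))
  attr_x <- attributes(m1)
  expect_equal(select_component(m1, "delta-RewP",
                                template_window = list(time_ms = c(5, 35),
                                                       freq_hz = c(5, 20))), 1L)
})

test_that("PC-weighted scores behave as projections and are row-order invariant", {
  set.seed(8)
  tpl <- tf_blob(20, 10, 8, 4)
  amps <- runif(12, 0.5, 2)
  X <- planted_matrix(tpl, amps, noise_sd = 1e-8)
  idx <- expand.grid(channel = c("Cz", "FCz"), condition = c("gain", "loss"),
                     subject = c("S1", "S2", "S3"),
                     stringsAsFactors = FALSE)[, 3:1]
  attr(X, "index") <- idx
  m <- fit_tfpca(X)
  # surface equal to the loading itself scores mean(loading^2) > 0
  Xa <- rbind(m$loadings[, 1], 0)
  attr(Xa, "index") <- data.frame(subject = c("S1", "S1"),
                                  condition = c("gain", "loss"),
                                  channel = "Cz", stringsAsFactors = FALSE)
  attr(Xa, "time_ms") <- attr(X, "time_ms"); attr(Xa, "freq_hz") <- attr(X, "freq_hz")
  sc <- pc_weighted_scores(m, Xa, 1, sensor = "Cz")
  expect_equal(sc$value[sc$condition == "gain"], mean(m$loadings[, 1]^2))
  expect_gt(sc$value[sc$condition == "gain"], 0)
  expect_equal(sc$value[sc$condition == "loss"], 0)  # zero surface -> 0
  expect_error(pc_weighted_scores(m, Xa, 1, sensor = "Oz9"), "unknown sensor")

  # permuting rows permutes scores identically
  sc1 <- pc_weighted_scores(m, X, 1, sensor = "all")
  perm <- sample(nrow(X))
  Xp <- X[perm, ]
  attr(Xp, "index") <- idx[perm, ]
  sc2 <- pc_weighted_scores(m, Xp, 1, sensor = "all")
  key <- function(s) s[order(s$subject, s$condition, s$channel), "value"]
  expect_equal(key(sc1), key(sc2), tolerance = 1e-12)
})

test_that("condition contrast topography is zero for identical conditions and signed for planted effects", {
  sc <- data.frame(subject = rep(c("S1", "S2"), each = 4),
                   condition = rep(c("gain", "loss"), 4),
                   channel = rep(c("Cz", "FCz"), each = 2, times = 2),
                   value = 1.5, stringsAsFactors = FALSE)
  topo <- condition_contrast_topography(sc)
  expect_equal(topo$contrast, c(0, 0))
  sc$value[sc$condition == "loss" & sc$channel == "FCz"] <- 3
  topo2 <- condition_contrast_topography(sc, default_montage(16, 0))
  expect_equal(topo2$contrast[topo2$channel == "FCz"], 1.5)
  expect_equal(topo2$contrast[topo2$channel == "Cz"], 0)
  expect_true(all(c("x", "y") %in% names(topo2)))
  expect_error(condition_contrast_topography(sc[sc$condition == "gain", ]),
               "both conditions")
})
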