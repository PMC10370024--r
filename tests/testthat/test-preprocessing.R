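test_that("baseline correction removes the baseline-window mean", {
  # constant epoch -> all zeros
  d <- array(5, dim = c(1, 3, 256))
  ep <- make_epochs(d, t0 = -150, montage = default_montage(3, 0))
  out <- baseline_correct(ep)
  expect_equal(max(abs(out$data)), 0)

  # known baseline mean is subtracted as a pure shift
  d2 <- array(rep(sin(seq_len(256) / 10) + 2.5, each = 2), c(1, 2, 256))
  ep2 <- make_epochs(d2, t0 = -150, montage = default_montage(2, 0))
  t <- ep2$time_ms
  bl <- rowMeans(d2[1, , t >= -150 & t <= 0])
  out2 <- baseline_correct(ep2)
  expect_equal(out2$data[1, , ], d2[1, , ] - bl, tolerance = 1e-12)

  # random epochs: post-hoc baseline mean is 0 within float tolerance
  set.seed(1)
  ep3 <- make_epochs(array(rnorm(4 * 5 * 256), c(4, 5, 256)), t0 = -150,
                     montage = default_montage(5, 0))
  out3 <- baseline_correct(ep3)
  idx <- out3$time_ms >= -150 & out3$time_ms <= 0
  expect_lt(max(abs(apply(out3$data[, , idx], c(1, 2), mean))), 1e-9)

  expect_error(baseline_correct(ep3, c(-5000, 0)), "outside epoch span")
})

test_that("ocular regression recovers clean EEG under known propagation", {
  # clean signal and EOG have disjoint support, so least squares is exact
  n <- 512
  clean <- c(sin(2 * pi * 5 * (1:256) / 256), rep(0, 256))
  eog <- c(rep(0, 256), 80 * sin(pi * (1:256) / 256))
  mont <- rbind(default_montage(2, 0),
                data.frame(name = "VEOG", x = 0, y = 1.1, type = "eog"))
  d <- array(0, c(1, 3, n))
  d[1, 1, ] <- clean + 0.3 * eog
  d[1, 2, ] <- 2 * clean + 0.1 * eog
  d[1, 3, ] <- eog
  ep <- epoch_set(d, time_ms = (0:(n - 1)), sampling_rate = 1000,
                  montage = mont, condition = "gain")
  out <- regress_ocular(ep, "VEOG")
  expect_lt(sqrt(mean((out$data[1, 1, ] - clean)^2)), 1e-6)
  expect_lt(sqrt(mean((out$data[1, 2, ] - 2 * clean)^2)), 1e-6)
  expect_equal(out$data[1, 3, ], eog)          # EOG retained unmodified
  b <- attr(out, "ocular_coefficients")
  expect_equal(unname(b[, 1]), c(0.3, 0.1), tolerance = 1e-9)

  # residuals orthogonal to the regressor
  set.seed(2)
  d[1, 1, ] <- rnorm(n); d[1, 2, ] <- rnorm(n)
  ep2 <- epoch_set(d, time_ms = (0:(n - 1)), sampling_rate = 1000,
                   montage = mont, condition = "gain")
  out2 <- regress_ocular(ep2, "VEOG")
  expect_lt(abs(sum(out2$data[1, 1, ] * eog)) / sqrt(sum(eog^2)), 1e-8)

  # zero propagation: output equals input
  d[1, 1, ] <- clean; d[1, 2, ] <- clean
  ep3 <- epoch_set(d, time_ms = (0:(n - 1)), sampling_rate = 1000,
                   montage = mont, condition = "gain")
  out3 <- regress_ocular(ep3, "VEOG")
  expect_equal(out3$data[1, 1, ], clean, tolerance = 1e-9)

  # constant EOG is an error
  d[1, 3, ] <- 1
  ep4 <- epoch_set(d, time_ms = (0:(n - 1)), sampling_rate = 1000,
                   montage = mont, condition = "gain")
  expect_error(regress_ocular(ep4, "VEOG"), "zero variance")
})

test_that("artifact rejection honors thresholds, windows, and channel order", {
  fs <- 256
  n <- 768                                     # -1000..2000 ms
  mk <- function(spikes) {
    # spikes: list of c(epoch, time_ms)
    d <- array(0, c(10, 4, n))
    ep <- make_epochs(d, fs = fs, montage = default_montage(4, 0),
                      condition = rep(c("gain", "loss"), 5))
    for (s in spikes) {
      idx <- which.min(abs(ep$time_ms - s[2]))
      ep$data[s[1], 1, idx] <- 150
    }
    ep
  }
  # spike at +500 ms on a monitored channel -> dropped
  ep <- mk(list(c(1, 500)))
  out <- reject_artifacts(ep, channels = c("Fz", "FCz"))
  expect_false(out$kept[1])
  # spike at +1800 ms -> outside the 1500-ms poststimulus window -> kept
  ep <- mk(list(c(1, 1800)))
  out <- reject_artifacts(ep, channels = c("Fz", "FCz"))
  expect_true(all(out$kept))
  # spike at -900 ms -> outside the 800-ms prestimulus window -> kept
  ep <- mk(list(c(1, -900)))
  out <- reject_artifacts(ep, channels = c("Fz", "FCz"))
  expect_true(all(out$kept))
  # 3 spiked epochs inside windows out of 10 -> exactly 7 survive
  ep <- mk(list(c(2, 100), c(5, -300), c(9, 1400)))
  out <- reject_artifacts(ep, channels = c("Fz", "FCz"))
  expect_equal(sum(out$kept), 7L)
  expect_setequal(attr(out, "rejection_report")$epoch, c(2, 5, 9))
  # decisions invariant to channel ordering
  out2 <- reject_artifacts(ep, channels = c("FCz", "Fz"))
  expect_identical(out$kept, out2$kept)
  # spikes on unmonitored channels are ignored
  ep$data[3, 4, 300] <- 500
  out3 <- reject_artifacts(ep, channels = c("Fz", "FCz"))
  expect_true(out3$kept[3])
  # rejecting everything in one condition is an error
  ep <- mk(lapply(seq(1, 9, 2), function(e) c(e, 500)))  # all gain epochs
  expect_error(reject_artifacts(ep, channels = c("Fz", "FCz")),
               "insufficient data")
})

test_that("ERP averaging is an arithmetic mean with a minimum-count contract", {
  d <- array(0, c(4, 2, 64))
  base <- sin(seq_len(64) / 5)
  for (e in 1:4) d[e, , ] <- rep(base, each = 2)
  ep <- make_epochs(d, montage = default_montage(2, 0),
                    condition = c("gain", "gain", "loss", "loss"))
  erp <- average_erp(ep, min_epochs = 2)
  expect_equal(erp$erp["gain", 1, ], base)     # identical epochs -> that epoch
  # +1/-1 constant epochs average to zero
  d2 <- array(c(1, -1), c(2, 2, 64))
  ep2 <- make_epochs(d2, montage = default_montage(2, 0),
                     condition = c("gain", "gain"))
  expect_error(average_erp(ep2), "kept epochs")
  erp2 <- average_erp(ep2, min_epochs = 2)
  expect_equal(max(abs(erp2$erp["gain", , ])), 0)
  # ERP error shrinks ~ 1/sqrt(n)
  set.seed(3)
  tmpl <- sin(seq_len(64) / 4)
  noisy <- function(n) {
    dd <- array(rep(tmpl, each = n * 8), c(n, 8, 64)) +
      array(rnorm(n * 8 * 64), c(n, 8, 64))
    e <- average_erp(make_epochs(dd, montage = default_montage(8, 0),
                                 condition = rep("gain", n)), min_epochs = 1)
    sqrt(mean((sweep(e$erp["gain", , ], 2, tmpl))^2))
  }
  ratio <- noisy(50) / noisy(10)
  expect_gt(ratio, 0.25)
  expect_lt(ratio, 0.65)
})

test_that("the preprocessing chain runs in order and logs provenance", {
  cfg <- generator_config(n_subjects = 1, n_trials = 24)
  co <- simulate_cohort(1, cfg, seed = 8)
  tr <- simulate_trial_amplitudes(co, simulate_behavior(co, cfg, seed = 8),
                                  cfg, seed = 8)
  ep <- simulate_subject_epochs(co[1, ], tr, cfg, seed = 8)
  erp <- preprocess_epochs(ep, min_epochs = 2)
  expect_match(erp$log[1], "baseline")
  expect_match(erp$log[2], "ocular")
  expect_match(erp$log[3], "reject")
  expect_match(erp$log[4], "average")
})
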