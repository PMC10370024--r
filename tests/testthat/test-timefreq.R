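test_that("zero-phase Butterworth matches the analytic squared magnitude response", {
  fs <- 256
  t <- (0:(8 * fs - 1)) / fs
  mid <- (2 * fs):(6 * fs)
  ratio_at <- function(f, kind, cutoff) {
    x <- sin(2 * pi * f * t)
    y <- butterworth_filter(x, kind, cutoff, fs)
    sqrt(mean(y[mid]^2) / mean(x[mid]^2))
  }
  # DC through the low-pass is untouched
  dc <- butterworth_filter(rep(1, 2048), "lowpass", 4, fs)
  expect_equal(dc, rep(1, 2048), tolerance = 1e-6)
  # probe frequencies against |H|^2 for both kinds
  for (f in c(2, 6, 8)) {
    expect_lt(abs(ratio_at(f, "lowpass", 4) / butterworth_gain2(f, 4) - 1),
              0.02)
    expect_lt(abs(ratio_at(f, "highpass", 2) /
                    butterworth_gain2(f, 2, kind = "highpass") - 1), 0.02)
  }
  # zero phase: a symmetric pulse stays symmetric about its center
  n <- 1024
  pulse <- exp(-((1:n) - 512.5)^2 / (2 * 30^2))
  y <- butterworth_filter(pulse, "lowpass", 8, fs)
  expect_equal(y, rev(y), tolerance = 1e-9)
  expect_error(butterworth_filter(pulse, "lowpass", 200, fs), "Nyquist")
})

test_that("binomial RID conserves energy on random signals", {
  set.seed(10)
  errs <- replicate(100, {
    x <- rnorm(sample(128:512, 1))
    s <- binomial_rid(x, 128)
    abs(sum(s$values) - sum(x^2)) / sum(x^2)
  })
  expect_lt(max(errs), 1e-6)
  # zero in, zero out
  s0 <- binomial_rid(rep(0, 256), 128)
  expect_equal(max(abs(s0$values)), 0)
  expect_error(binomial_rid(c(1, NA, 3), 128), "non-finite")
  expect_error(binomial_rid(rnorm(256), 128, downsample_to = 512),
               "target above")
})

test_that("RID concentrates tones in frequency and impulses in time", {
  fs <- 128
  x <- sin(2 * pi * 6 * (0:511) / fs)
  s <- binomial_rid(x, fs)
  fm <- colSums(s$values)
  expect_gt(sum(fm[s$freq_hz >= 4 & s$freq_hz <= 8]) / sum(fm), 0.9)
  # unit impulse: time marginal within +-2 bins of the impulse
  k <- 100
  xi <- rep(0, 256); xi[k] <- 1
  si <- binomial_rid(xi, fs)
  tm <- rowSums(si$values)
  expect_gt(sum(tm[(k - 2):(k + 2)]) / sum(tm), 0.9)
})

test_that("RID is time-shift covariant away from the edges", {
  fs <- 128
  burst <- function(center) {
    t <- (0:383) / fs
    sin(2 * pi * 8 * t) * exp(-(t - center)^2 / (2 * 0.05^2))
  }
  s1 <- binomial_rid(burst(1.2), fs)
  s2 <- binomial_rid(burst(1.2 + 16 / fs), fs)   # shift by 16 samples
  inner <- 100:250
  expect_equal(s2$values[inner + 16, ], s1$values[inner, ], tolerance = 1e-8)
})

test_that("RID frequency marginal matches the periodogram for noise-free tones", {
  # full-lag transform (no lag truncation), both spectra aggregated onto a
  # common 2-Hz partition of 0..fs/4
  fs <- 128; n <- 1024
  breaks <- seq(-1, fs / 4 + 1, by = 2)   # bands centred on even frequencies
  for (f0 in c(6, 10)) {
    x <- sin(2 * pi * f0 * (0:(n - 1)) / fs)
    s <- binomial_rid(x, fs, n_freq_bins = 513L)
    marg <- colSums(s$values)
    mb <- vapply(seq_len(length(breaks) - 1), function(i)
      sum(marg[s$freq_hz >= breaks[i] & s$freq_hz < breaks[i + 1]]), 0)
    mb <- mb / sum(mb)
    p <- abs(fft(x))^2 / n
    pf <- (0:(n - 1)) * fs / n
    pb <- vapply(seq_len(length(breaks) - 1), function(i)
      sum(p[pf >= breaks[i] & pf < breaks[i + 1]]), 0)
    pb <- pb / sum(pb)
    expect_lt(sum(abs(mb - pb)), 0.05)
  }
})

test_that("band surfaces localize planted components and respect zero input", {
  fs <- 256
  n <- 768
  t_ms <- -1000 + (0:(n - 1)) / fs * 1000
  mont <- default_montage(2, 0)
  mk_erp <- function(wave) {
    erp <- array(rep(wave, each = 2 * 2), c(2, 2, n),
                 dimnames = list(c("gain", "loss"), mont$name, NULL))
    structure(list(erp = erp, n_epochs = c(gain = 20L, loss = 20L),
                   time_ms = t_ms, sampling_rate = fs, montage = mont,
                   subject_id = "S001", log = character()),
              class = "erp_set")
  }
  theta_burst <- cos(2 * pi * 6 * (t_ms - 325) / 1000) *
    exp(-(t_ms - 325)^2 / (2 * 55^2))
  sf <- erp_band_surfaces(mk_erp(theta_burst), band_config())
  v <- sf$theta$values[1, , ]
  # marginal peaks localize the burst (pointwise cells can carry signed
  # cross-terms; the marginals are the physically meaningful projections)
  fpk <- sf$theta$freq_hz[which.max(colSums(v))]
  tpk <- sf$theta$time_ms[which.max(rowSums(v))]
  expect_true(fpk >= 4 && fpk <= 8)
  expect_true(tpk >= 200 && tpk <= 450)

  slow <- exp(-(t_ms - 350)^2 / (2 * 80^2))
  sd_ <- erp_band_surfaces(mk_erp(slow), band_config())
  vd <- sd_$delta$values[1, , ]
  fm <- colSums(vd)
  expect_gt(sum(fm[sd_$delta$freq_hz <= 3]) / sum(abs(fm)), 0.9)

  sz <- erp_band_surfaces(mk_erp(rep(0, n)), band_config())
  expect_equal(max(abs(sz$delta$values)), 0)
  expect_equal(max(abs(sz$theta$values)), 0)
})
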