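test_that("a constant-amplitude tone demodulates to a flat modulator", {
  fs <- 200
  t <- seq.int(0, 20 * fs - 1) / fs
  y <- amhier:::zscore(sin(2 * pi * 20 * t))
  res <- pad_demodulate(y, pad_params(1), fs = fs)
  expect_true(all(res$modulator > 0))
  expect_lt(stats::sd(res$modulator) / mean(res$modulator), 0.05)
})

test_that("a sinusoidal modulator on a noise carrier is recovered", {
  fs <- 1000
  t <- seq.int(0, 10 * fs - 1) / fs
  m_true <- 2 + sin(2 * pi * 1 * t)
  y <- amhier:::zscore(m_true * amhier:::with_seed(1, stats::rnorm(length(t))))
  res <- pad_demodulate(y, pad_params(0.3), fs = fs)
  expect_gt(stats::cor(m_true, res$modulator), 0.95)
  expect_gt(stats::cor(res$modulator * res$carrier, y), 0.99)
  expect_true(all(res$modulator > 0))
})

test_that("windowed processing of long signals still recovers the modulator", {
  fs <- 1000
  t <- seq.int(0, 40 * fs - 1) / fs
  m_true <- exp(0.6 * sin(2 * pi * 0.5 * t))
  y <- amhier:::zscore(m_true * amhier:::with_seed(2, stats::rnorm(length(t))))
  res <- pad_demodulate(y, pad_params(0.2), fs = fs)   # ~7 windows
  expect_gt(stats::cor(m_true, res$modulator), 0.95)
})

test_that("the modulator shape is invariant to input scale", {
  fs <- 500
  t <- seq.int(0, 10 * fs - 1) / fs
  m_true <- 2 + sin(2 * pi * 0.7 * t)
  c_t <- amhier:::with_seed(3, stats::rnorm(length(t)))
  shape <- lapply(c(0.1, 1, 10), function(alpha) {
    m <- pad_demodulate(alpha * m_true * c_t, pad_params(0.3), fs = fs)$modulator
    m / sqrt(sum(m^2))
  })
  expect_lt(max(abs(shape[[1]] - shape[[2]])), 2e-3)
  expect_lt(max(abs(shape[[3]] - shape[[2]])), 2e-3)
})

test_that("demodulation rejects a timescale on the order of the duration", {
  expect_error(pad_demodulate(stats::rnorm(1000), pad_params(2), fs = 1000),
               "timescale")
})

test_that("the cascade isolates the constructed hierarchy rates", {
  fs <- 16000
  tone <- make_compound_tone(synth_spec(duration = 20, sample_rate = fs,
                                        offset = 4))
  casc <- pad_cascade(normalize(tone$signal))
  expect_named(casc$band_modulators,
               c("delta", "theta", "alpha", "beta", "gamma"))
  got <- vapply(casc$band_modulators[1:4], function(m) {
    amhier:::spectral_argmax(m, casc$env_rate, f_min = 0.2)
  }, 0)
  bin <- casc$env_rate / length(casc$band_modulators$delta)
  expect_true(all(abs(got - c(2, 4, 8, 16)) <= bin + 1e-9))
  expect_true(all(vapply(casc$stage_modulators, function(m) all(m > 0), TRUE)))
})

test_that("cascade power concentrates in the tiers a hierarchy occupies", {
  h <- make_am_hierarchy(2, list(c(1, 2)), carrier = 200, duration = 20,
                         sample_rate = 4000)
  casc <- pad_cascade(normalize(h$signal))
  pw <- vapply(casc$band_modulators, stats::var, 0)
  expect_gt(10 * log10(pw[["delta"]] / pw[["alpha"]]), 20)
  expect_gt(10 * log10(pw[["delta"]] / pw[["gamma"]]), 20)
})

test_that("scalograms normalize to 0 dB and track ridges", {
  fs <- 200
  t <- seq.int(0, 30 * fs - 1) / fs
  sc <- cwt_scalogram(1 + 0.9 * sin(2 * pi * 2 * t), fs)
  expect_equal(max(sc$db), 0)
  ridge <- sc$freq[apply(sc$magnitude, 2, which.max)]
  mid <- seq.int(round(0.1 * length(t)), round(0.9 * length(t)))
  expect_true(all(abs(log2(ridge[mid] / 2)) < 1 / 8))   # within 2 voices
  # rising exponential chirp (1 -> 8 Hz): ridge rises monotonically overall
  f0 <- 1; f1 <- 8
  chirp <- 1 + 0.9 * sin(2 * pi * (f0 * max(t) / log(f1 / f0)) *
                           ((f1 / f0)^(t / max(t)) - 1))
  sc2 <- cwt_scalogram(chirp, fs)
  ridge2 <- sc2$freq[apply(sc2$magnitude, 2, which.max)]
  expect_gt(stats::cor(mid, ridge2[mid], method = "spearman"), 0.95)
  expect_error(cwt_scalogram(stats::rnorm(100), 50, f_range = c(0.1, 40)),
               "Nyquist")
})

test_that("scalogram corpus averaging maps onto the unit interval", {
  fs <- 100
  t <- seq.int(0, 10 * fs - 1) / fs
  maps <- lapply(c(2, 3), function(f) {
    cwt_scalogram(1 + 0.5 * sin(2 * pi * f * t), fs, f_range = c(0.5, 10))
  })
  avg <- scalogram_average(maps)
  expect_true(all(avg >= 0 & avg <= 1))
  expect_equal(dim(avg), dim(maps[[1]]$magnitude))
})

test_that("spectrum peaks find real components and ignore noise", {
  fs <- 200
  t <- seq.int(0, 30 * fs - 1) / fs
  x <- sin(2 * pi * 2 * t) + sin(2 * pi * 5 * t)
  pk <- spectrum_peaks(x, fs)
  bin <- fs / (2 * floor(length(x) / 9))    # Welch resolution bound
  expect_length(pk, 2)
  expect_true(all(abs(pk - c(2, 5)) < 2 * bin))
  # ground-truth parent modulator: single peak at the parent rate
  h <- make_am_hierarchy(2, list(c(1, 2)), duration = 30, sample_rate = 200,
                         seed = 5)
  pk2 <- spectrum_peaks(h$ground_truth$true_modulators[[1]], 200)
  expect_length(pk2, 1)
  expect_lt(abs(pk2 - 2), 2 * bin)
  expect_identical(spectrum_peaks(numeric(1000), 200), numeric(0))
  # white noise with a 6 dB prominence requirement: empty in >= 90% of seeds
  empty <- vapply(1:20, function(s) {
    length(amhier:::with_seed(s, spectrum_peaks(stats::rnorm(10000), 1000))) == 0
  }, TRUE)
  expect_gte(mean(empty), 0.9)
})

test_that("white-noise cascades show no spurious band peaks", {
  flat <- vapply(1:20, function(s) {
    sig <- audio_signal(amhier:::with_seed(s, stats::rnorm(16000)), 1000)
    casc <- pad_cascade(normalize(sig))
    all(vapply(names(casc$band_ranges), function(b) {
      rng <- casc$band_ranges[[b]]
      m <- casc$band_modulators[[b]]
      n <- length(m)
      m <- m[seq.int(floor(0.05 * n), ceiling(0.95 * n))]  # drop edge taper
      # deep Welch averaging so chance fluctuations sit well under 3 dB
      ps <- amhier:::welch_psd(m, casc$env_rate, n_segments = 32)
      lo <- max(rng[1] * 1.25, 0.4)
      sel <- ps$freq >= lo & ps$freq <= rng[2] * 0.8
      if (sum(sel) < 3) return(TRUE)
      p_db <- 10 * log10(ps$psd[sel])
      max(p_db) - stats::median(p_db) < 3
    }, TRUE))
  }, TRUE)
  expect_gte(mean(flat), 0.9)
})
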