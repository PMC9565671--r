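test_that("ERB filterbank centres span the requested range uniformly in ERB", {
  fb <- design_erb_filterbank(28, 100, 7250)
  expect_equal(fb$n_channels, 28)
  expect_equal(fb$channel_centers[1], 100, tolerance = 1e-6)
  expect_equal(fb$channel_centers[28], 7250, tolerance = 1e-6)
  expect_true(all(diff(fb$channel_centers) > 0))
  # spacing constant on the ERB-number scale: ERBn(f) = 21.4 log10(4.37 f/1000 + 1)
  erbn <- 21.4 * log10(4.37 * fb$channel_centers / 1000 + 1)
  expect_lt(diff(range(diff(erbn))), 1e-9)
  # two channels -> exactly the endpoints
  fb2 <- design_erb_filterbank(2, 100, 7250)
  expect_equal(fb2$channel_centers, c(100, 7250), tolerance = 1e-6)
  expect_error(design_erb_filterbank(1, 100, 7250), "at least 2")
})

test_that("a centred pure tone excites essentially one channel", {
  fs <- 16000
  fb <- design_erb_filterbank()
  # tone placed at the channel centre nearest 1 kHz; a tone at a channel
  # crossover necessarily splits between the two adjacent channels
  fc <- fb$channel_centers[which.min(abs(fb$channel_centers - 1000))]
  t <- seq.int(0, 2 * fs - 1) / fs
  sig <- normalize(audio_signal(sin(2 * pi * fc * t), fs))
  cem <- decompose(sig, fb, env_rate = 1000)
  e <- rowMeans(cem$envelopes^2)
  expect_equal(which.max(e), which.min(abs(fb$channel_centers - 1000)))
  expect_gt(max(e) / sum(e), 0.9)
})

test_that("decompose handles silence and rejects too-short signals", {
  fs <- 16000
  still <- audio_signal(numeric(fs), fs)
  cem <- decompose(still, design_erb_filterbank(), env_rate = 1000)
  expect_true(all(cem$envelopes == 0))
  short <- audio_signal(numeric(round(0.05 * fs)), fs)
  expect_error(decompose(short, design_erb_filterbank()), "too short")
})

test_that("filtering is zero-phase on synthetic AM tones", {
  fs <- 1000
  t <- seq.int(0, 10 * fs - 1) / fs
  env <- 1 + 0.9 * cos(2 * pi * 3 * t)
  filt <- amhier:::fft_bandpass(env - mean(env), fs, f_lo = 1, f_hi = 6)
  cc <- stats::ccf(env, filt, lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("channel envelope energies conserve broadband envelope energy", {
  fs <- 16000
  wn <- amhier:::with_seed(2, stats::rnorm(2 * fs))
  sig <- normalize(audio_signal(wn, fs))
  cem <- decompose(sig, design_erb_filterbank(), env_rate = 1000)
  broad <- mean(amhier:::hilbert_env(sig$samples)^2)
  ratio <- sum(rowMeans(cem$envelopes^2)) / broad
  expect_gt(10 * log10(ratio), -3)
  expect_lt(10 * log10(ratio), 3)
})

test_that("spectral PCA separates independently modulated channel blocks", {
  n <- 5000
  fb <- design_erb_filterbank()
  mk <- function(seed, scale) {
    e <- abs(amhier:::fft_bandpass(amhier:::with_seed(seed, stats::rnorm(n)),
                                   1000, f_hi = 10, order = 2))
    scale * e
  }
  e1 <- mk(9, 1)
  e2 <- mk(10, 0.5)
  jitter <- function(seed) {
    1 + 0.05 * amhier:::with_seed(seed, matrix(stats::rnorm(14 * n), 14))
  }
  env <- abs(rbind(matrix(rep(e1, each = 14), nrow = 14) * jitter(11),
                   matrix(rep(e2, each = 14), nrow = 14) * jitter(12)))
  cem <- channel_envelope_matrix(env, 1000, fb$channel_centers)
  L <- spectral_pca(cem)$loadings
  a <- 1:14
  b <- 15:28
  expect_gt(mean(L[1, a]), 10 * mean(L[1, b]))   # PC1 = the stronger block
  expect_gt(mean(L[2, b]), 10 * mean(L[2, a]))   # PC2 = the other block
})

test_that("spectral PCA edge cases behave as documented", {
  fb <- design_erb_filterbank()
  n <- 3000
  e <- abs(amhier:::fft_bandpass(amhier:::with_seed(1, stats::rnorm(n)),
                                 1000, f_hi = 10, order = 2))
  env <- matrix(1e-12, 28, n)
  env[7, ] <- e
  cem <- channel_envelope_matrix(env, 1000, fb$channel_centers)
  fit <- spectral_pca(cem)
  expect_gt(fit$explained_variance_ratio[1], 0.99)
  # duplicated corpus item leaves the grand average unchanged
  expect_equal(spectral_pca(list(cem, cem))$loadings, fit$loadings)
  # fewer time samples than channels is rejected
  tiny <- channel_envelope_matrix(matrix(1 + stats::runif(28 * 20), 28, 20),
                                  1000, fb$channel_centers)
  expect_error(spectral_pca(tiny), "fewer time samples")
})

test_that("band detection matches a brute-force oracle on small profiles", {
  centers <- seq_len(12)
  for (seed in 1:30) {
    L <- amhier:::with_seed(seed, {
      raw <- matrix(stats::runif(3 * 12), nrow = 3)
      # smooth a little so profiles resemble loading curves
      t(apply(raw, 1, function(v) stats::filter(c(v[1], v, v[12]),
                                                rep(1 / 3, 3))[2:13]))
    })
    loads <- pca_loadings(abs(L), c(0.5, 0.3, 0.2), centers)
    for (mpd in c(2, 3)) {
      got <- detect_bands(loads, min_peak_distance = mpd, min_pc_count = 2)
      want <- detect_bands_oracle(loads, min_peak_distance = mpd,
                                  min_pc_count = 2)
      expect_identical(as.integer(got$band_peak_channels), want$peaks)
      expect_identical(as.integer(got$band_edge_channels), want$edges)
    }
  }
})

test_that("band detection handles flat and near-tie profiles", {
  centers <- seq_len(10)
  flat <- pca_loadings(matrix(1, 2, 10), c(0.6, 0.4), centers)
  expect_length(detect_bands(flat)$band_peak_channels, 0)
  # two close peaks within a PC: only the larger survives the separation rule
  v <- c(0.1, 0.2, 1.0, 0.5, 0.9, 0.1, 0.1, 0.1, 0.1, 0.1)
  loads <- pca_loadings(rbind(v, v), c(0.6, 0.4), centers)
  got <- detect_bands(loads, min_peak_distance = 3, min_pc_count = 2)
  expect_identical(as.integer(got$band_peak_channels), 3L)
  expect_identical(find_peaks_oracle(v, 3), 3L)
  expect_identical(find_peaks_oracle(v, 1), c(3L, 5L))
})
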