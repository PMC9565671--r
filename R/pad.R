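# Probabilistic amplitude demodulation: MAP inference of a positive modulator
# under a Gaussian-process prior with an exponential link, the recursive
# cascade at the five oscillatory rates, and spectral summaries (Morlet
# scalograms, FFT peak extraction) of the resulting modulators.
#
# Model.  The signal is y_t = m_t * c_t with m_t = exp(x_t) a positive
# modulator and c_t a unit-variance white Gaussian carrier.  Marginalising the
# carrier, y_t | x_t ~ N(0, exp(2 x_t) + sigma_n^2).  x follows a stationary
# zero-mean GP with a squared-exponential kernel whose length-scale is the
# modulator timescale.  The MAP log-modulator maximises
#   -1/2 sum_t [ y_t^2 / v_t + log v_t ] - 1/2 x' K^{-1} x,
#   v_t = exp(2 x_t) + sigma_n^2.
# The prior term is evaluated with a circulant embedding of K, so K^{-1} x
# costs one FFT pair; the optimiser is L-BFGS-B with analytic gradients.
# Long signals are processed in 50%-overlapping windows cross-faded on the
# log-modulator.

#' PAD parameters
#'
#' @param timescale modulator timescale in seconds: the GP length-scale of
#'   the log-modulator.  The squared-exponential prior suppresses modulator
#'   content above roughly `0.19 / timescale` Hz.
#' @param noise_variance observation noise floor (relative to the unit
#'   carrier variance); keeps the likelihood finite when the modulator
#'   approaches zero.
#' @param prior_var prior variance of the log-modulator.
#' @return an object of class `pad_params`.
#' @export
pad_params <- function(timescale, noise_variance = 1e-3, prior_var = 1) {
  stopifnot(timescale > 0, noise_variance > 0, prior_var > 0)
  structure(list(timescale = timescale, noise_variance = noise_variance,
                 prior_var = prior_var, link = "exponential"),
            class = "pad_params")
}

# Circulant-embedding eigenvalues of the SE kernel on a length-n grid.
se_kernel_eigs <- function(n, fs, ell, prior_var) {
  tau <- seq.int(0L, n - 1L)
  d <- pmin(tau, n - tau) / fs
  row <- prior_var * exp(-d^2 / (2 * ell^2))
  lam <- Re(stats::fft(row))
  pmax(lam, 1e-9 * max(lam))
}

# Gaussian smoothing via FFT (used for initialisation only).
gauss_smooth <- function(x, fs, ell) {
  n <- length(x)
  tau <- seq.int(0L, n - 1L)
  d <- pmin(tau, n - tau) / fs
  w <- exp(-d^2 / (2 * ell^2))
  w <- w / sum(w)
  Re(stats::fft(stats::fft(x) * stats::fft(w), inverse = TRUE)) / n
}

# MAP log-modulator for one window.
pad_map_window <- function(y, fs, params, max_iter = 300) {
  n <- length(y)
  lam <- se_kernel_eigs(n, fs, params$timescale, params$prior_var)
  sn2 <- params$noise_variance
  y2 <- y^2
  x0 <- 0.5 * log(pmax(gauss_smooth(y2, fs, params$timescale), 0) + sn2)
  nlp <- function(x) {
    v <- exp(2 * x) + sn2
    X <- stats::fft(x)
    prior <- 0.5 * sum(Mod(X)^2 / lam) / n
    0.5 * sum(y2 / v + log(v)) + prior
  }
  grad <- function(x) {
    v <- exp(2 * x) + sn2
    g_lik <- (1 / v - y2 / v^2) * exp(2 * x)
    g_prior <- Re(stats::fft(stats::fft(x) / lam, inverse = TRUE)) / n
    g_lik + g_prior
  }
  fit <- stats::optim(x0, nlp, grad, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 1e9))
  if (fit$convergence != 0 && fit$convergence != 1) {
    warning(sprintf(
      "PAD optimiser did not converge (code %d: %s); returning best iterate",
      fit$convergence, fit$message), call. = FALSE)
  }
  list(x = fit$par, value = fit$value, convergence = fit$convergence)
}

#' Probabilistic amplitude demodulation (MAP)
#'
#' Returns the positive modulator and carrier pair with the highest posterior
#' probability given the signal, under a squared-exponential GP prior on the
#' log-modulator and a unit-variance white Gaussian carrier.  The carrier is
#' recovered as `y / m`.
#'
#' Signals much longer than the prior timescale are processed in
#' 50%-overlapping windows of `window_factor * timescale` seconds (at least
#' 8192 samples when available), cross-faded linearly on the log-modulator.
#'
#' @param signal an [audio_signal] or numeric vector (z-scored).
#' @param params a [pad_params()].
#' @param fs sampling rate (Hz); taken from `signal` when it is an
#'   [audio_signal].
#' @param window_factor window length in units of the timescale.
#' @param max_iter L-BFGS iteration budget per window.
#' @return an object of class `pad_result` with fields `modulator` (positive),
#'   `carrier`, `log_posterior` (unnormalised, summed over windows), and
#'   `params`.
#' @export
pad_demodulate <- function(signal, params, fs = NULL, window_factor = 64,
                           max_iter = 300) {
  stopifnot(inherits(params, "pad_params"))
  if (inherits(signal, "audio_signal")) {
    y <- signal$samples
    fs <- signal$sample_rate
  } else {
    y <- signal
    if (is.null(fs)) stop("fs is required for a bare numeric signal", call. = FALSE)
  }
  n <- length(y)
  if (params$timescale >= n / fs / 4) {
    stop("timescale must be much shorter than the signal duration", call. = FALSE)
  }
  win <- max(round(window_factor * params$timescale * fs), min(n, 8192L))
  if (n <= 1.5 * win) {
    fit <- pad_map_window(y, fs, params, max_iter)
    x <- fit$x
    lp <- -fit$value
  } else {
    hop <- floor(win / 2)
    starts <- seq.int(1L, n - win + 1L, by = hop)
    if (starts[length(starts)] + win - 1L < n) starts <- c(starts, n - win + 1L)
    x <- numeric(n)
    wsum <- numeric(n)
    lp <- 0
    ramp <- pmin(seq_len(win), rev(seq_len(win)))   # triangular crossfade
    ramp <- ramp / max(ramp)
    for (s in starts) {
      idx <- seq.int(s, s + win - 1L)
      fit <- pad_map_window(y[idx], fs, params, max_iter)
      x[idx] <- x[idx] + ramp * fit$x
      wsum[idx] <- wsum[idx] + ramp
      lp <- lp - fit$value
    }
    x <- x / pmax(wsum, .Machine$double.eps)
  }
  m <- exp(x)
  structure(list(modulator = m, carrier = y / m, log_posterior = lp,
                 params = params, fs = fs),
            class = "pad_result")
}

#' @export
print.pad_result <- function(x, ...) {
  cat(sprintf(
    "<pad_result> %d samples @ %g Hz, timescale %g s, log-posterior %.1f\n",
    length(x$modulator), x$fs, x$params$timescale, x$log_posterior))
  invisible(x)
}

#' Default oscillatory band ranges for the PAD cascade
#'
#' Delta (0-4 Hz), theta (4-8), alpha (8-12), beta (12-30), gamma (30-50),
#' returned slowest-first.
#' @return named list of `c(lo, hi)` pairs in Hz.
#' @export
pad_band_ranges <- function() {
  list(delta = c(0, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 50))
}

# SE length-scale whose prior half-power point sits at frequency f:
# exp(-2 pi^2 ell^2 f^2) = 1/2  =>  ell = sqrt(log(2)/2) / (pi f).
timescale_for_cutoff <- function(f) sqrt(log(2) / 2) / (pi * f)

#' Recursive PAD cascade over oscillatory bands
#'
#' Runs PAD recursively, fastest band first: the first stage demodulates the
#' signal with a timescale whose prior cutoff matches the fastest band's
#' upper edge; each later stage demodulates the previous stage's modulator
#' with the next slower timescale.  The emitted modulator for each band is
#' the corresponding stage's modulator band-limited (zero phase) to that
#' band's range.
#'
#' The cascade operates at a reduced working rate (default 1000 Hz,
#' anti-aliased): every cascade cutoff is at or below 50 Hz, so nothing the
#' cascade can represent is lost, and exact GP inference stays tractable for
#' signals minutes long.
#'
#' @param signal an [audio_signal] (z-scored).
#' @param band_ranges named list of `c(lo, hi)` Hz pairs, slowest first
#'   (default [pad_band_ranges()]).
#' @param work_rate internal processing rate (Hz).
#' @param ... passed to [pad_demodulate()].
#' @return an object of class `pad_cascade`: `band_modulators` (named list of
#'   zero-phase band-limited modulator waveforms, one per band),
#'   `stage_modulators` (the positive modulator at each recursion stage),
#'   `band_ranges`, `env_rate`, and `core_modulators`/`core_ranges` — the
#'   four core phase-analysis tiers, with the top two bands merged into a
#'   single beta/gamma tier spanning both ranges.
#' @export
pad_cascade <- function(signal, band_ranges = pad_band_ranges(),
                        work_rate = 1000, ...) {
  stopifnot(inherits(signal, "audio_signal"))
  hi_edges <- vapply(band_ranges, `[`, 0, 2L)
  stopifnot(all(diff(hi_edges) > 0))      # slowest first
  x <- signal$samples
  fs <- signal$sample_rate
  if (fs > work_rate) {
    x <- fft_resample(fft_bandpass(x, fs, f_hi = 0.45 * work_rate), fs, work_rate)
    fs <- work_rate
  }
  x <- zscore(x)
  order_fast_first <- rev(seq_along(band_ranges))
  current <- x
  stage_mod <- vector("list", length(band_ranges))
  band_mod <- vector("list", length(band_ranges))
  names(stage_mod) <- names(band_mod) <- names(band_ranges)
  for (i in order_fast_first) {
    rng <- band_ranges[[i]]
    params <- pad_params(timescale = timescale_for_cutoff(rng[2]))
    res <- tryCatch(
      pad_demodulate(current, params, fs = fs, ...),
      error = function(e) {
        stop(sprintf("PAD cascade failed at stage '%s': %s",
                     names(band_ranges)[i], conditionMessage(e)), call. = FALSE)
      }
    )
    stage_mod[[i]] <- res$modulator
    m0 <- res$modulator - mean(res$modulator)
    band_mod[[i]] <- if (rng[1] > 0) {
      fft_bandpass(m0, fs, f_lo = rng[1], f_hi = rng[2])
    } else {
      fft_bandpass(m0, fs, f_hi = rng[2])
    }
    current <- res$modulator
  }
  # Four core modulators for phase analysis: the top two bands merged into a
  # single beta/gamma tier, band-limited from the first (fastest) stage's
  # modulator, which is the one whose content spans that merged range.
  nb <- length(band_ranges)
  if (nb >= 3) {
    core_mod <- band_mod[seq_len(nb - 2L)]
    core_rng <- band_ranges[seq_len(nb - 2L)]
    top_rng <- c(band_ranges[[nb - 1L]][1], band_ranges[[nb]][2])
    top_stage <- stage_mod[[nb]]
    merged_name <- paste0(names(band_ranges)[nb - 1L], "_",
                          names(band_ranges)[nb])
    core_mod[[merged_name]] <- fft_bandpass(top_stage - mean(top_stage), fs,
                                            f_lo = top_rng[1],
                                            f_hi = top_rng[2])
    core_rng[[merged_name]] <- top_rng
  } else {
    core_mod <- band_mod
    core_rng <- band_ranges
  }
  structure(list(band_modulators = band_mod, stage_modulators = stage_mod,
                 band_ranges = band_ranges, core_modulators = core_mod,
                 core_ranges = core_rng, env_rate = fs),
            class = "pad_cascade")
}

#' @export
print.pad_cascade <- function(x, ...) {
  cat(sprintf("<pad_cascade> bands: %s @ %g Hz\n",
              paste(names(x$band_modulators), collapse = ", "), x$env_rate))
  invisible(x)
}

#' Morlet scalogram of a modulator
#'
#' Continuous wavelet transform with an analytic Morlet wavelet (centre
#' frequency 6 rad/s), 16 voices per octave over `f_range`.  Magnitudes are
#' returned both raw and in dB normalised so the maximum is 0 dB.
#'
#' @param modulator numeric vector (a positive modulator or any envelope).
#' @param fs sampling rate (Hz).
#' @param f_range frequency range `c(lo, hi)` in Hz; `hi` must be below the
#'   Nyquist rate.
#' @param voices voices per octave.
#' @return object of class `cwt_scalogram`: `freq` (Hz), `magnitude`
#'   (freq x time), `db` (max = 0 dB).
#' @export
cwt_scalogram <- function(modulator, fs, f_range = c(0.1, 40), voices = 16) {
  stopifnot(all(is.finite(modulator)))
  if (f_range[2] >= fs / 2) {
    stop("upper frequency must be below the Nyquist rate", call. = FALSE)
  }
  n <- length(modulator)
  x <- modulator - mean(modulator)
  X <- stats::fft(x)
  w0 <- 6
  freqs <- 2^(seq(log2(f_range[1]), log2(f_range[2]), by = 1 / voices))
  omega <- 2 * pi * freq_grid(n, fs)
  mag <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    s <- w0 / (2 * pi * freqs[i])       # scale mapping for the Morlet wavelet
    psi <- sqrt(2) * pi^(-0.25) * exp(-0.5 * (s * omega - w0)^2)
    psi[omega < 0] <- 0                  # analytic wavelet
    W <- stats::fft(X * psi, inverse = TRUE) / n
    mag[i, ] <- Mod(W)
  }
  mx <- max(mag)
  db <- if (mx > 0) 20 * log10(pmax(mag, 1e-300) / mx) else mag
  structure(list(freq = freqs, magnitude = mag, db = db, fs = fs),
            class = "cwt_scalogram")
}

#' @export
print.cwt_scalogram <- function(x, ...) {
  cat(sprintf("<cwt_scalogram> %d frequencies (%.2g-%.3g Hz) x %d samples\n",
              length(x$freq), min(x$freq), max(x$freq), ncol(x$magnitude)))
  invisible(x)
}

#' Plot a scalogram as a heat map
#' @param x a `cwt_scalogram`.
#' @param ... passed to [graphics::image()].
#' @export
plot.cwt_scalogram <- function(x, ...) {
  t <- seq.int(0L, ncol(x$magnitude) - 1L) / x$fs
  graphics::image(t, log2(x$freq), t(x$db), ylab = "modulation rate (log2 Hz)",
                  xlab = "time (s)", ...)
  invisible(x)
}

#' Average several scalograms on a common [0, 1] scale
#'
#' Each map is normalised to `[0, 1]` by its own maximum, then the maps are
#' averaged pointwise (all maps must share dimensions).
#'
#' @param maps list of `cwt_scalogram` objects.
#' @return matrix (freq x time) of the averaged normalised magnitudes.
#' @export
scalogram_average <- function(maps) {
  stopifnot(length(maps) >= 1)
  norm <- lapply(maps, function(m) {
    mx <- max(m$magnitude)
    if (mx > 0) m$magnitude / mx else m$magnitude
  })
  Reduce(`+`, norm) / length(norm)
}

#' Spectral peaks of a modulator
#'
#' Welch power spectrum of the mean-removed modulator, then local maxima at
#' least `prominence_db` above the median spectrum level, sorted by
#' frequency.
#'
#' @param modulator numeric vector.
#' @param fs sampling rate (Hz).
#' @param prominence_db required height above the median spectrum level (dB).
#' @param n_segments Welch segment count (averaging reduces the variance of
#'   the spectrum estimate so noise fluctuations do not register as peaks).
#' @return numeric vector of peak frequencies in Hz (possibly empty).
#' @export
spectrum_peaks <- function(modulator, fs, prominence_db = 6, n_segments = 8) {
  if (all(modulator == 0)) return(numeric(0))
  ps <- welch_psd(modulator - mean(modulator), fs, n_segments = n_segments)
  p_db <- 10 * log10(pmax(ps$psd, 1e-300))
  floor_db <- stats::median(p_db[-1])
  idx <- find_peaks(p_db, min_distance = 2)
  idx <- idx[p_db[idx] >= floor_db + prominence_db]
  ps$freq[idx]
}
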