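# Low-level signal primitives shared by both demodulation front-ends.
#
# All band-limiting in this package is done in the frequency domain by applying
# the squared magnitude response of an order-4 Butterworth filter (the exact
# zero-phase response of that filter run forward and backward).  A recursive
# realization is avoided on purpose: the pipeline needs very narrow normalized
# bands (down to ~1e-3 of Nyquist) where transfer-function IIR coefficients are
# numerically fragile, and the phase statistics downstream cannot tolerate
# filter phase distortion or transients.

#' Z-score a numeric vector
#'
#' Centers to mean 0 and rescales to unit standard deviation (denominator `n`,
#' population convention, so repeated application is exactly idempotent).
#'
#' @param x numeric vector, not constant.
#' @return numeric vector with mean 0 and SD 1.
#' @keywords internal
zscore <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (!is.finite(s) || s <= 0) {
    stop("cannot z-score a constant (or non-finite) signal", call. = FALSE)
  }
  (x - mu) / s
}

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal of a real vector: positive frequencies
#' doubled, negative frequencies zeroed (DC and Nyquist kept).
#'
#' @param x real numeric vector.
#' @return complex vector, `Re()` equals `x` up to round-off.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert envelope (magnitude of the analytic signal)
#' @param x real numeric vector.
#' @return nonnegative numeric vector.
#' @keywords internal
hilbert_env <- function(x) Mod(analytic_signal(x))

# Squared Butterworth magnitude response on a frequency grid.
# order refers to the underlying one-pass filter; the squared response is what
# a forward-backward (zero-phase) application realizes.
butter_gain2 <- function(f, f_lo = NULL, f_hi = NULL, order = 4) {
  g <- rep(1, length(f))
  if (!is.null(f_hi)) g <- g / (1 + (f / f_hi)^(2 * order))
  if (!is.null(f_lo)) {
    r <- (f / f_lo)^(2 * order)
    g <- g * r / (1 + r)
  }
  g
}

#' Zero-phase band-pass filter
#'
#' Applies the squared magnitude response of an order-`order` Butterworth
#' band-pass (the exact forward-backward response) in the frequency domain.
#' The input is reflection-padded before the transform so that circular
#' wrap-around does not leak energy across the signal boundary.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param f_lo lower edge (Hz), or `NULL` for a low-pass.
#' @param f_hi upper edge (Hz), or `NULL` for a high-pass.
#' @param order one-pass Butterworth order (default 4).
#' @return filtered vector, same length as `x`, zero phase shift.
#' @keywords internal
fft_bandpass <- function(x, fs, f_lo = NULL, f_hi = NULL, order = 4) {
  stopifnot(!is.null(f_lo) || !is.null(f_hi))
  n <- length(x)
  f_ref <- if (!is.null(f_lo)) f_lo else f_hi
  pad <- min(n, ceiling(2 * fs / f_ref))
  np <- next_fast_len(n + 2L * pad)
  extra <- np - n - 2L * pad      # zeros beyond the right reflection, at
                                  # least `pad` samples away from the signal
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[seq.int(n - pad + 1L, n)]),
          numeric(extra))
  f <- freq_grid(np, fs)
  g <- butter_gain2(abs(f), f_lo = f_lo, f_hi = f_hi, order = order)
  y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE) / np)
  y[seq.int(pad + 1L, pad + n)]
}

# Smallest 5-smooth integer >= n (fast FFT length).
next_fast_len <- function(n) {
  if (n <= 6) return(as.integer(n))
  m <- n
  repeat {
    k <- m
    while (k %% 2 == 0) k <- k / 2
    while (k %% 3 == 0) k <- k / 3
    while (k %% 5 == 0) k <- k / 5
    if (k == 1) return(as.integer(m))
    m <- m + 1
  }
}

# Two-sided DFT frequency grid in Hz (matching R's fft bin order).
freq_grid <- function(n, fs) {
  k <- c(seq.int(0L, floor(n / 2)), seq.int(-ceiling(n / 2) + 1L, -1L))
  k * fs / n
}

#' Resample a slowly varying signal to a lower rate
#'
#' Frequency-domain resampling: the spectrum is truncated at the new Nyquist
#' frequency (an ideal anti-alias low-pass) and inverted on the coarser grid.
#' Intended for nonnegative envelopes whose content lies far below the target
#' Nyquist; requires `duration * out_rate` to be a whole number of samples.
#'
#' @param x numeric vector at rate `fs`.
#' @param fs input sampling rate (Hz).
#' @param out_rate output sampling rate (Hz), `out_rate <= fs`.
#' @return numeric vector of length `length(x) * out_rate / fs`.
#' @keywords internal
fft_resample <- function(x, fs, out_rate) {
  n <- length(x)
  if (out_rate == fs) return(x)
  stopifnot(out_rate < fs)
  m <- n * out_rate / fs
  if (abs(m - round(m)) > 1e-6) {
    stop("duration * out_rate must be an integer number of samples", call. = FALSE)
  }
  m <- as.integer(round(m))
  X <- stats::fft(x)
  keep_pos <- floor(m / 2)           # positive bins kept (excluding DC)
  Y <- complex(m)
  Y[1] <- X[1]
  if (keep_pos >= 1) {
    idx <- seq_len(keep_pos)
    Y[1 + idx] <- X[1 + idx]
    Y[m + 1 - idx] <- X[n + 1 - idx]
    if (m %% 2 == 0) Y[m / 2 + 1] <- Re(X[m / 2 + 1])  # shared Nyquist bin
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Unwrap a phase sequence
#' @param p phase angles (radians).
#' @return unwrapped phases (cumulative, no 2*pi jumps).
#' @keywords internal
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

# Wrap angles into [-pi, pi).
wrap_phase <- function(p) {
  ((p + pi) %% (2 * pi)) - pi
}

#' Strict local maxima with minimum-separation pruning
#'
#' A sample is a peak when it strictly exceeds its neighbours; a flat plateau
#' that strictly exceeds both flanks counts once, at its midpoint.  When two
#' retained peaks would be closer than `min_distance` (in samples/channels),
#' the smaller is discarded, largest-first.
#'
#' @param v numeric vector.
#' @param min_distance minimum index separation between retained peaks.
#' @return integer vector of peak indices (sorted increasing).
#' @keywords internal
find_peaks <- function(v, min_distance = 1) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L  # plateau
      if (j < n && v[j + 1L] < v[i]) {
        cand <- c(cand, as.integer(floor((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(cand) == 0 || min_distance <= 1) return(cand)
  keep <- logical(length(cand))
  ord <- order(v[cand], decreasing = TRUE)
  taken <- integer(0)
  for (k in ord) {
    if (all(abs(cand[k] - taken) >= min_distance)) {
      keep[k] <- TRUE
      taken <- c(taken, cand[k])
    }
  }
  sort(cand[keep])
}

# Local minima (same semantics, applied to the negated vector).
find_troughs <- function(v, min_distance = 1) {
  find_peaks(-v, min_distance = min_distance)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram (Hann window, 50% overlap).  Used wherever a
#' smooth spectrum estimate is needed for peak picking.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param n_segments nominal number of 50%-overlapping segments.
#' @return list with `freq` (Hz) and `psd` (power per Hz, one-sided).
#' @keywords internal
welch_psd <- function(x, fs, n_segments = 8) {
  n <- length(x)
  seg <- max(16L, 2L * floor(n / (n_segments + 1)))
  seg <- min(seg, n)
  hop <- max(1L, floor(seg / 2))
  w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, seg - 1L) / (seg - 1L))
  starts <- seq.int(1L, n - seg + 1L, by = hop)
  nb <- floor(seg / 2) + 1L
  acc <- numeric(nb)
  for (s in starts) {
    xs <- x[seq.int(s, s + seg - 1L)]
    xs <- (xs - mean(xs)) * w
    P <- Mod(stats::fft(xs))^2 / (fs * sum(w^2))
    half <- P[seq_len(nb)]
    if (seg %% 2 == 0) half[2:(nb - 1L)] <- 2 * half[2:(nb - 1L)]
    else half[2:nb] <- 2 * half[2:nb]
    acc <- acc + half
  }
  list(freq = seq.int(0L, nb - 1L) * fs / seg, psd = acc / length(starts))
}

# Frequency (Hz) of the largest magnitude-spectrum bin at or above f_min.
spectral_argmax <- function(x, fs, f_min = 0) {
  n <- length(x)
  X <- Mod(stats::fft(x - mean(x)))[seq_len(floor(n / 2) + 1L)]
  f <- seq.int(0L, floor(n / 2)) * fs / n
  ok <- f >= f_min
  f[ok][which.max(X[ok])]
}

# Evaluate a function under a temporary RNG state; restores the caller's seed.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic substream seeds derived from one master seed.
substream_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
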