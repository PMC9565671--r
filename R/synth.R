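# Synthetic stimulus generators.  Every input the analysis pipeline needs can
# be produced here with full seed control and exact ground truth, so each
# downstream stage is testable against construction.

#' Audio signal container
#'
#' A mono PCM signal held in memory: samples, sampling rate, and free-form
#' provenance metadata.
#'
#' @param samples numeric vector (mono) or matrix (channels in columns; kept
#'   as-is, averaged to mono by [normalize()]).
#' @param sample_rate sampling rate in Hz.
#' @param meta named list of provenance metadata.
#' @return an object of class `audio_signal`.
#' @export
audio_signal <- function(samples, sample_rate, meta = list()) {
  stopifnot(is.numeric(samples), length(samples) > 0,
            is.numeric(sample_rate), sample_rate > 0)
  structure(list(samples = samples, sample_rate = sample_rate, meta = meta),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  n <- if (is.matrix(x$samples)) nrow(x$samples) else length(x$samples)
  ch <- if (is.matrix(x$samples)) ncol(x$samples) else 1L
  cat(sprintf("<audio_signal> %d samples (%.3f s) @ %g Hz, %d channel(s)\n",
              n, n / x$sample_rate, x$sample_rate, ch))
  invisible(x)
}

#' Specification of a compound amplitude-modulated tone
#'
#' Describes a sinusoidal carrier multiplied by a sum of sinusoidal
#' modulators.  The default configuration (modulators at 2, 4, 8 and 16 Hz
#' with equal unit weights and zero phase, carrier at 200 Hz, 30 s at
#' 44.1 kHz, no additive offset) is the rhythmic-but-non-musical reference
#' stimulus used by [run_simulation_experiment()]: a sound carrying delta,
#' theta, alpha and beta/gamma rhythm at power-of-two rates over a vocal-pitch
#' carrier.
#'
#' With `offset = 0` the summed modulator is signed, so the audible envelope
#' is its absolute value; tests that need the modulator itself to be a
#' positive envelope should set `offset >= sum(abs(mod_weights))`.
#'
#' @param mod_freqs modulator frequencies (Hz); may be empty.
#' @param carrier_freq carrier frequency (Hz), must exceed every modulator
#'   frequency.
#' @param duration duration in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param mod_phases modulator phases (radians), recycled default 0.
#' @param mod_weights modulator amplitudes, recycled default 1.
#' @param offset additive constant applied to the summed modulator.
#' @param seed optional integer seed recorded in the spec (the tone itself is
#'   deterministic).
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(mod_freqs = c(2, 4, 8, 16), carrier_freq = 200,
                       duration = 30, sample_rate = 44100,
                       mod_phases = NULL, mod_weights = NULL,
                       offset = 0, seed = NULL) {
  k <- length(mod_freqs)
  if (is.null(mod_phases)) mod_phases <- rep(0, k)
  if (is.null(mod_weights)) mod_weights <- rep(1, k)
  if (length(mod_phases) != k || length(mod_weights) != k) {
    stop("mod_freqs, mod_phases and mod_weights must have equal length",
         call. = FALSE)
  }
  nyq <- sample_rate / 2
  if (any(c(mod_freqs, carrier_freq) <= 0) ||
      any(c(mod_freqs, carrier_freq) >= nyq)) {
    stop("all frequencies must lie in (0, sample_rate/2)", call. = FALSE)
  }
  if (k > 0 && any(mod_freqs >= carrier_freq)) {
    stop("modulator frequencies must be below the carrier frequency",
         call. = FALSE)
  }
  stopifnot(duration > 0)
  structure(list(mod_freqs = mod_freqs, mod_phases = mod_phases,
                 mod_weights = mod_weights, carrier_freq = carrier_freq,
                 duration = duration, sample_rate = sample_rate,
                 offset = offset, seed = seed),
            class = "synth_spec")
}

time_axis <- function(duration, sample_rate) {
  n <- round(duration * sample_rate)
  seq.int(0L, n - 1L) / sample_rate
}

#' Ground truth attached to a synthetic signal
#'
#' Records the per-band modulators, the carrier, and how they combine
#' (`"sum"` of modulators or `"product"` of nested modulators), so parameter
#' recovery can be asserted exactly.  [gt_reconstruct()] rebuilds the emitted
#' samples from these parts.
#'
#' @name ground_truth
#' @keywords internal
NULL

new_ground_truth <- function(true_modulators, carrier, combine, sample_rate,
                             offset = 0, parent_daughter_ratio = NULL,
                             parent_phase_offset = NULL) {
  structure(list(true_modulators = true_modulators, carrier = carrier,
                 combine = combine, sample_rate = sample_rate, offset = offset,
                 parent_daughter_ratio = parent_daughter_ratio,
                 parent_phase_offset = parent_phase_offset),
            class = "ground_truth")
}

#' Rebuild a synthetic signal from its ground truth
#'
#' @param gt a `ground_truth` object.
#' @return z-scored numeric vector equal (to within 1e-9) to the samples of
#'   the signal the ground truth was emitted with.
#' @export
gt_reconstruct <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  mods <- gt$true_modulators
  m <- switch(gt$combine,
    sum = gt$offset + Reduce(`+`, mods, accumulate = FALSE),
    product = Reduce(`*`, mods),
    stop("unknown combine mode", call. = FALSE)
  )
  zscore(m * gt$carrier)
}

#' Compound amplitude-modulated tone
#'
#' Emits `z-score((offset + sum_k w_k sin(2 pi f_k t + phi_k)) * sin(2 pi f_c t))`
#' together with ground truth carrying each sinusoidal modulator separately.
#' With the default `synth_spec()` this is a carrier at 200 Hz whose magnitude
#' spectrum has components only at `carrier +/- {2, 4, 8, 16}` Hz.
#'
#' @param spec a [synth_spec()].
#' @return list with elements `signal` ([audio_signal]) and `ground_truth`.
#' @export
#' @examples
#' tone <- make_compound_tone(synth_spec(duration = 2, sample_rate = 8000))
#' tone$signal
make_compound_tone <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  t <- time_axis(spec$duration, spec$sample_rate)
  k <- length(spec$mod_freqs)
  mods <- lapply(seq_len(k), function(i) {
    spec$mod_weights[i] * sin(2 * pi * spec$mod_freqs[i] * t + spec$mod_phases[i])
  })
  names(mods) <- if (k > 0) sprintf("mod_%gHz", spec$mod_freqs) else character(0)
  modulator <- spec$offset + if (k > 0) Reduce(`+`, mods) else 0
  carrier <- sin(2 * pi * spec$carrier_freq * t)
  samples <- zscore(modulator * carrier)
  sig <- audio_signal(samples, spec$sample_rate,
                      meta = list(kind = "compound_tone", spec = spec))
  gt <- new_ground_truth(mods, carrier, combine = "sum",
                         sample_rate = spec$sample_rate, offset = spec$offset)
  list(signal = sig, ground_truth = gt)
}

#' Hierarchically nested amplitude-modulation stimulus
#'
#' Builds a strictly positive nested modulator as a product of raised cosines:
#' a parent band at `parent_freq` and, for each integer ratio `(a, b)`, a
#' daughter band completing `b` cycles per `a` parent cycles at the stated
#' phase offset.  Each offset shifts the phase of the slower (parent) tier of
#' its parent-daughter pair; shifting the parent of a 1:2 pair by pi swaps
#' which of the two daughter beats inside the parent cycle is the strong one
#' — the acoustic analogue of turning a strong-weak (trochaic) pattern into
#' a weak-strong (iambic) one.  (For a 1:2 pair a daughter-side shift of pi
#' is a whole daughter cycle and would change nothing, which is why the
#' convention shifts the slower band.)
#'
#' @param parent_freq parent AM frequency (Hz).
#' @param ratios list of integer pairs `c(a, b)` with `a < b`, coprime; each
#'   is applied to the previous tier's frequency, so
#'   `list(c(1, 2), c(1, 2))` with a 2 Hz parent yields bands at 2, 4, 8 Hz.
#' @param phase_offsets radians, one per ratio: entry `i` shifts the phase
#'   of tier `i` (the parent of the i-th parent-daughter pair); the fastest
#'   tier is never shifted.  Default all 0.
#' @param carrier either a carrier frequency in Hz (sine) or `"noise"` for a
#'   seeded white Gaussian carrier.
#' @param duration seconds.
#' @param sample_rate Hz.
#' @param seed integer seed (used only for a noise carrier).
#' @param mod_depth depth of each raised-cosine tier in (0, 1]; the default
#'   0.9 keeps the product strictly positive.
#' @return list with `signal` and `ground_truth`; the ground truth carries one
#'   raised-cosine modulator per tier (combine mode `"product"`).
#' @export
make_am_hierarchy <- function(parent_freq, ratios = list(c(1, 2)),
                              phase_offsets = NULL, carrier = "noise",
                              duration = 10, sample_rate = 1000,
                              seed = 1, mod_depth = 0.9) {
  stopifnot(parent_freq > 0, mod_depth > 0, mod_depth <= 1)
  if (is.null(phase_offsets)) phase_offsets <- rep(0, length(ratios))
  stopifnot(length(phase_offsets) == length(ratios))
  for (r in ratios) {
    if (length(r) != 2 || r[1] >= r[2] || r[1] < 1 ||
        r[1] != round(r[1]) || r[2] != round(r[2])) {
      stop("each ratio must be an integer pair (a, b) with a < b", call. = FALSE)
    }
    if (coprime_gcd(r[1], r[2]) != 1) {
      stop("ratio pairs must be coprime", call. = FALSE)
    }
  }
  t <- time_axis(duration, sample_rate)
  freqs <- parent_freq
  for (r in ratios) freqs <- c(freqs, freqs[length(freqs)] * r[2] / r[1])
  offs <- c(phase_offsets, 0)     # offset i belongs to the slower tier i
  mods <- lapply(seq_along(freqs), function(i) {
    1 + mod_depth * cos(2 * pi * freqs[i] * t + offs[i])
  })
  names(mods) <- sprintf("band_%gHz", freqs)
  modulator <- Reduce(`*`, mods)
  if (identical(carrier, "noise")) {
    c_t <- with_seed(seed, stats::rnorm(length(t)))
  } else {
    stopifnot(is.numeric(carrier), carrier > 0, carrier < sample_rate / 2)
    c_t <- sin(2 * pi * carrier * t)
  }
  samples <- zscore(modulator * c_t)
  sig <- audio_signal(samples, sample_rate,
                      meta = list(kind = "am_hierarchy", parent_freq = parent_freq,
                                  ratios = ratios, phase_offsets = phase_offsets,
                                  band_freqs = freqs, seed = seed))
  gt <- new_ground_truth(mods, c_t, combine = "product",
                         sample_rate = sample_rate,
                         parent_daughter_ratio = ratios,
                         parent_phase_offset = phase_offsets)
  list(signal = sig, ground_truth = gt)
}

coprime_gcd <- function(a, b) {
  while (b != 0) { tmp <- b; b <- a %% b; a <- tmp }
  a
}

#' Independent-band control stimulus
#'
#' Emits a signal whose per-band envelopes are mutually independent by
#' construction: each band's envelope is narrow-band Gaussian noise centred on
#' the requested rate, generated from its own RNG substream, offset to stay
#' positive, and summed.  This is the unstructured counterpart to
#' [make_am_hierarchy()] — a surrogate for quasi-rhythmic environmental sound
#' with no cross-band phase dependency.
#'
#' @param band_freqs centre rates (Hz) of at least two envelope bands.
#' @param duration seconds.
#' @param sample_rate Hz.
#' @param seed master seed; each band (and the carrier) uses an independent
#'   substream derived from it.
#' @param rel_bw relative bandwidth of each envelope band (default 1/3).
#' @return list with `signal` and `ground_truth` (combine mode `"sum"`,
#'   one positive envelope per band).
#' @export
make_independent_bands <- function(band_freqs, duration = 10,
                                   sample_rate = 1000, seed = 1,
                                   rel_bw = 1 / 3) {
  if (length(band_freqs) < 2) {
    stop("at least two bands are required", call. = FALSE)
  }
  stopifnot(all(band_freqs > 0), all(band_freqs < sample_rate / 2))
  t <- time_axis(duration, sample_rate)
  n <- length(t)
  seeds <- substream_seeds(seed, length(band_freqs) + 1L)
  mods <- lapply(seq_along(band_freqs), function(i) {
    f <- band_freqs[i]
    raw <- with_seed(seeds[i], stats::rnorm(n))
    nb <- fft_bandpass(raw, sample_rate,
                       f_lo = f * (1 - rel_bw / 2), f_hi = f * (1 + rel_bw / 2))
    s <- stats::sd(nb)
    if (s > 0) nb <- nb / s
    1 + 0.3 * pmax(pmin(nb, 3), -3)   # clipped at 3 SD: strictly positive
  })
  names(mods) <- sprintf("band_%gHz", band_freqs)
  modulator <- Reduce(`+`, mods)
  c_t <- with_seed(seeds[length(seeds)], stats::rnorm(n))
  samples <- zscore(modulator * c_t)
  sig <- audio_signal(samples, sample_rate,
                      meta = list(kind = "independent_bands",
                                  band_freqs = band_freqs, seed = seed))
  gt <- new_ground_truth(mods, c_t, combine = "sum", sample_rate = sample_rate)
  list(signal = sig, ground_truth = gt)
}
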