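# Second analysis stage: a modulation-rate filterbank applied to each
# spectral-band envelope, PCA over modulation channels, and extraction of the
# four core AM-band envelopes.

#' Design a log-spaced modulation-rate filterbank
#'
#' Channel centres are purely geometrically (log) spaced — ERB formulas are
#' undefined at modulation rates — spanning 0.9-40 Hz by default, the range
#' containing the AM rates that carry rhythm.  Edges sit at the geometric
#' midpoints between adjacent centres, half a log-step beyond at the ends.
#'
#' @param n_channels number of channels (default 24).
#' @param f_lo lowest centre rate (Hz).
#' @param f_hi highest centre rate (Hz).
#' @return a `filterbank_spec` with `spacing = "log"`.
#' @export
design_mod_filterbank <- function(n_channels = 24, f_lo = 0.9, f_hi = 40) {
  if (n_channels < 2) stop("n_channels must be at least 2", call. = FALSE)
  stopifnot(f_lo > 0, f_hi > f_lo)
  lg <- seq(log(f_lo), log(f_hi), length.out = n_channels)
  step <- lg[2] - lg[1]
  lg_edges <- c(lg[1] - step / 2, (lg[-1] + lg[-n_channels]) / 2,
                lg[n_channels] + step / 2)
  new_filterbank_spec(exp(lg), exp(lg_edges), spacing = "log",
                      f_lo = f_lo, f_hi = f_hi)
}

#' Named AM bands and their edge frequencies
#'
#' The four core amplitude-modulation bands used throughout the package, with
#' edges at 0.9, 2.5, 7, 17 and 30 Hz.  Each band is annotated with the
#' musical unit whose typical event rate falls inside it: delta ~ crotchets
#' (quarter notes), theta ~ quavers, alpha ~ demiquavers, beta/gamma ~ note
#' onsets.  Note one known wrinkle: a 16 Hz modulator is often described as a
#' "gamma" timescale in the oscillations literature, yet under these edges it
#' falls in the alpha band's upper neighbourhood (7-17 Hz); band assignment
#' here always follows the edge table, not the colloquial label.
#'
#' @param edge_freqs strictly increasing band edges (Hz), one more than the
#'   number of bands.
#' @param names band names.
#' @param unit_labels musical-unit annotation per band.
#' @return an object of class `am_band_spec`.
#' @export
am_band_spec <- function(edge_freqs = c(0.9, 2.5, 7, 17, 30),
                         names = c("delta", "theta", "alpha", "beta_gamma"),
                         unit_labels = c("crotchet", "quaver", "demiquaver",
                                         "onset")) {
  stopifnot(all(diff(edge_freqs) > 0),
            length(edge_freqs) == length(names) + 1L,
            length(unit_labels) == length(names))
  structure(list(names = names, edge_freqs = edge_freqs,
                 unit_labels = unit_labels),
            class = "am_band_spec")
}

# Modulation-rate decomposition of one envelope: band-pass at each channel's
# edges, then the Hilbert envelope of each modulation channel.
mod_decompose <- function(envelope, env_rate, fb = design_mod_filterbank()) {
  stopifnot(is.numeric(envelope), inherits(fb, "filterbank_spec"))
  out <- matrix(0, nrow = fb$n_channels, ncol = length(envelope))
  x <- envelope - mean(envelope)
  for (k in seq_len(fb$n_channels)) {
    lo <- fb$channel_edges[k]
    hi <- min(fb$channel_edges[k + 1L], 0.999 * env_rate / 2)
    out[k, ] <- hilbert_env(fft_bandpass(x, env_rate, f_lo = lo, f_hi = hi))
  }
  channel_envelope_matrix(out, env_rate, fb$channel_centers)
}

#' Temporal PCA over modulation-rate channels
#'
#' Each spectral-band envelope is decomposed by the modulation-rate
#' filterbank; the Hilbert envelopes of the 24 modulation channels enter a
#' correlation-matrix PCA (channels as variables).  Absolute loadings of the
#' top `n_keep` components are averaged across the supplied spectral bands
#' (band-by-band analysis, then averaging), and core AM bands are detected
#' with the temporal criteria: minimum peak separation of 5 channels, one
#' supporting component suffices.
#'
#' @param band_envelopes a numeric vector (one spectral band's envelope), a
#'   list of such vectors, or a matrix with bands in rows.
#' @param env_rate envelope sampling rate (Hz).
#' @param fb modulation filterbank (default [design_mod_filterbank()]).
#' @param n_keep components retained (default 3).
#' @param min_peak_distance channel separation for peak picking (default 5).
#' @param min_pc_count supporting components required per band (default 1).
#' @return list with elements `loadings` ([pca_loadings], grand average) and
#'   `bands` ([band_solution]).
#' @export
temporal_pca <- function(band_envelopes, env_rate,
                         fb = design_mod_filterbank(), n_keep = 3,
                         min_peak_distance = 5, min_pc_count = 1) {
  if (is.numeric(band_envelopes) && !is.matrix(band_envelopes)) {
    band_envelopes <- list(band_envelopes)
  }
  if (is.matrix(band_envelopes)) {
    band_envelopes <- lapply(seq_len(nrow(band_envelopes)),
                             function(i) band_envelopes[i, ])
  }
  min_len <- 10 * env_rate / fb$f_lo
  for (e in band_envelopes) {
    if (length(e) < min_len) {
      stop(sprintf(paste0("envelope too short: need at least 10 cycles of the",
                          " slowest rate (%.0f samples at %g Hz)"),
                   min_len, env_rate), call. = FALSE)
    }
  }
  items <- lapply(band_envelopes, mod_decompose, env_rate = env_rate, fb = fb)
  loadings <- spectral_pca(items, n_keep = n_keep)
  bands <- detect_bands(loadings, min_peak_distance = min_peak_distance,
                        min_pc_count = min_pc_count)
  list(loadings = loadings, bands = bands)
}

#' Band-limited envelopes of each detected spectral band
#'
#' Re-filters the raw signal into the detected core spectral bands (each band
#' spanning from one boundary edge to the next, with the filterbank limits at
#' the outer ends), and returns the Hilbert envelope of each band resampled
#' to `env_rate`.
#'
#' @param signal an [audio_signal].
#' @param solution a spectral [band_solution] with at least one band.
#' @param fb_spec the `filterbank_spec` the solution was derived under (its
#'   outer edges bound the first and last band).
#' @param env_rate envelope output rate (Hz).
#' @return a [channel_envelope_matrix] with one row per spectral band.
#' @export
spectral_band_envelopes <- function(signal, solution,
                                    fb_spec = design_erb_filterbank(),
                                    env_rate = 1000) {
  stopifnot(inherits(signal, "audio_signal"), inherits(solution, "band_solution"))
  nb <- length(solution$band_peak_channels)
  if (nb < 1) stop("band solution has no bands", call. = FALSE)
  lims <- c(min(fb_spec$channel_edges), solution$band_edge_freqs,
            max(fb_spec$channel_edges))
  x <- signal$samples
  fs <- signal$sample_rate
  m <- as.integer(round(length(x) * env_rate / fs))
  env <- matrix(0, nrow = nb, ncol = m)
  for (b in seq_len(nb)) {
    band <- fft_bandpass(x, fs, f_lo = lims[b],
                         f_hi = min(lims[b + 1L], 0.999 * fs / 2),
                         order = fb_spec$filter_order)
    env[b, ] <- pmax(fft_resample(hilbert_env(band), fs, env_rate), 0)
  }
  channel_envelope_matrix(env, env_rate, solution$band_center_freqs)
}

#' Grid of AM-band envelopes (spectral band x AM band)
#'
#' Band-pass filters each spectral-band envelope at the edges of each named
#' AM band, yielding the band-limited (zero-mean) modulation waveforms whose
#' phases feed the coupling statistics.  For the default five spectral and
#' four AM bands this is the 4 x 5 envelope grid.
#'
#' @param band_envelopes a [channel_envelope_matrix] of spectral-band
#'   envelopes (one row per spectral band), e.g. from
#'   [spectral_band_envelopes()].
#' @param am_spec an [am_band_spec()].
#' @return an object of class `am_envelope_grid`: 3-d array
#'   `[spectral_band, am_band, time]` plus rates and names.
#' @export
extract_am_grid <- function(band_envelopes, am_spec = am_band_spec()) {
  stopifnot(inherits(band_envelopes, "channel_envelope_matrix"),
            inherits(am_spec, "am_band_spec"))
  env_rate <- band_envelopes$env_rate
  if (max(am_spec$edge_freqs) >= env_rate / 2) {
    stop("AM band edge at or above the envelope Nyquist rate", call. = FALSE)
  }
  E <- band_envelopes$envelopes
  ns <- nrow(E); na <- length(am_spec$names); nt <- ncol(E)
  grid <- array(0, dim = c(ns, na, nt),
                dimnames = list(spectral_band = NULL, am_band = am_spec$names,
                                time = NULL))
  for (s in seq_len(ns)) {
    x <- E[s, ] - mean(E[s, ])
    for (a in seq_len(na)) {
      grid[s, a, ] <- fft_bandpass(x, env_rate,
                                   f_lo = am_spec$edge_freqs[a],
                                   f_hi = am_spec$edge_freqs[a + 1L])
    }
  }
  structure(list(envelopes = grid, env_rate = env_rate,
                 am_spec = am_spec,
                 spectral_centers = band_envelopes$channel_centers),
            class = "am_envelope_grid")
}

#' @export
print.am_envelope_grid <- function(x, ...) {
  d <- dim(x$envelopes)
  cat(sprintf("<am_envelope_grid> %d spectral x %d AM bands x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$env_rate))
  invisible(x)
}
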