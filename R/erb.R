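# Cochlear-style spectral front-end: log-ERB filterbank, Hilbert envelopes,
# and PCA-based discovery of co-modulated spectral bands.

#' ERB-number scale
#'
#' Converts frequency in Hz to the ERB-number scale
#' `ERBn(f) = 21.4 * log10(4.37 * f / 1000 + 1)` (and back).  Uniform spacing
#' on this scale mimics the frequency resolution of the normal human cochlea.
#'
#' @param f frequency in Hz.
#' @return ERB number (dimensionless).
#' @export
erb_number <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)

#' @rdname erb_number
#' @param e ERB number.
#' @export
erb_number_inv <- function(e) (10^(e / 21.4) - 1) / 4.37 * 1000

new_filterbank_spec <- function(centers, edges, spacing, f_lo, f_hi,
                                filter_order = 4) {
  stopifnot(all(diff(centers) > 0), length(edges) == length(centers) + 1L)
  structure(list(n_channels = length(centers), f_lo = f_lo, f_hi = f_hi,
                 spacing = spacing, channel_centers = centers,
                 channel_edges = edges, filter_order = filter_order),
            class = "filterbank_spec")
}

#' @export
print.filterbank_spec <- function(x, ...) {
  cat(sprintf("<filterbank_spec> %d channels, %s-spaced, %g-%g Hz\n",
              x$n_channels, x$spacing, x$f_lo, x$f_hi))
  invisible(x)
}

#' Design a cochlear (ERB-spaced) band-pass filterbank
#'
#' Channel centre frequencies are uniformly spaced on the ERB-number scale
#' between `f_lo` and `f_hi` (both included); channel edges sit at the
#' ERB-scale midpoints between adjacent centres, with the outer edges half a
#' step beyond the end centres.  The default 28 channels spanning 100-7250 Hz
#' cover the spectral range relevant to speech and most musical instruments.
#'
#' Channel responses are steep (order-16 Butterworth magnitude, applied with
#' zero phase): at ~1 ERB channel spacing, near-rectangular edges are needed
#' for a tone to excite essentially one channel, as it does in the cochlea;
#' shallow edges would smear every component across neighbouring channels
#' and blur the co-modulation structure the PCA stage looks for.
#'
#' @param n_channels number of channels (>= 2).
#' @param f_lo lowest centre frequency (Hz, >= 20).
#' @param f_hi highest centre frequency (Hz).
#' @param filter_order Butterworth magnitude order of the channel edges.
#' @return a `filterbank_spec`.
#' @export
design_erb_filterbank <- function(n_channels = 28, f_lo = 100, f_hi = 7250,
                                  filter_order = 16) {
  if (n_channels < 2) stop("n_channels must be at least 2", call. = FALSE)
  stopifnot(f_lo >= 20, f_hi > f_lo)
  e <- seq(erb_number(f_lo), erb_number(f_hi), length.out = n_channels)
  step <- e[2] - e[1]
  e_edges <- c(e[1] - step / 2, (e[-1] + e[-n_channels]) / 2,
               e[n_channels] + step / 2)
  new_filterbank_spec(erb_number_inv(e), pmax(erb_number_inv(e_edges), 1e-3),
                      spacing = "erb-log", f_lo = f_lo, f_hi = f_hi,
                      filter_order = filter_order)
}

#' Channel-envelope matrix
#'
#' Per-channel nonnegative Hilbert envelopes from a filterbank decomposition,
#' stored channels x time at the (decimated) envelope rate.
#'
#' @param envelopes numeric matrix, channels in rows, all values >= 0.
#' @param env_rate envelope sampling rate (Hz).
#' @param channel_centers channel centre frequencies (Hz).
#' @return an object of class `channel_envelope_matrix`.
#' @export
channel_envelope_matrix <- function(envelopes, env_rate, channel_centers) {
  stopifnot(is.matrix(envelopes), nrow(envelopes) == length(channel_centers),
            all(envelopes >= 0), env_rate > 0)
  structure(list(envelopes = envelopes, env_rate = env_rate,
                 channel_centers = channel_centers),
            class = "channel_envelope_matrix")
}

#' @export
print.channel_envelope_matrix <- function(x, ...) {
  cat(sprintf("<channel_envelope_matrix> %d channels x %d samples @ %g Hz\n",
              nrow(x$envelopes), ncol(x$envelopes), x$env_rate))
  invisible(x)
}

#' Decompose a signal into per-channel Hilbert envelopes
#'
#' Passes the signal through the filterbank (zero-phase band-pass per
#' channel), takes the magnitude of the analytic signal in each channel, and
#' resamples each envelope to `env_rate` with an ideal anti-alias low-pass.
#' Negative round-off residue after resampling is clipped at zero.
#'
#' @param signal an [audio_signal] (z-scored; see [normalize()]).
#' @param spec a `filterbank_spec` from [design_erb_filterbank()].
#' @param env_rate envelope output rate (Hz); 1000 Hz retains modulation
#'   content far above the 0.9-40 Hz range analysed downstream.
#' @return a [channel_envelope_matrix].
#' @export
decompose <- function(signal, spec, env_rate = 1000) {
  stopifnot(inherits(signal, "audio_signal"), inherits(spec, "filterbank_spec"))
  x <- signal$samples
  fs <- signal$sample_rate
  n <- length(x)
  min_bw <- min(diff(spec$channel_edges))
  if (n < 4 * fs / min_bw) {
    stop("signal too short for the narrowest filter (edge-dominated)",
         call. = FALSE)
  }
  if (env_rate > fs) stop("env_rate cannot exceed the sample rate", call. = FALSE)
  m <- n * env_rate / fs
  if (abs(m - round(m)) > 1e-6) {
    stop("signal duration must be an integer number of envelope samples",
         call. = FALSE)
  }
  env <- matrix(0, nrow = spec$n_channels, ncol = as.integer(round(m)))
  for (k in seq_len(spec$n_channels)) {
    lo <- spec$channel_edges[k]
    hi <- min(spec$channel_edges[k + 1L], 0.999 * fs / 2)
    band <- fft_bandpass(x, fs, f_lo = lo, f_hi = hi,
                         order = spec$filter_order)
    e <- hilbert_env(band)
    env[k, ] <- pmax(fft_resample(e, fs, env_rate), 0)
  }
  channel_envelope_matrix(env, env_rate, spec$channel_centers)
}

#' PCA loadings over filterbank channels
#'
#' Absolute principal-component loadings (components x channels) together
#' with the per-component explained-variance ratio.  Absolute values are used
#' so that averaging across items cannot cancel loadings of opposite sign.
#'
#' @param loadings matrix, components in rows, channels in columns, >= 0.
#' @param explained_variance_ratio numeric vector in `[0, 1]`, non-increasing.
#' @param channel_centers channel centre frequencies (Hz).
#' @return an object of class `pca_loadings`.
#' @export
pca_loadings <- function(loadings, explained_variance_ratio, channel_centers) {
  stopifnot(is.matrix(loadings), all(loadings >= 0),
            length(channel_centers) == ncol(loadings),
            all(explained_variance_ratio >= -1e-12),
            all(explained_variance_ratio <= 1 + 1e-12),
            all(diff(explained_variance_ratio) <= 1e-12))
  structure(list(loadings = loadings,
                 explained_variance_ratio = explained_variance_ratio,
                 n_components_kept = nrow(loadings),
                 channel_centers = channel_centers),
            class = "pca_loadings")
}

# Covariance-matrix PCA of one envelope matrix (observations = time samples,
# variables = channels), with variance-scaled loadings: |eigenvector| *
# component SD.  The scaling matters twice over.  Channel envelopes span
# orders of magnitude (filter-skirt leakage in off-band channels); a
# correlation PCA would z-score that residue up to unit variance and let it
# masquerade as structure.  And eigenvectors of near-zero eigenvalues are
# still unit norm, so unscaled loadings of negligible components would carry
# full-size spurious peaks; scaling by the component SD shrinks them to the
# noise level where the peak floor in detect_bands() ignores them.
pca_one_item <- function(env, n_keep) {
  X <- t(env)                               # time x channels
  if (nrow(X) <= ncol(X)) {
    stop("fewer time samples than channels; cannot run channel PCA",
         call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  live <- sds > 1e-6 * max(sds)
  if (!any(live)) stop("all channels are silent", call. = FALSE)
  p <- stats::prcomp(X[, live, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_keep, ncol(p$rotation))
  load <- matrix(0, nrow = n_keep, ncol = ncol(X))
  load[seq_len(k), live] <-
    t(abs(p$rotation[, seq_len(k), drop = FALSE])) * p$sdev[seq_len(k)]
  evr <- numeric(n_keep)
  evr[seq_len(k)] <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]
  list(loadings = load, evr = evr)
}

#' Spectral PCA across a corpus of channel-envelope matrices
#'
#' Runs a covariance-matrix PCA over channels for each item (observations
#' are envelope time samples), keeps the top `n_keep` components as
#' variance-scaled absolute loadings, and averages loadings and
#' explained-variance ratios across items.  The grand-average loading
#' profile is what band detection operates on.
#'
#' @param corpus a [channel_envelope_matrix] or list of them, all sharing the
#'   same channel centres.
#' @param n_keep number of components retained (default 5).
#' @return a [pca_loadings] grand average.
#' @export
spectral_pca <- function(corpus, n_keep = 5) {
  if (inherits(corpus, "channel_envelope_matrix")) corpus <- list(corpus)
  stopifnot(length(corpus) >= 1)
  centers <- corpus[[1]]$channel_centers
  for (item in corpus) {
    stopifnot(inherits(item, "channel_envelope_matrix"))
    if (!isTRUE(all.equal(item$channel_centers, centers))) {
      stop("all items must share the same channel centres", call. = FALSE)
    }
  }
  fits <- lapply(corpus, function(item) pca_one_item(item$envelopes, n_keep))
  load <- Reduce(`+`, lapply(fits, `[[`, "loadings")) / length(fits)
  evr <- Reduce(`+`, lapply(fits, `[[`, "evr")) / length(fits)
  pca_loadings(load, evr, centers)
}

#' Core-band solution from PCA loading profiles
#'
#' Peak channels, flanking-trough boundary channels, and their frequencies.
#'
#' @param band_peak_channels integer vector of peak channel indices.
#' @param band_edge_channels integer vector of boundary channel indices
#'   (length = number of bands - 1; edges interleave peaks).
#' @param channel_centers channel centre frequencies (Hz).
#' @param supporting_pc_count number of components supporting each band.
#' @return an object of class `band_solution`.
#' @export
band_solution <- function(band_peak_channels, band_edge_channels,
                          channel_centers, supporting_pc_count) {
  nb <- length(band_peak_channels)
  if (nb > 0) {
    stopifnot(length(band_edge_channels) == nb - 1L,
              length(supporting_pc_count) == nb)
    if (nb > 1) {
      lo <- band_peak_channels[-nb]; hi <- band_peak_channels[-1]
      stopifnot(all(band_edge_channels > lo), all(band_edge_channels < hi))
    }
  }
  structure(list(band_peak_channels = band_peak_channels,
                 band_edge_channels = band_edge_channels,
                 band_center_freqs = channel_centers[band_peak_channels],
                 band_edge_freqs = channel_centers[band_edge_channels],
                 channel_centers = channel_centers,
                 supporting_pc_count = supporting_pc_count),
            class = "band_solution")
}

#' @export
print.band_solution <- function(x, ...) {
  if (length(x$band_peak_channels) == 0) {
    cat("<band_solution> no bands detected\n")
  } else {
    cat(sprintf("<band_solution> %d band(s) at %s Hz; edges at %s Hz\n",
                length(x$band_peak_channels),
                paste(signif(x$band_center_freqs, 3), collapse = ", "),
                if (length(x$band_edge_freqs)) {
                  paste(signif(x$band_edge_freqs, 3), collapse = ", ")
                } else "-"))
  }
  invisible(x)
}

#' Detect co-modulation bands from PCA loading profiles
#'
#' For each retained component, local maxima of the absolute loading profile
#' are found at a minimum peak-to-peak channel separation; maxima below
#' `rel_peak_floor` of the largest loading in the whole profile set are
#' ignored (they are filter-skirt or round-off residue, not co-modulation
#' structure).  Peaks
#' from different components that fall within one channel of each other are
#' clustered; a cluster supported by at least `min_pc_count` components is a
#' candidate band (its peak channel is the member channel with the largest
#' summed loading).  The minimum peak distance is then also enforced between
#' the resulting bands themselves — candidate bands closer than
#' `min_peak_distance` channels to a stronger one (more supporting
#' components, then larger summed loading) are dropped, which keeps adequate
#' spacing between the inferred modulation bands.  The boundary between two
#' adjacent bands is the median, across the components supporting either
#' band, of the trough channel flanking the supporting peak on the side
#' facing the other band.
#'
#' @param loadings a [pca_loadings].
#' @param min_peak_distance minimum channel separation between peaks within a
#'   component and between retained bands (2 for spectral profiles, 5 for
#'   modulation-rate profiles).
#' @param min_pc_count minimum number of components that must peak within one
#'   channel of each other for a band to be retained.
#' @param rel_peak_floor smallest peak loading considered, as a fraction of
#'   the component's maximum loading.
#' @return a [band_solution]; empty (zero bands) when no channel satisfies
#'   the criterion, which signals unstructured input.
#' @export
detect_bands <- function(loadings, min_peak_distance = 2, min_pc_count = 2,
                         rel_peak_floor = 0.05) {
  stopifnot(inherits(loadings, "pca_loadings"))
  L <- loadings$loadings
  n_pc <- nrow(L); n_ch <- ncol(L)
  pk <- lapply(seq_len(n_pc), function(j) {
    p <- find_peaks(L[j, ], min_peak_distance)
    p[L[j, p] >= rel_peak_floor * max(L)]
  })
  tr <- lapply(seq_len(n_pc), function(j) find_troughs(L[j, ]))
  all_peaks <- data.frame(
    pc = rep(seq_len(n_pc), vapply(pk, length, 1L)),
    ch = unlist(pk)
  )
  if (nrow(all_peaks) == 0) {
    return(band_solution(integer(0), integer(0), loadings$channel_centers,
                         integer(0)))
  }
  # cluster peak channels: merge channels separated by <= 1
  ord <- order(all_peaks$ch)
  all_peaks <- all_peaks[ord, ]
  cl <- cumsum(c(1L, as.integer(diff(all_peaks$ch) > 1)))
  bands <- list()
  for (g in unique(cl)) {
    sub <- all_peaks[cl == g, ]
    n_support <- length(unique(sub$pc))
    if (n_support < min_pc_count) next
    # peak channel: member channel with largest summed loading across PCs
    cand <- unique(sub$ch)
    score <- vapply(cand, function(c0) sum(L[, c0]), 0)
    bands[[length(bands) + 1L]] <- list(
      peak = cand[which.max(score)],
      support = n_support,
      strength = max(score),
      members = sub
    )
  }
  if (length(bands) == 0) {
    return(band_solution(integer(0), integer(0), loadings$channel_centers,
                         integer(0)))
  }
  # enforce the minimum spacing between the resulting bands, strongest first
  rank <- order(vapply(bands, `[[`, 0L, "support"),
                vapply(bands, `[[`, 0, "strength"), decreasing = TRUE)
  kept_peaks <- integer(0)
  keep <- logical(length(bands))
  for (k in rank) {
    if (all(abs(bands[[k]]$peak - kept_peaks) >= min_peak_distance)) {
      keep[k] <- TRUE
      kept_peaks <- c(kept_peaks, bands[[k]]$peak)
    }
  }
  bands <- bands[keep]
  peaks <- vapply(bands, `[[`, 0L, "peak")
  o <- order(peaks)
  bands <- bands[o]; peaks <- peaks[o]
  # boundaries: median flanking-trough channel between adjacent bands
  edges <- integer(0)
  if (length(bands) > 1) {
    for (i in seq_len(length(bands) - 1L)) {
      right <- flanking_troughs(bands[[i]], tr, side = "right", n_ch = n_ch)
      left <- flanking_troughs(bands[[i + 1L]], tr, side = "left", n_ch = n_ch)
      cand <- c(right, left)
      cand <- cand[cand > peaks[i] & cand < peaks[i + 1L]]
      e <- if (length(cand)) {
        as.integer(round(stats::median(cand)))
      } else {
        as.integer(round((peaks[i] + peaks[i + 1L]) / 2))   # no trough found
      }
      e <- min(max(e, peaks[i] + 1L), peaks[i + 1L] - 1L)
      edges <- c(edges, e)
    }
  }
  band_solution(peaks, edges, loadings$channel_centers,
                vapply(bands, `[[`, 0L, "support"))
}

# Nearest trough on one side of each supporting peak of a band.
flanking_troughs <- function(band, troughs_by_pc, side, n_ch) {
  out <- integer(0)
  for (r in seq_len(nrow(band$members))) {
    p <- band$members$ch[r]
    trs <- troughs_by_pc[[band$members$pc[r]]]
    t0 <- if (side == "right") {
      cand <- trs[trs > p]
      if (length(cand)) min(cand) else NA_integer_
    } else {
      cand <- trs[trs < p]
      if (length(cand)) max(cand) else NA_integer_
    }
    if (!is.na(t0)) out <- c(out, t0)
  }
  out
}
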