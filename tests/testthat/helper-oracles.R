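# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately written as plain definition-checking loops,
# independent of the package's vectorized implementations.

# Mutual information of a joint table by direct double summation of
# p(x,y) * log2(p(x,y) / (p(x) p(y))).
mi_oracle <- function(joint) {
  p <- joint / sum(joint)
  px <- rowSums(p)
  py <- colSums(p)
  mi <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    }
  }
  mi
}

# Strict-local-maximum peak picking by definition checking at every index,
# plateau handled as midpoint, then greedy largest-first min-distance pruning
# by repeated global-maximum extraction.
find_peaks_oracle <- function(v, min_distance = 1) {
  n <- length(v)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    if (v[i] > v[i - 1L] && j < n && v[j + 1L] < v[i]) {
      cand <- c(cand, floor((i + j) / 2))
    }
    i <- j + 1L
  }
  kept <- integer(0)
  remaining <- cand
  while (length(remaining) > 0) {
    best <- remaining[which.max(v[remaining])]
    kept <- c(kept, best)
    remaining <- remaining[abs(remaining - best) >= min_distance]
  }
  as.integer(sort(kept))
}

# Band detection oracle: same documented semantics as detect_bands(), coded
# as straightforward loops for small channel counts.
detect_bands_oracle <- function(loadings, min_peak_distance = 2,
                                min_pc_count = 2, rel_peak_floor = 0.05) {
  L <- loadings$loadings
  n_pc <- nrow(L)
  gmax <- max(L)
  peaks <- list()
  troughs <- list()
  for (j in seq_len(n_pc)) {
    p <- find_peaks_oracle(L[j, ], min_peak_distance)
    peaks[[j]] <- p[L[j, p] >= rel_peak_floor * gmax]
    troughs[[j]] <- find_peaks_oracle(-L[j, ], 1)
  }
  tab <- do.call(rbind, lapply(seq_len(n_pc), function(j) {
    if (length(peaks[[j]]) == 0) return(NULL)
    data.frame(pc = j, ch = peaks[[j]])
  }))
  if (is.null(tab)) return(list(peaks = integer(0), edges = integer(0)))
  tab <- tab[order(tab$ch), ]
  grp <- 1L
  gid <- integer(nrow(tab))
  gid[1] <- 1L
  for (r in seq_len(nrow(tab))[-1]) {
    if (tab$ch[r] - tab$ch[r - 1L] > 1) grp <- grp + 1L
    gid[r] <- grp
  }
  cl <- list()
  for (g in unique(gid)) {
    sub <- tab[gid == g, ]
    if (length(unique(sub$pc)) < min_pc_count) next
    cand <- unique(sub$ch)
    sc <- sapply(cand, function(c0) sum(L[, c0]))
    cl[[length(cl) + 1L]] <- list(peak = cand[which.max(sc)],
                                  support = length(unique(sub$pc)),
                                  strength = max(sc), members = sub)
  }
  if (length(cl) == 0) return(list(peaks = integer(0), edges = integer(0)))
  ord <- order(sapply(cl, `[[`, "support"), sapply(cl, `[[`, "strength"),
               decreasing = TRUE)
  kept <- list()
  for (k in ord) {
    pks <- sapply(kept, `[[`, "peak")
    if (length(kept) == 0 || all(abs(cl[[k]]$peak - pks) >= min_peak_distance)) {
      kept[[length(kept) + 1L]] <- cl[[k]]
    }
  }
  kept <- kept[order(sapply(kept, `[[`, "peak"))]
  pk <- sapply(kept, `[[`, "peak")
  edges <- integer(0)
  if (length(kept) > 1) {
    for (i in seq_len(length(kept) - 1L)) {
      cand <- c()
      for (r in seq_len(nrow(kept[[i]]$members))) {
        p0 <- kept[[i]]$members$ch[r]
        trs <- troughs[[kept[[i]]$members$pc[r]]]
        trs <- trs[trs > p0]
        if (length(trs)) cand <- c(cand, min(trs))
      }
      for (r in seq_len(nrow(kept[[i + 1L]]$members))) {
        p0 <- kept[[i + 1L]]$members$ch[r]
        trs <- troughs[[kept[[i + 1L]]$members$pc[r]]]
        trs <- trs[trs < p0]
        if (length(trs)) cand <- c(cand, max(trs))
      }
      cand <- cand[cand > pk[i] & cand < pk[i + 1L]]
      e <- if (length(cand)) round(stats::median(cand)) else
        round((pk[i] + pk[i + 1L]) / 2)
      edges <- c(edges, min(max(e, pk[i] + 1L), pk[i + 1L] - 1L))
    }
  }
  list(peaks = as.integer(pk), edges = as.integer(edges))
}

# Piecewise-linear loading profile through (channel, value) anchors.
tent_profile <- function(n_channels, anchors) {
  stats::approx(x = anchors[, 1], y = anchors[, 2],
                xout = seq_len(n_channels), rule = 2)$y
}

# Loading fixture emulating the grand-average spectral profile of music-like
# corpora: peaks at the channels nearest 300/500/1000/2500/5500 Hz, flanking
# troughs at the channels nearest 350/700/1750/3900 Hz, on the default
# 28-channel ERB grid, supported by all five components.
spectral_fixture_loadings <- function() {
  fb <- design_erb_filterbank()
  near <- function(f) which.min(abs(fb$channel_centers - f))
  pk <- sapply(c(300, 500, 1000, 2500, 5500), near)
  tr <- sapply(c(350, 700, 1750, 3900), near)
  anchors <- rbind(c(1, 0.3),
                   cbind(pk, 1)[1, , drop = FALSE],
                   c(tr[1], 0.1), c(pk[2], 1), c(tr[2], 0.1),
                   c(pk[3], 1), c(tr[3], 0.1), c(pk[4], 1), c(tr[4], 0.1),
                   c(pk[5], 1), c(28, 0.4))
  base <- tent_profile(28, anchors)
  L <- t(sapply(1:5, function(j) base * (0.75 + 0.05 * j)))
  pca_loadings(L, explained_variance_ratio = c(0.4, 0.2, 0.1, 0.05, 0.02),
               channel_centers = fb$channel_centers)
}

# Loading fixture emulating the grand-average modulation-rate profile: four
# AM bands with flanking troughs at the channels nearest 2.5, 7 and 17 Hz on
# the default 24-channel log grid.
temporal_fixture_loadings <- function() {
  fb <- design_mod_filterbank()
  near <- function(f) which.min(abs(fb$channel_centers - f))
  pk <- sapply(c(1.5, 4.5, 11, 25), near)
  tr <- sapply(c(2.5, 7, 17), near)
  anchors <- rbind(c(1, 0.3), c(pk[1], 1), c(tr[1], 0.1), c(pk[2], 1),
                   c(tr[2], 0.1), c(pk[3], 1), c(tr[3], 0.1), c(pk[4], 1),
                   c(24, 0.3))
  base <- tent_profile(24, anchors)
  L <- t(sapply(1:3, function(j) base * (0.8 + 0.07 * j)))
  pca_loadings(L, explained_variance_ratio = c(0.4, 0.2, 0.1),
               channel_centers = fb$channel_centers)
}

# Modulation envelope with sinusoidal AM components whose amplitudes wobble
# slowly and independently (so modulation channels carry covariance
# structure), strictly positive.
synth_mod_envelope <- function(freqs, seed, env_rate = 200, duration = 30) {
  n <- duration * env_rate
  t <- seq.int(0L, n - 1L) / env_rate
  seeds <- amhier:::substream_seeds(seed, length(freqs))
  e <- numeric(n)
  for (i in seq_along(freqs)) {
    w <- amhier:::with_seed(seeds[i], stats::rnorm(n))
    wb <- amhier:::fft_bandpass(w, env_rate, f_hi = 0.3, order = 2)
    e <- e + (1 + 0.5 * wb / stats::sd(wb)) * (1 + cos(2 * pi * freqs[i] * t))
  }
  e
}

# Phase series with exactly uniform bin coverage for the given bin count.
uniform_phase_ramp <- function(n_bins = 16, reps = 100) {
  centers <- -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  rep(centers, times = reps)
}
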