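# Phase statistics between AM bands: instantaneous phase, mutual information
# between discretized phases, the n:m phase synchronization index, ratio
# enumeration, and adjacency coupling profiles.

#' Instantaneous phase of a band-limited envelope
#'
#' The angle of the analytic signal of the mean-removed envelope, wrapped to
#' `[-pi, pi)`.
#'
#' @param band_envelope numeric vector, band-limited (e.g. one cell of an
#'   [extract_am_grid()] grid or a [pad_cascade()] band modulator).
#' @return numeric vector of phase angles in radians.
#' @export
inst_phase <- function(band_envelope) {
  x <- band_envelope - mean(band_envelope)
  if (all(abs(x) < 1e-12)) {
    stop("phase is undefined for a constant envelope", call. = FALSE)
  }
  wrap_phase(Arg(analytic_signal(x)))
}

#' Mutual information from a joint probability table
#'
#' Plug-in mutual information (base 2) of a pre-binned joint distribution.
#'
#' @param joint nonnegative matrix summing to 1 (or to the total count).
#' @return list with `mi`, `h_x`, `h_y`, `h_xy`, all in bits.
#' @export
mi_from_joint <- function(joint) {
  stopifnot(is.matrix(joint), all(joint >= 0), sum(joint) > 0)
  p <- joint / sum(joint)
  px <- rowSums(p)
  py <- colSums(p)
  h <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  h_x <- h(px); h_y <- h(py); h_xy <- h(as.vector(p))
  list(mi = h_x + h_y - h_xy, h_x = h_x, h_y = h_y, h_xy = h_xy)
}

#' Mutual information between two phase series
#'
#' Phases are discretized into `n_bins` equal-width bins over `[-pi, pi)` and
#' the plug-in mutual information of the joint histogram is returned in bits.
#'
#' @param phi_x,phi_y phase series in radians, equal length.
#' @param n_bins number of equal-width phase bins (default 16).
#' @param details if `TRUE`, return the full list from [mi_from_joint()]
#'   instead of the scalar MI.
#' @return MI in bits (scalar), or a list when `details = TRUE`.
#' @export
phase_mi <- function(phi_x, phi_y, n_bins = 16, details = FALSE) {
  stopifnot(length(phi_x) == length(phi_y), n_bins >= 2)
  n <- length(phi_x)
  if (n < 10 * n_bins^2) {
    warning(sprintf(paste0("series length %d < 10 * n_bins^2 = %d; the ",
                           "plug-in MI estimate will be upward biased"),
                    n, 10 * n_bins^2), call. = FALSE)
  }
  bx <- phase_bin(phi_x, n_bins)
  by <- phase_bin(phi_y, n_bins)
  joint <- matrix(tabulate((bx - 1L) * n_bins + by, nbins = n_bins * n_bins),
                  nrow = n_bins, byrow = TRUE)
  out <- mi_from_joint(joint)
  if (details) out else out$mi
}

# Equal-width bins over [-pi, pi); the right endpoint wraps into the last bin.
phase_bin <- function(phi, n_bins) {
  b <- floor((wrap_phase(phi) + pi) / (2 * pi) * n_bins) + 1L
  pmin(pmax(b, 1L), n_bins)
}

#' Integer ratio pair for n:m phase locking
#'
#' A parent:daughter ratio `a:b` describes a daughter band completing `b`
#' cycles per `a` parent cycles.  In the synchronization index the slow
#' (parent) phase is multiplied by `n = b` and the fast (daughter) phase by
#' `m = a`, so that `n * f_slow = m * f_fast` at exact lock.  (Labels follow
#' the parent:daughter convention — "1:2" means one parent cycle spans two
#' daughter cycles.)
#'
#' @param a parent-cycle count (integer).
#' @param b daughter-cycle count (integer), coprime with `a`, `a < b`.
#' @return object of class `ratio_pair` with fields `n` (slow multiplier),
#'   `m` (fast multiplier), `label`.
#' @export
ratio_pair <- function(a, b) {
  stopifnot(a == round(a), b == round(b), a >= 1, a < b)
  if (coprime_gcd(a, b) != 1) stop("a and b must be coprime", call. = FALSE)
  structure(list(n = as.integer(b), m = as.integer(a),
                 label = sprintf("%d:%d", a, b)),
            class = "ratio_pair")
}

#' Enumerate candidate n:m ratios
#'
#' All coprime parent:daughter pairs `a:b` with both integers below 10 and a
#' frequency ratio `b/a` in `(1, 3]`.  The boundary ratio 3 (label 1:3) is
#' included.  Pairs are ordered by ratio value, ties by parent count.
#'
#' @param max_int exclusive upper bound on both integers (default 10).
#' @param max_ratio inclusive upper bound on `b/a` (default 3).
#' @return list of [ratio_pair] objects.
#' @export
enumerate_ratios <- function(max_int = 10, max_ratio = 3) {
  out <- list()
  for (a in seq_len(max_int - 1L)) {
    for (b in seq_len(max_int - 1L)) {
      if (b <= a) next
      r <- b / a
      if (r <= 1 || r > max_ratio) next
      if (coprime_gcd(a, b) != 1) next
      out[[length(out) + 1L]] <- ratio_pair(a, b)
    }
  }
  ord <- order(vapply(out, function(p) p$n / p$m, 0),
               vapply(out, `[[`, 0L, "m"))
  out[ord]
}

#' n:m phase synchronization index
#'
#' `PSI = | mean_t exp(i (n phi_slow(t) - m phi_fast(t))) |`, the resultant
#' length of the generalized phase difference (taken modulo 2 pi), between 0
#' (no synchronization) and 1 (perfect synchronization).
#'
#' @param phi_slow phase series of the slower (parent) band, radians.
#' @param phi_fast phase series of the faster (daughter) band, equal length.
#' @param ratio a [ratio_pair()] (or integer pair `c(a, b)`).
#' @return PSI in `[0, 1]`.
#' @export
psi <- function(phi_slow, phi_fast, ratio) {
  if (!inherits(ratio, "ratio_pair")) ratio <- ratio_pair(ratio[1], ratio[2])
  stopifnot(length(phi_slow) == length(phi_fast))
  d <- wrap_phase(ratio$n * phi_slow - ratio$m * phi_fast)
  Mod(mean(exp(1i * d)))
}

#' Phase-coupling profile of an AM band set
#'
#' Computes, for each set of AM band waveforms, the mutual information
#' between the discretized phases of every band pair (adjacent and
#' non-adjacent) and the phase synchronization index between every adjacent
#' band pair across all enumerated n:m ratios.
#'
#' For an [extract_am_grid()] input, statistics are reported per spectral
#' band and as the mean across spectral bands; for a [pad_cascade()] input
#' the four core modulators (beta/gamma merged) form a single band set.
#' Three kinds of degenerate band are excluded, each reported with its
#' reason: spectral bands whose envelope carries negligible energy (below 5%
#' of the strongest band), AM bands whose waveform is constant (phase
#' undefined), and AM bands with no in-band spectral content (under a quarter
#' of the waveform's power inside the band's frequency range) — such a
#' waveform is pure filter-skirt leakage of a component outside the band, so
#' its analytic phase is not the phase of an oscillation at that tier.
#' Adjacent pairs are formed over the remaining bands.
#'
#' @param x an `am_envelope_grid` or `pad_cascade`.
#' @param n_bins phase bins for the MI estimate.
#' @param ratios list of [ratio_pair]s (default [enumerate_ratios()]).
#' @param mi_warn if `FALSE`, suppress the short-series MI bias warning.
#' @return object of class `phase_coupling_table` with data frames `mi`
#'   (columns: spectral_band, band_x, band_y, mi_bits, h_x, h_y, h_xy), `psi`
#'   (spectral_band, pair, ratio_label, psi), and `excluded`.  Rows with
#'   `spectral_band == "mean"` average the per-band results.
#' @export
coupling_profile <- function(x, n_bins = 16, ratios = enumerate_ratios(),
                             mi_warn = TRUE) {
  UseMethod("coupling_profile")
}

#' @export
coupling_profile.am_envelope_grid <- function(x, n_bins = 16,
                                              ratios = enumerate_ratios(),
                                              mi_warn = TRUE) {
  ns <- dim(x$envelopes)[1]
  band_names <- x$am_spec$names
  sets <- lapply(seq_len(ns), function(s) {
    waves <- lapply(seq_along(band_names), function(a) x$envelopes[s, a, ])
    names(waves) <- band_names
    waves
  })
  # drop spectral bands with negligible envelope energy
  power <- vapply(seq_len(ns), function(s) mean(x$envelopes[s, , ]^2), 0)
  keep <- power >= 0.05^2 * max(power)
  set_names <- sprintf("spectral_%d", seq_len(ns))
  excluded <- if (any(!keep)) {
    data.frame(spectral_band = set_names[!keep], band = NA_character_,
               reason = "negligible envelope energy")
  } else NULL
  edges <- x$am_spec$edge_freqs
  ranges <- lapply(seq_along(x$am_spec$names),
                   function(a) c(edges[a], edges[a + 1L]))
  names(ranges) <- x$am_spec$names
  profile_band_sets(sets[keep], set_names[keep], n_bins, ratios, excluded,
                    band_ranges = ranges, env_rate = x$env_rate,
                    mi_warn = mi_warn)
}

#' @export
coupling_profile.pad_cascade <- function(x, n_bins = 16,
                                         ratios = enumerate_ratios(),
                                         mi_warn = TRUE) {
  profile_band_sets(list(x$core_modulators), "pad", n_bins, ratios, NULL,
                    band_ranges = x$core_ranges, env_rate = x$env_rate,
                    mi_warn = mi_warn)
}

# Fraction of a waveform's power carried by DFT bins inside [lo, hi]
# (closed interval, so content exactly at a band edge counts as in-band).
# The outer 10% of the waveform is trimmed first: zero-phase filtering leaves
# boundary transients whose broadband energy would mask the distinction
# between real in-band content and out-of-band leakage.
inband_power_fraction <- function(x, fs, lo, hi) {
  n0 <- length(x)
  trim <- floor(0.1 * n0)
  x <- x[seq.int(trim + 1L, n0 - trim)]
  x <- x - mean(x)
  tot <- sum(x^2)
  if (tot <= 0) return(0)
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  f <- abs(freq_grid(n, fs))
  sum(P[f >= lo & f <= hi]) / sum(P)
}

profile_band_sets <- function(sets, set_names, n_bins, ratios, excluded,
                              band_ranges = NULL, env_rate = NULL,
                              mi_warn = TRUE, min_inband_fraction = 0.25) {
  mi_rows <- list(); psi_rows <- list(); excl_rows <- list(excluded)
  for (s in seq_along(sets)) {
    waves <- sets[[s]]
    bn <- names(waves)
    phases <- vector("list", length(waves))
    ok <- logical(length(waves))
    for (i in seq_along(waves)) {
      ph <- tryCatch(inst_phase(waves[[i]]), error = function(e) NULL)
      if (is.null(ph)) {
        excl_rows[[length(excl_rows) + 1L]] <- data.frame(
          spectral_band = set_names[s], band = bn[i],
          reason = "constant band waveform")
        next
      }
      if (!is.null(band_ranges)) {
        frac <- inband_power_fraction(waves[[i]], env_rate,
                                      band_ranges[[i]][1], band_ranges[[i]][2])
        if (frac < min_inband_fraction) {
          excl_rows[[length(excl_rows) + 1L]] <- data.frame(
            spectral_band = set_names[s], band = bn[i],
            reason = sprintf("no in-band spectral content (%.0f%% in band)",
                             100 * frac))
          next
        }
      }
      phases[[i]] <- ph
      ok[i] <- TRUE
    }
    live <- which(ok)
    for (a in seq_along(live)) {
      for (b in seq_along(live)) {
        if (b <= a) next
        i <- live[a]; j <- live[b]
        d <- if (mi_warn) {
          phase_mi(phases[[i]], phases[[j]], n_bins, details = TRUE)
        } else {
          suppressWarnings(
            phase_mi(phases[[i]], phases[[j]], n_bins, details = TRUE))
        }
        mi_rows[[length(mi_rows) + 1L]] <- data.frame(
          spectral_band = set_names[s], band_x = bn[i], band_y = bn[j],
          mi_bits = d$mi, h_x = d$h_x, h_y = d$h_y, h_xy = d$h_xy)
      }
    }
    if (length(live) >= 2) {
      for (a in seq_len(length(live) - 1L)) {
        i <- live[a]; j <- live[a + 1L]
        for (r in ratios) {
          psi_rows[[length(psi_rows) + 1L]] <- data.frame(
            spectral_band = set_names[s],
            pair = sprintf("%s-%s", bn[i], bn[j]),
            ratio_label = r$label,
            psi = psi(phases[[i]], phases[[j]], r))
        }
      }
    }
  }
  mi <- if (length(mi_rows)) do.call(rbind, mi_rows) else
    data.frame(spectral_band = character(0), band_x = character(0),
               band_y = character(0), mi_bits = numeric(0), h_x = numeric(0),
               h_y = numeric(0), h_xy = numeric(0))
  psi_df <- if (length(psi_rows)) do.call(rbind, psi_rows) else
    data.frame(spectral_band = character(0), pair = character(0),
               ratio_label = character(0), psi = numeric(0))
  # mean across band sets (only meaningful with > 1 set)
  if (length(sets) > 1) {
    if (nrow(mi)) {
      agg <- stats::aggregate(cbind(mi_bits, h_x, h_y, h_xy) ~ band_x + band_y,
                              data = mi, FUN = mean)
      mi <- rbind(mi, data.frame(spectral_band = "mean", agg))
    }
    if (nrow(psi_df)) {
      agg <- stats::aggregate(psi ~ pair + ratio_label, data = psi_df,
                              FUN = mean)
      psi_df <- rbind(psi_df, data.frame(spectral_band = "mean", agg))
    }
  }
  excl <- Filter(Negate(is.null), excl_rows)
  excl <- if (length(excl)) do.call(rbind, excl) else
    data.frame(spectral_band = character(0), band = character(0),
               reason = character(0))
  structure(list(mi = mi, psi = psi_df, excluded = excl),
            class = "phase_coupling_table")
}

#' @export
print.phase_coupling_table <- function(x, ...) {
  cat(sprintf("<phase_coupling_table> %d MI rows, %d PSI rows, %d exclusion(s)\n",
              nrow(x$mi), nrow(x$psi), nrow(x$excluded)))
  am <- psi_argmax(x)
  if (nrow(am)) {
    cat("  strongest ratio per adjacent pair:\n")
    for (r in seq_len(nrow(am))) {
      cat(sprintf("    %-22s %s (PSI %.3f)\n", am$pair[r], am$ratio_label[r],
                  am$psi[r]))
    }
  }
  invisible(x)
}

#' Strongest ratio per adjacent band pair
#'
#' @param table a `phase_coupling_table`.
#' @param spectral_band which band-set rows to use; defaults to `"mean"` when
#'   present, otherwise the single available set.
#' @return data frame with one row per adjacent pair: the ratio with the
#'   maximal PSI.
#' @export
psi_argmax <- function(table, spectral_band = NULL) {
  stopifnot(inherits(table, "phase_coupling_table"))
  p <- table$psi
  if (nrow(p) == 0) return(p)
  if (is.null(spectral_band)) {
    spectral_band <- if ("mean" %in% p$spectral_band) "mean"
                     else p$spectral_band[1]
  }
  p <- p[p$spectral_band == spectral_band, ]
  rows <- lapply(split(p, p$pair), function(d) d[which.max(d$psi), ])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
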