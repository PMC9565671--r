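---
title: "Amplitude-modulation hierarchies: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplitude-modulation hierarchies: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(amhier)
```

## The problem

The rhythm of speech and music is carried by the amplitude envelope — the
slow (< 40 Hz) fluctuation of intensity riding on top of the fast
spectral content. Perceptually relevant structure lives in *bands* of
amplitude modulation (AM): a delta-rate band around 0.9–2.5 Hz (prosodic
feet, crotchets), a theta-rate band around 2.5–7 Hz (syllables, quavers),
and faster alpha and beta/gamma bands (demiquavers, note onsets). Metrical
patterns arise from the *phase relations* between adjacent bands: a parent
cycle at one tier encompasses an integer number of daughter cycles at the
next, and which daughter beat coincides with the parent peak decides
whether a strong-weak or weak-strong pattern is heard.

`amhier` quantifies this structure along two independent routes — one
modelled on the cochlea, one on Bayesian inference — and measures cross-band
dependence with mutual information and the n:m phase synchronization index.
This vignette documents the models, every tunable parameter that matters,
the numerical decisions, and what the synthetic test-bench does and does not
establish about real recordings.

## The spectral route

### Cochlear filterbank

`design_erb_filterbank()` places 28 channel centres uniformly on the
ERB-number scale, `ERBn(f) = 21.4·log10(4.37·f/1000 + 1)`, between 100 and
7250 Hz — the spacing of the normal human cochlea over the range occupied by
speech and most instruments. Channel edges sit at ERB-scale midpoints.
`decompose()` band-passes the signal per channel with zero phase, takes the
Hilbert envelope (magnitude of the analytic signal), and resamples each
envelope to `env_rate` (default 1000 Hz — ample headroom above the
0.9–40 Hz modulation range while keeping hour-scale audio tractable).

**Channel steepness.** Channel edges use an order-16 Butterworth magnitude
response applied with exactly zero phase. At ~1.08-ERB spacing a gentle
(order-4) edge lets a centred pure tone leak roughly half of its envelope
energy into neighbouring channels, which blurs the co-modulation structure
the PCA stage must detect; with order-16 edges a centred tone keeps > 97%
of its envelope energy in one channel, as it effectively does in the
cochlea. A tone falling exactly on a channel crossover still splits between
the two adjacent channels — that is geometry, not a filter defect.
Modulation-rate filters (below) keep the gentler order-4 response: their
bands are deliberately broad, and steep edges would ring over the few
cycles a slow modulator completes.

### Band discovery by PCA

`spectral_pca()` runs a PCA per item with channels as variables and
envelope samples as observations, keeps the top 5 components, and averages
the **absolute, variance-scaled loadings** (|eigenvector| × component SD)
across items; `detect_bands()` then reads bands off the grand-average
profiles: peaks are co-modulated channel clusters, flanking troughs are
band boundaries.

Two variants of this step look plausible and only one works:

* *Covariance vs correlation.* Correlation PCA (z-scoring each channel)
  seems attractive so that loud channels do not dominate — but channel
  envelopes legitimately span orders of magnitude, and the quiet channels
  contain nothing except filter-skirt leakage *of the same modulation*.
  Z-scoring promotes that leakage to unit variance, every channel becomes
  co-modulated with every other, and the loading profiles flatten. On
  single-component fixtures the correlation variant detects bands at junk
  channels; the covariance variant recovers exactly the constructed bands.
  The covariance form also reproduces the peaked/near-zero loading shapes
  reported for real corpora.
* *Eigenvectors vs variance-scaled loadings.* Eigenvectors are unit-norm
  regardless of eigenvalue, so a component that explains a vanishing share
  of variance still carries full-size entries — and spurious peaks. Scaling
  by the component SD shrinks negligible components to the noise level.

`detect_bands()` applies four rules, in order: (1) per component, strict
local maxima at a minimum peak-to-peak separation (2 channels for spectral
profiles, 5 for modulation-rate profiles; plateaus count once, at their
midpoint); (2) peaks below 5% of the largest loading in the profile set are
ignored (skirt/round-off residue); (3) peaks from different components
within one channel of each other form a cluster, and a cluster supported by
at least `min_pc_count` components (2 of 5 spectral, 1 of 3 temporal) is a
band; (4) the minimum separation is enforced between the resulting bands
themselves, strongest first, so inferred bands keep adequate spacing.
Boundaries are the median flanking-trough channel across the supporting
components. An empty solution is a valid outcome and signals unstructured
input.

### Modulation-rate stage

`design_mod_filterbank()` spaces 24 channels geometrically over 0.9–40 Hz
(an auditory-bandwidth formula has no meaning at modulation rates, so the
spacing is purely logarithmic). `temporal_pca()` decomposes each
spectral-band envelope with this filterbank, applies the same PCA/detection
machinery per band and averages across bands. `extract_am_grid()` band-pass
filters each spectral-band envelope at the canonical AM edges — 0.9, 2.5,
7, 17, 30 Hz — yielding the spectral-band × AM-band grid of band-limited
waveforms whose phases feed the coupling statistics. The edge table is kept
fixed for the grid (rather than re-estimated per input) so that coupling
results are comparable across inputs; `temporal_pca()` remains available
when the band structure itself is the question.

## Probabilistic amplitude demodulation

`pad_demodulate()` implements MAP inference in the generative model

* `y_t = m_t · c_t`, carrier `c_t ~ N(0, 1)` white;
* `m_t = exp(x_t)` with `x` a stationary zero-mean Gaussian process with a
  squared-exponential kernel whose length-scale is the **modulator
  timescale** (seconds);
* marginalising the carrier, `y_t | x_t ~ N(0, exp(2x_t) + σ_n²)`.

The exponential link guarantees a positive modulator; the timescale
controls how fast the modulator may vary (the prior suppresses content
above roughly `0.19 / timescale` Hz). Defaults: `noise_variance = 1e-3`
(a floor that keeps the likelihood finite when the modulator approaches
zero), `prior_var = 1` (order-unity log-modulator excursions). The carrier
is recovered as `y / m`; the reconstruction `m · c` equals `y` by
construction, so reconstruction checks exercise bookkeeping rather than
inference.

**Numerics.** The GP prior is evaluated through a circulant embedding of
the kernel, so `K⁻¹x` costs one FFT pair per evaluation; eigenvalues are
floored at `1e-9` of their maximum. The optimiser is L-BFGS-B with analytic
gradients, initialised at `x₀ = ½·log(smooth(y²) + σ_n²)` (Gaussian
smoothing at the prior timescale), which starts close enough that a few
hundred iterations suffice. Signals much longer than the timescale are
processed in 50%-overlapping windows of `64 × timescale` seconds (at least
8192 samples), cross-faded triangularly on the log-modulator. Non-converged
optimiser exits are reported with their diagnostic code, never silently.

`pad_cascade()` runs PAD recursively, fastest band first: the first stage
demodulates the signal with a timescale matched to the gamma band's 50 Hz
upper edge; each later stage demodulates the previous stage's modulator
with the next slower timescale (stage cutoff at each band's upper edge,
`ℓ = sqrt(ln 2 / 2) / (π·f_hi)`). The emitted per-band modulator is the
stage modulator band-limited, zero-phase, to the band's range: delta ≤ 4,
theta 4–8, alpha 8–12, beta 12–30, gamma 30–50 Hz. The cascade operates at
a 1000 Hz working rate (anti-aliased): every cascade cutoff is ≤ 50 Hz, so
nothing the cascade can represent is lost, and exact GP inference stays
tractable for signals minutes long.

For phase analysis the cascade also exposes four **core modulators** —
delta, theta, alpha, and a merged beta/gamma tier (12–50 Hz, taken from the
first-stage modulator, whose content spans that range). Adjacent tiers of
the rhythmic hierarchy are delta–theta, theta–alpha, and alpha–beta/gamma;
splitting the top tier in two would manufacture a beta–gamma "pair" whose
two members usually carry the same single component and cannot express an
integer-ratio relationship.

`cwt_scalogram()` provides the standard visualization: an analytic Morlet
wavelet (centre frequency 6), 16 voices per octave over 0.1–40 Hz,
magnitudes normalised so the maximum is 0 dB; `scalogram_average()`
normalises each map to [0, 1] before averaging, so loud items do not
dominate a corpus mean. `spectrum_peaks()` summarises a modulator by the
local maxima of a Welch spectrum (Hann, 50% overlap) that rise at least
6 dB above the median spectrum level — Welch averaging is what makes a
"6 dB prominence" meaningful, since raw periodogram bins of noise fluctuate
by far more than that.

## Phase statistics

`inst_phase()` takes the angle of the analytic signal of the mean-removed
band waveform; a constant waveform has no phase and is rejected.

`phase_mi()` discretizes two phase series into 16 equal-width bins over
[−π, π) and reports plug-in mutual information in bits. Sixteen bins
resolve phase octants comfortably while keeping the 256-cell joint
histogram estimable; the estimator's upward bias is about
`(bins−1)²/(2N·ln 2)` bits, and a warning is raised when the series is
shorter than `10·bins²` samples. The bin count is exposed.

`psi()` implements the n:m synchronization index
`| ⟨exp(i(n·θ_slow − m·θ_fast))⟩ |`. Ratio labels follow the
parent:daughter convention: "a:b" means one parent (slow) cycle spans
`b/a` daughter cycles, and the locking condition `n·f_slow = m·f_fast`
fixes the multipliers as `n = b` on the slow phase and `m = a` on the fast
phase. The label and the multiplier pair are easy to transpose; the
convention is stated wherever ratios appear. `enumerate_ratios()` yields
all coprime pairs with both integers below 10 and a frequency ratio in
(1, 3] — the boundary ratio 3 is included because 1:3 relationships
(three phonemes per syllable, triplets) are substantively meaningful.

`coupling_profile()` assembles the full table: MI for all band pairs
(adjacent and not), PSI for adjacent pairs across all ratios, per spectral
band plus the across-band mean for the spectral route. Three kinds of
degenerate band are excluded, each with a recorded reason:

* spectral bands whose envelope energy is below 5% of the strongest band
  (silent regions of the spectrum);
* AM bands whose waveform is constant (phase undefined);
* AM bands with **no in-band spectral content** — under a quarter of the
  waveform's power (outer 10% trimmed to drop filter edge transients)
  inside the band's own frequency range. Such a waveform is nothing but
  filter-skirt leakage of a component that lives outside the band, and its
  analytic phase is the leaked component's phase, not evidence of an
  oscillation at that tier. Adjacency is then taken over the remaining
  bands.

The last rule matters for sparse stimuli. A compound tone with modulators
at 2, 4, 8 and 16 Hz puts nothing in the 17–30 Hz band; without the rule,
that band's "phase" is a leaked copy of the 16 Hz component and every
statistic involving it is an artifact of the 16-vs-17 Hz edge geometry.
Real, broadband recordings are unaffected — every band then has genuine
in-band content.

## The synthetic test-bench

* `make_compound_tone()`: `(offset + Σ w_k·sin(2π f_k t + φ_k)) · sin(2π f_c t)`,
  z-scored. Defaults — modulators at 2, 4, 8, 16 Hz, equal unit weights,
  zero phases, 200 Hz carrier, 30 s at 44.1 kHz — define the reference
  rhythmic-but-non-musical stimulus: power-of-two rhythm over a vocal-pitch
  carrier. The default `offset = 0` leaves the summed "modulator" signed;
  its audible envelope is then the rectified `|Σ sin|`, whose even-harmonic
  intermodulation products (6, 10, 14, 18 Hz, …) dominate the faster bands.
  `run_simulation_experiment()` therefore raises the offset to
  `sum(mod_weights)`, making the modulator a nonnegative sum of four
  modulation envelopes — the configuration under which the constructed 1:2
  hierarchy is actually present in the envelope a demodulator can see. (No
  positive-envelope method can recover a signed modulator: the signal is
  identical for `(m, c)` and `(|m|, sign(m)·c)`.)
* `make_am_hierarchy()`: a strictly positive product of raised cosines —
  a parent rate and daughters at chosen coprime integer ratios, with phase
  offsets applied to the slower tier of each pair (for a 1:2 pair a
  daughter-side π shift is a whole daughter cycle and changes nothing,
  which is why the convention shifts the parent; a π parent shift swaps
  the strong and weak beats). Carrier: sine or seeded white noise. Exact
  per-tier ground truth is emitted, and `gt_reconstruct()` rebuilds the
  signal from it to within 1e-9.
* `make_independent_bands()`: per-band positive envelopes of narrow-band
  Gaussian noise from independent RNG substreams, summed over a shared
  noise carrier — the unstructured control with no cross-band phase
  dependency.

All generators are bit-reproducible given a seed; substream seeds are
derived deterministically from the master seed.

**What passing tests show — and what they do not.** The fixtures are
stationary, noiseless-in-structure, and spectrally sparse; they establish
that each pipeline stage recovers known structure and stays at chance on
constructed non-structure. Real music and speech add tempo drift,
broadband and nonstationary carriers, reverberation, and production noise;
corpus-scale findings (which spectral bands music occupies, where its MI
peaks lie) require hours of real audio and are outside what this package's
tests can certify.

## Problem sizes used by the tests

The shipped suite runs the simulation experiment at full scale (30 s at
44.1 kHz) once, and otherwise scales fixtures to seconds of audio at
0.2–16 kHz: demodulation parameter recovery uses twenty 20–80 s signals at
0.5–1 kHz across timescales 0.1–2 s; synchronization nulls use 10⁴-sample
phase series over 100 seeds; independence floors use 300 s envelopes at
200 Hz (narrow-band phases decorrelate over seconds, so shorter series sit
well above the i.i.d. Rayleigh floor). These sizes were chosen so each
property is measured where its statistics are meaningful.

## Known limitations

* A pure tone at a channel crossover splits its envelope energy between
  the two adjacent channels; channel-level energy statements hold for
  centred components only.
* The 0.9/2.5/7/17/30 Hz AM edge table places a 16 Hz component — often
  described as a "gamma" timescale — inside the alpha band (7–17 Hz). Band
  assignment here always follows the edge table; sparse stimuli with
  components near 16–17 Hz are sensitive to this edge, which is why
  content-free bands are excluded rather than analysed.
* Plug-in MI is biased upward on short series; compare MI values only
  between series of equal length, or heed the length warning.
* PSI on a band containing several comparable components reflects their
  mixture phase, which can wind at an intermediate rate; interpret ratio
  argmaxes jointly with the band's spectrum.
* PAD inference is MAP, not a full posterior: no uncertainty over the
  modulator is propagated, and θ (timescales, noise floor) is set, not
  learned.
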