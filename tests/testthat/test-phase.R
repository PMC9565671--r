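test_that("instantaneous phase advances at the envelope's rate", {
  fs <- 1000
  t <- seq.int(0, 10 * fs - 1) / fs
  ph <- inst_phase(sin(2 * pi * 2 * t))
  mid <- seq.int(fs, 9 * fs)
  slope <- stats::coef(stats::lm(amhier:::unwrap_phase(ph)[mid] ~ t[mid]))[2]
  expect_lt(abs(slope - 2 * pi * 2) / (2 * pi * 2), 1e-3)
  # -cos is sin shifted by a quarter cycle: phases differ by pi/2
  d <- amhier:::wrap_phase(inst_phase(-cos(2 * pi * 2 * t)) -
                             inst_phase(sin(2 * pi * 2 * t)))
  expect_lt(abs(abs(Arg(mean(exp(1i * d)))) - pi / 2), 0.01)
  expect_error(inst_phase(rep(3, 100)), "constant")
})

test_that("a pi parent offset appears as a pi shift in the recovered phase", {
  ref <- make_am_hierarchy(2, list(c(1, 2)), phase_offsets = 0,
                           duration = 10, sample_rate = 1000, seed = 1)
  shf <- make_am_hierarchy(2, list(c(1, 2)), phase_offsets = pi,
                           duration = 10, sample_rate = 1000, seed = 1)
  d <- amhier:::wrap_phase(
    inst_phase(shf$ground_truth$true_modulators[[1]]) -
      inst_phase(ref$ground_truth$true_modulators[[1]]))
  expect_lt(abs(abs(Arg(mean(exp(1i * d)))) - pi), 0.05)
})

test_that("phase MI matches identity, table and independence oracles", {
  # identical phase series with exactly uniform bin coverage: MI = log2(16)
  ph <- uniform_phase_ramp(16, 200)
  expect_equal(suppressWarnings(phase_mi(ph, ph)), 4, tolerance = 1e-9)
  # a pre-binned diagonal 3x3 joint table: MI = log2(3)
  diag3 <- diag(3) / 3
  expect_equal(mi_from_joint(diag3)$mi, log2(3), tolerance = 1e-12)
  expect_equal(mi_oracle(diag3), log2(3), tolerance = 1e-12)
  # independent uniform phases at T = 1e6: MI below 0.01 bits
  x <- amhier:::with_seed(1, stats::runif(1e6, -pi, pi))
  y <- amhier:::with_seed(2, stats::runif(1e6, -pi, pi))
  expect_lt(phase_mi(x, y), 0.01)
})

test_that("phase MI equals the exhaustive double-sum oracle on small tables", {
  for (seed in 1:25) {
    dims <- amhier:::with_seed(seed, sample(2:6, 2, replace = TRUE))
    joint <- amhier:::with_seed(seed + 100, {
      j <- matrix(stats::rexp(prod(dims)), dims[1], dims[2])
      if (seed %% 3 == 0) j[j < 1] <- 0   # exercise empty cells
      j / sum(j)
    })
    d <- mi_from_joint(joint)
    expect_equal(d$mi, mi_oracle(joint), tolerance = 1e-12)
    expect_lte(d$mi, min(d$h_x, d$h_y) + 1e-12)
    expect_gte(d$mi, -1e-12)
  }
})

test_that("phase MI is symmetric, bounded, and warns on short series", {
  x <- amhier:::with_seed(3, stats::runif(5000, -pi, pi))
  y <- amhier:::wrap_phase(x + amhier:::with_seed(4, stats::rnorm(5000, 0, 1)))
  d_xy <- suppressWarnings(phase_mi(x, y, details = TRUE))
  d_yx <- suppressWarnings(phase_mi(y, x, details = TRUE))
  expect_lt(abs(d_xy$mi - d_yx$mi), 1e-12)
  expect_lte(d_xy$mi, min(d_xy$h_x, d_xy$h_y))
  expect_warning(phase_mi(x[1:100], y[1:100]), "biased")
})

test_that("the synchronization index is exact for locked phases", {
  t <- seq.int(0, 9999) / 1000
  p_slow <- amhier:::wrap_phase(2 * pi * 2 * t)
  p_fast <- amhier:::wrap_phase(2 * pi * 4 * t)
  expect_lt(abs(psi(p_slow, p_fast, ratio_pair(1, 2)) - 1), 1e-9)
  # invariant to a constant offset of either series
  expect_equal(psi(p_slow + 1.1, p_fast, ratio_pair(1, 2)),
               psi(p_slow, p_fast, ratio_pair(1, 2)), tolerance = 1e-12)
  # invariant to joint time reversal
  expect_equal(psi(rev(p_slow), rev(p_fast), ratio_pair(1, 2)),
               psi(p_slow, p_fast, ratio_pair(1, 2)), tolerance = 1e-12)
  # wrong multiplier pair does not lock
  expect_lt(psi(p_slow, p_fast, ratio_pair(1, 3)), 0.05)
})

test_that("random phases follow the Rayleigh small-sample statistics", {
  vals <- vapply(1:100, function(s) {
    psi(amhier:::with_seed(s, stats::runif(1e4, -pi, pi)),
        amhier:::with_seed(s + 500, stats::runif(1e4, -pi, pi)),
        ratio_pair(1, 2))
  }, 0)
  expect_true(all(vals >= 0 & vals <= 1))
  expect_gte(mean(vals < 0.05), 0.95)
  expect_lt(abs(mean(vals) - sqrt(pi) / (2 * sqrt(1e4))), 0.3 * sqrt(pi) / (2 * sqrt(1e4)))
})

test_that("ratio enumeration matches its constraints and the named set", {
  rts <- enumerate_ratios()
  labels <- vapply(rts, `[[`, "", "label")
  expect_true(all(c("1:2", "1:3", "2:3", "3:4", "4:5") %in% labels))
  for (r in rts) {
    expect_lt(r$n, 10)
    expect_lt(r$m, 10)
    expect_gt(r$n / r$m, 1)
    expect_lte(r$n / r$m, 3)
    expect_equal(amhier:::coprime_gcd(r$m, r$n), 1)
  }
  # equals a brute-force enumeration
  brute <- c()
  for (a in 1:9) for (b in 1:9) {
    if (b > a && b / a > 1 && b / a <= 3 && amhier:::coprime_gcd(a, b) == 1) {
      brute <- c(brute, sprintf("%d:%d", a, b))
    }
  }
  expect_setequal(labels, brute)
  expect_error(ratio_pair(2, 4), "coprime")
})

test_that("coupling profiles recover the constructed 1:2 hierarchy", {
  h <- make_am_hierarchy(2, list(c(1, 2), c(1, 2)), carrier = "noise",
                         duration = 12, sample_rate = 1000, seed = 6)
  env <- Reduce(`*`, h$ground_truth$true_modulators)
  grid <- extract_am_grid(channel_envelope_matrix(matrix(env, 1), 1000, 200))
  cp <- coupling_profile(grid, mi_warn = FALSE)
  am <- psi_argmax(cp)
  expect_gte(nrow(am), 2)
  expect_true(all(am$ratio_label == "1:2"))
  # adjacent coupling beats non-adjacent coupling
  mi <- cp$mi
  mi_dt <- mi$mi_bits[mi$band_x == "delta" & mi$band_y == "theta"]
  mi_da <- mi$mi_bits[mi$band_x == "delta" & mi$band_y == "alpha"]
  expect_gt(mi_dt, mi_da)
})

test_that("independent band envelopes stay near the synchronization floor", {
  rts <- enumerate_ratios()
  mx <- vapply(1:20, function(s) {
    ind <- make_independent_bands(c(2, 4), duration = 300, sample_rate = 200,
                                  seed = s)
    ph <- lapply(ind$ground_truth$true_modulators, inst_phase)
    max(vapply(rts, function(r) psi(ph[[1]], ph[[2]], r), 0))
  }, 0)
  expect_true(all(mx < 0.1))
})

test_that("degenerate bands are excluded with a reason", {
  n <- 6000
  t <- seq.int(0, n - 1) / 1000
  env <- 2 + sin(2 * pi * 1.5 * t) + 0.8 * sin(2 * pi * 4 * t)
  grid <- extract_am_grid(channel_envelope_matrix(matrix(env, 1), 1000, 200))
  cp <- coupling_profile(grid, mi_warn = FALSE)
  # alpha and beta/gamma carry no content: both reported absent
  expect_setequal(cp$excluded$band, c("alpha", "beta_gamma"))
  expect_true(all(grepl("in-band|constant", cp$excluded$reason)))
  expect_true(all(cp$psi$pair == "delta-theta"))
})
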