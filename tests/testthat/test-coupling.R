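test_that("clipping truncates to the analysis window exactly once", {
  cfg <- resp_sim_config(n_singers = 2, duration = 400, sampling_rate = 10,
                         seed = 1)
  e <- generate_respiration_ensemble(cfg)
  tr <- get_trace(e, 1)
  clipped <- clip_trace(tr, 360)
  expect_equal(length(clipped$samples), 3600)
  expect_identical(clip_trace(clipped, 360)$samples, clipped$samples)
  short <- clip_trace(tr, 300)
  expect_error(clip_trace(short, 360), "shorter")
})

test_that("Morlet phases advance at the tone frequency for a pure sinusoid", {
  fs <- 8
  t <- seq(0, 400, by = 1 / fs)
  spec <- wavelet_spec(0.1, 0.4, 5)
  for (f in c(0.1, 0.2, 0.4)) {
    ph <- morlet_phases(sin(2 * pi * f * t), spec, sampling_rate = fs)
    j <- which.min(abs(ph$freqs - f))
    v <- which(ph$valid[, j])
    steps <- wrap_phase(diff(ph$phase[v, j]))
    slope <- mean(steps) * fs
    expect_lt(abs(slope - 2 * pi * f) / (2 * pi * f), 0.01)
  }
})

test_that("phase differences are zero for identical traces and 2*pi*f*tau for a delay", {
  fs <- 8
  t <- seq(0, 400, by = 1 / fs)
  f <- 0.2
  spec <- wavelet_spec(0.1, 0.4, 5)
  pa <- morlet_phases(sin(2 * pi * f * t), spec, sampling_rate = fs)
  dp_same <- phase_differences(pa, pa)
  expect_true(all(abs(dp_same$delta[dp_same$valid]) < 1e-12))
  tau <- 1 / (4 * f)  # quarter period
  pb <- morlet_phases(sin(2 * pi * f * (t - tau)), spec, sampling_rate = fs)
  dp <- phase_differences(pa, pb)
  j <- which.min(abs(dp$freqs - f))
  expect_lt(abs(mean(dp$delta[dp$valid[, j], j]) - pi / 2), 0.02)
})

test_that("phase wrapping lands in (-pi, pi] and is antisymmetric", {
  eps <- 0.01
  expect_equal(wrap_phase(pi + eps), -pi + eps)
  expect_equal(wrap_phase(pi), pi)
  expect_equal(wrap_phase(-3 * pi / 2), pi / 2)
  x <- seq(-10, 10, length.out = 501)
  w <- wrap_phase(x)
  expect_true(all(w > -pi & w <= pi))
  # swapping the pair negates the wrapped difference (off the boundary)
  a <- c(0.3, 2.9, -2.9, 1.0)
  b <- c(-0.2, -2.8, 2.8, 0.1)
  expect_equal(wrap_phase(a - b), -wrap_phase(b - a))
})

test_that("mismatched phase arrays are rejected", {
  fs <- 8
  spec <- wavelet_spec(0.1, 0.4, 5)
  pa <- morlet_phases(sin(seq(0, 100, by = 1 / fs)), spec, sampling_rate = fs)
  pb <- morlet_phases(sin(seq(0, 50, by = 1 / fs)), spec, sampling_rate = fs)
  expect_error(phase_differences(pa, pb), "differ")
  expect_error(morlet_phases(rnorm(100), wavelet_spec(), sampling_rate = 0.5),
               "Nyquist")
})

test_that("coupling indices honour their defining windows", {
  expect_equal(aci(rep(0, 10)), 1)
  expect_equal(aci(rep(c(pi / 2, -pi / 2), 25)), 0)
  expect_equal(aci(c(pi / 4, -pi / 4, pi / 2)), 2 / 3)  # closed interval
  expect_equal(psi(rep(1.3, 7)), 1)
  expect_equal(psi(rep(c(0, pi), 50)), 0)
  expect_equal(ici(rep(pi / 8, 9)), 1)
  expect_equal(ici(rep(-pi / 8, 9)), 0)
  expect_equal(aci(rep(-pi / 8, 9)), 1)  # symmetric vs directional
  expect_equal(ici(c(0, pi / 4, 0.3, -0.1)), 2 / 4)  # 0 excluded, pi/4 in
  expect_error(aci(numeric(0)), "valid")
  expect_error(psi(numeric(0)), "valid")
  expect_error(ici(numeric(0)), "valid")
})

test_that("index identities hold on random phase sets", {
  set.seed(11)
  for (i in 1:20) {
    d <- wrap_phase(rnorm(500, sd = 2))
    expect_gte(min(aci(d), psi(d), ici(d)), 0)
    expect_lte(max(aci(d), psi(d), ici(d)), 1)
    expect_equal(aci(d), aci(-d))          # pair-swap symmetry
    expect_equal(psi(d), psi(-d))
    # directional decomposition: both orientations tile the ACI window
    # except points at exactly zero
    expect_lte(ici(d) + ici(-d), aci(d) + 1e-12)
    expect_equal(ici(d) + ici(-d), aci(d) - mean(d == 0))
  }
})

test_that("pipeline indices equal brute-force loop computations bit-exactly", {
  set.seed(7)
  d <- wrap_phase(rnorm(400, sd = 1.5))
  expect_identical(aci(d), brute_aci(d))
  expect_identical(ici(d), brute_ici(d))
  # counting indices are bit-exact; the resultant length differs from a
  # naive loop only by floating summation order
  expect_equal(psi(d), brute_psi(d), tolerance = 1e-12)
})

test_that("aggregation averages a singer's partners then a voice's singers", {
  pieces <- data.frame(piece = "p", unit = "u", a = 1L, b = 1L, c = 1L,
                       stringsAsFactors = FALSE)
  d3 <- study_design(voices = c("a", "b", "c"), singers_per_voice = 1,
                     conditions = "c1", pieces = pieces, blocks = "u")
  vals <- c("a_1.b_1" = 0.2, "a_1.c_1" = 0.4, "b_1.c_1" = 0.6)
  pairs <- expand.grid(singer_a = c("a_1", "b_1", "c_1"),
                       singer_b = c("a_1", "b_1", "c_1"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$singer_a != pairs$singer_b, ]
  key <- apply(pairs, 1, function(r) paste(sort(r), collapse = "."))
  pairs$frequency <- 0.2
  pairs$aci <- pairs$psi <- pairs$ici <- unname(vals[key])
  agg <- aggregate_coupling(pairs, d3)
  expect_equal(agg$singer_means$aci, c(0.3, 0.4, 0.5))
  expect_equal(agg$voice_means$aci, c(0.3, 0.4, 0.5))
  # constancy: equal pairwise values propagate unchanged
  pairs$aci <- pairs$psi <- pairs$ici <- 0.42
  agg2 <- aggregate_coupling(pairs, d3)
  expect_true(all(abs(agg2$voice_means$aci - 0.42) < 1e-12))
  expect_error(aggregate_coupling(pairs[-1, ], d3), "missing singer pair")
})

test_that("band aggregation selects components by centre frequency", {
  expect_equal(frequency_band(c(0.025, 0.03, 0.05, 0.14, 0.15, 0.4)),
               c("very_low", "very_low", "low", "low", "high", "high"))
  freqs <- component_frequencies(wavelet_spec())
  expect_equal(length(freqs), 10)
  expect_true(all(freqs >= 0.025 & freqs <= 0.40))
  expect_setequal(unique(frequency_band(freqs)),
                  c("very_low", "low", "high"))
  # linear spacing option
  lin <- component_frequencies(wavelet_spec(spacing = "linear"))
  expect_equal(diff(lin), rep(diff(lin)[1], 9))
})

test_that("index correlations recover perfect, null and coupled structure", {
  v <- data.frame(aci = seq(0.1, 0.9, length.out = 20))
  v$psi <- v$aci
  v$ici <- v$aci
  ic <- index_correlations(v)
  expect_equal(ic$r, rep(1, 3))
  set.seed(2)
  v2 <- data.frame(aci = runif(300), psi = runif(300), ici = runif(300))
  expect_true(all(abs(index_correlations(v2)$r) < 0.15))
  expect_error(index_correlations(v[1:2, ]), "at least 3")
})
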