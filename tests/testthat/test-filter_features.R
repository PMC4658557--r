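# Settings for tracking broadband (noise-excited) fixtures: a 4-resonance
# fixture needs 2 poles per resonance plus one for the spectral floor, and
# no pre-emphasis because a white excitation has no source tilt to undo.
broadband_settings <- function(ceiling = 4000) {
  formant_settings(ceiling = ceiling, max_formants = 4, lpc_order = 9,
                   pre_emphasis_from = ceiling)
}

test_that("LPC tracking recovers resonator frequencies from noise", {
  set.seed(7)
  targets <- c(500, 1500, 2500, 3500)
  noise <- waveform(rnorm(88200), 44100)
  fw <- apply_formant_filter(noise, targets, 80)
  tr <- correct_octave_jumps(track_formants(fw, broadband_settings()))
  med <- apply(tr$frequencies[, 1:4], 2, stats::median, na.rm = TRUE)
  expect_true(all(abs(med - targets) / targets < 0.05))
  m <- formant_means(tr)
  expect_true(all(abs(m - targets) / targets < 0.05))
})

test_that("formant tracking survives a pure tone without crashing", {
  w <- tone_wave(1000, dur = 0.5)
  tr <- track_formants(w, formant_settings(ceiling = 3500))
  expect_s3_class(tr, "formant_track")
  expect_equal(ncol(tr$frequencies), 5L)
})

test_that("tracking is robust to the analysis ceiling for separated formants", {
  set.seed(13)
  noise <- waveform(rnorm(88200), 44100)
  fw <- apply_formant_filter(noise, c(500, 1500, 2500), 80)
  m35 <- apply(correct_octave_jumps(track_formants(fw,
    formant_settings(ceiling = 3500, max_formants = 3, lpc_order = 7,
                     pre_emphasis_from = 3500)))$frequencies[, 1, drop = FALSE],
    2, stats::median, na.rm = TRUE)
  m40 <- apply(correct_octave_jumps(track_formants(fw,
    formant_settings(ceiling = 4000, max_formants = 3, lpc_order = 7,
                     pre_emphasis_from = 4000)))$frequencies[, 1, drop = FALSE],
    2, stats::median, na.rm = TRUE)
  expect_lt(abs(m35 - m40) / m40, 0.05)
})

test_that("octave jump correction repairs isolated outliers and is idempotent", {
  f <- matrix(rep(c(500, 1500, 2500, 3200), each = 10), 10, 4)
  tr <- structure(list(times = seq_len(10) * 0.045, frequencies = f,
                       bandwidths = f * 0 + 100,
                       settings = formant_settings()),
                  class = "formant_track")
  bad <- tr
  bad$frequencies[5, 1] <- 1000
  fixed <- correct_octave_jumps(bad)
  expect_equal(fixed$frequencies, tr$frequencies)
  expect_equal(correct_octave_jumps(fixed)$frequencies, fixed$frequencies)
})

test_that("octave jump correction restores most corrupted frames", {
  set.seed(17)
  n <- 60
  truth <- matrix(rep(c(500, 1500, 2500, 3200), each = n), n, 4)
  noisy <- truth * matrix(1 + rnorm(n * 4, 0, 0.02), n, 4)
  corrupted <- noisy
  hit <- sample(n, round(0.3 * n))
  corrupted[hit, ] <- corrupted[hit, ] * 2
  tr <- structure(list(times = seq_len(n) * 0.045,
                       frequencies = corrupted,
                       bandwidths = corrupted * 0 + 100,
                       settings = formant_settings()),
                  class = "formant_track")
  fixed <- correct_octave_jumps(tr)$frequencies
  restored <- abs(fixed[hit, ] - truth[hit, ]) / truth[hit, ] < 0.1
  expect_gte(mean(restored), 0.9)
})

test_that("formant means average frames and preserve ordering", {
  f <- matrix(c(500, 520, 1500, 1500, 2500, 2500, 3200, 3200), 2, 4)
  tr <- structure(list(times = c(0, 0.045), frequencies = f,
                       bandwidths = f * 0 + 100,
                       settings = formant_settings()),
                  class = "formant_track")
  m <- formant_means(tr)
  expect_equal(unname(m), c(510, 1500, 2500, 3200))
  expect_true(all(diff(m) > 0))
  one <- tr; one$frequencies <- f[1, , drop = FALSE]; one$times <- 0
  expect_equal(unname(formant_means(one)), c(500, 1500, 2500, 3200))
  none <- tr; none$frequencies[, 4] <- NA
  expect_error(formant_means(none), "4 formants")
})

test_that("formant dispersion equals the origin regression", {
  expect_equal(formant_dispersion(c(500, 1500, 2500, 3500)), 1000)
  expect_equal(formant_dispersion(c(437.5, 1312.5, 2187.5, 3062.5)), 875)
  # one bird's printed formant means vs an independent least-squares fit
  means <- c(364.57, 888.79, 1255.5, 1908.71)
  x <- (2 * 1:4 - 1) / 2
  oracle <- unname(stats::coef(stats::lm(means ~ 0 + x)))
  expect_equal(formant_dispersion(means), oracle, tolerance = 1e-12)
  expect_error(formant_dispersion(c(500, 400, 2500, 3500)), "increasing")
})

test_that("vocal tract length follows the quarter-wave formula", {
  expect_equal(estimate_vtl(1000), 17.5)
  expect_equal(estimate_vtl(875), 20)
  # a printed per-individual dispersion implies the printed VTL within 0.5%
  expect_lt(abs(estimate_vtl(539.75) - 32.53) / 32.53, 0.005)
  expect_error(estimate_vtl(0), "positive")
})

test_that("vocal tract length is recovered from synthesized calls", {
  set.seed(19)
  for (vtl in c(22, 30)) {
    p <- voice_profile("b", f0_mean = 250, vtl = vtl, vtl_within_sd = 0,
                       snr_db = 25)
    s <- synth_contact_call(p)
    fs <- filter_stats(s$waveform)
    expect_lt(abs(fs$VTLest - vtl) / vtl, 0.08)
  }
})
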