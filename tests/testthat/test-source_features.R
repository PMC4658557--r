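test_that("the tracker pins a pure tone and rejects noise", {
  w <- tone_wave(250, dur = 1)
  c0 <- track_f0(w)
  voiced <- c0$f0[!is.na(c0$f0)]
  expect_gt(length(voiced), 0.9 * nrow(c0))
  expect_true(all(abs(voiced - 250) < 1))

  set.seed(2)
  wn <- waveform(rnorm(44100), 44100)
  cn <- track_f0(wn)
  expect_gte(mean(is.na(cn$f0)), 0.9)
})

test_that("tracked f0 never leaves the search band", {
  # a tone below the floor must not be reported below the floor
  w <- tone_wave(100, dur = 0.5)
  c0 <- track_f0(w)
  v <- c0$f0[!is.na(c0$f0)]
  expect_true(all(v >= 150 & v <= 350))
  # clean synthesized calls across the band track within 2%
  set.seed(4)
  for (f in c(160, 250, 340)) {
    ws <- synth_source(flat_contour(f, 0.4), 0, 0)
    cs <- track_f0(ws)
    expect_lt(abs(mean(cs$f0, na.rm = TRUE) - f) / f, 0.02)
  }
})

test_that("f0 contour statistics match hand computations", {
  ct <- data.frame(time = c(0, 0.01, 0.02), f0 = c(200, 210, 220))
  st <- f0_statistics(ct, 0.03)
  expect_equal(st$f0Start, 200)
  expect_equal(st$f0End, 220)
  expect_equal(st$f0Mean, 210)
  expect_equal(st$f0AbsSlope, 1000)
  expect_equal(st$f0Var, 20 / 0.03)

  cc <- data.frame(time = c(0, 0.01, 0.02), f0 = c(250, 250, 250))
  sc <- f0_statistics(cc, 0.02)
  expect_equal(sc$f0AbsSlope, 0)
  expect_equal(sc$f0Var, 0)
  expect_equal(sc$f0Min, sc$f0Max)

  cm <- data.frame(time = c(0, 0.01, 0.02), f0 = c(250, 240, 260))
  sm <- f0_statistics(cm, 0.03)
  expect_equal(sm$Timef0Min, 100 * 0.01 / 0.03)
  expect_equal(sm$Timef0Max, 100 * 0.02 / 0.03)

  expect_error(f0_statistics(data.frame(time = 0, f0 = 250), 0.01),
               "voiced")
})

test_that("FM statistics count modulation cycles", {
  t <- seq(0, 2, by = 0.01)
  ct <- data.frame(time = t, f0 = 250 + 5 * sin(2 * pi * 2 * t))
  fm <- fm_statistics(ct)
  expect_lt(abs(fm$FMRate - 2) / 2, 0.1)
  expect_lt(abs(fm$FMExtent - 10) / 10, 0.1)

  flat <- data.frame(time = t, f0 = rep(250, length(t)))
  expect_equal(fm_statistics(flat), list(FMRate = 0, FMExtent = 0))
  ramp <- data.frame(time = t, f0 = 200 + 50 * t)
  expect_equal(fm_statistics(ramp), list(FMRate = 0, FMExtent = 0))
})

test_that("pulse extraction recovers periods and amplitude trends", {
  set.seed(6)
  w <- synth_source(flat_contour(250, 0.5), 0, 0)
  p <- extract_pulses(w, track_f0(w))
  expect_true(all(abs(p$cycle_periods - 0.004) < 1 / 44100))
  # amplitude ramp leaves periods unchanged, amplitudes monotone
  ramp <- waveform(w$samples * seq(0.2, 1, length.out = length(w$samples)),
                   44100)
  pr <- extract_pulses(ramp, track_f0(w))
  expect_true(all(abs(pr$cycle_periods - 0.004) < 1 / 44100))
  expect_gt(stats::cor(seq_along(pr$cycle_peak_amplitudes),
                       pr$cycle_peak_amplitudes), 0.99)
})

test_that("jitter and shimmer match hand values and a brute-force oracle", {
  pt <- structure(list(cycle_periods = rep(c(5.0, 5.5) / 1000, 10),
                       cycle_peak_amplitudes = rep(1, 20)),
                  class = "pulse_train")
  expect_equal(jitter_local(pt), 0.0005 / 0.00525, tolerance = 1e-10)

  at <- structure(list(cycle_periods = rep(0.004, 20),
                       cycle_peak_amplitudes = rep(c(1.0, 0.8), 10)),
                  class = "pulse_train")
  expect_equal(shimmer_local(at), 0.2 / 0.9, tolerance = 1e-10)

  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    periods <- runif(n, 0.003, 0.006)
    amps <- runif(n, 0.2, 1)
    p <- structure(list(cycle_periods = periods,
                        cycle_peak_amplitudes = amps),
                   class = "pulse_train")
    # independent direct-formula evaluation
    jit <- sum(abs(periods[-1] - periods[-n])) / (n - 1) /
      (sum(periods) / n)
    shi <- sum(abs(amps[-1] - amps[-n])) / (n - 1) / (sum(amps) / n)
    expect_lt(abs(jitter_local(p) - jit), 1e-12)
    expect_lt(abs(shimmer_local(p) - shi), 1e-12)
  }

  expect_error(jitter_local(structure(list(cycle_periods = c(1, 2)),
                                      class = "pulse_train")), "3 cycles")
})

test_that("harmonics-to-noise separates clean, mixed and noise signals", {
  set.seed(10)
  clean <- synth_source(flat_contour(250, 1), 0, 0)
  c0 <- track_f0(clean)
  expect_gt(harmonics_to_noise(clean, c0), 25)

  x <- sin(2 * pi * 250 * (0:44099) / 44100)
  noisy <- waveform(x + rnorm(44100, 0, sqrt(mean(x^2))), 44100)
  cn <- track_f0(noisy)
  hnr <- harmonics_to_noise(noisy, cn)
  expect_gt(hnr, -3); expect_lt(hnr, 3)

  wn <- waveform(rnorm(44100), 44100)
  forced <- track_f0(tone_wave(250, 1))  # voiced frames at 250 Hz
  expect_lt(harmonics_to_noise(wn, forced), 0)
})

test_that("source statistics are invariant to amplitude scaling", {
  set.seed(12)
  p <- voice_profile("b", f0_mean = 260)
  s <- synth_contact_call(p)
  w <- s$waveform
  w3 <- waveform(w$samples * 0.25, w$sample_rate)
  a <- source_stats(w)
  b <- source_stats(w3)
  for (nm in names(a)) expect_equal(a[[nm]], b[[nm]], info = nm)
})

test_that("jitter and shimmer recover generator levels on full calls", {
  set.seed(14)
  p <- voice_profile("b", f0_mean = 250, jitter_level = 0.01,
                     shimmer_level = 0.12, snr_db = Inf, am_depth = 0.1)
  jd <- sd <- numeric(10)
  for (i in 1:10) {
    s <- synth_contact_call(p)
    fv <- source_stats(s$waveform)
    jd[i] <- fv$Jitter - s$ground_truth$Jitter
    sd[i] <- fv$Shimmer - s$ground_truth$Shimmer
  }
  expect_lt(abs(mean(jd)), 0.01)
  expect_lt(abs(mean(sd)), 0.05)
})
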