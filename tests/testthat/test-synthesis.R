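test_that("quarter-wave tube formants match the closed form", {
  expect_equal(formants_from_vtl(20, 4), c(437.5, 1312.5, 2187.5, 3062.5))
  expect_equal(formants_from_vtl(17.5, 2), c(500, 1500))
  expect_error(formants_from_vtl(-1), "positive")
})

test_that("VTL -> formants -> dispersion -> VTL is the identity", {
  for (vtl in seq(15, 35, by = 2.5)) {
    f <- formants_from_vtl(vtl, 4)
    expect_equal(estimate_vtl(formant_dispersion(f)), vtl)
  }
})

test_that("unperturbed source is exactly periodic", {
  set.seed(1)
  w <- synth_source(flat_contour(250, 0.5), 0, 0)
  p <- attr(w, "cycle_periods")
  expect_equal(stats::sd(p), 0)
  c0 <- track_f0(w)
  pulses <- extract_pulses(w, c0)
  expect_lt(jitter_local(pulses), 1e-3)
})

test_that("injected jitter is recovered by the jitter estimator", {
  set.seed(20)
  est <- vapply(1:30, function(i) {
    w <- synth_source(flat_contour(250, 0.5), 0.02, 0)
    jitter_local(extract_pulses(w, track_f0(w)))
  }, 0)
  expect_gt(mean(est), 0.01)
  expect_lt(mean(est), 0.03)
})

test_that("a linear contour is recovered at the call boundaries", {
  set.seed(3)
  contour <- data.frame(time = c(0, 0.5), f0 = c(220, 280))
  w <- synth_source(contour, 0, 0)
  st <- f0_statistics(track_f0(w), 0.5)
  expect_lt(abs(st$f0Start - 220) / 220, 0.02)
  expect_lt(abs(st$f0End - 280) / 280, 0.02)
})

test_that("formant filtering places spectral peaks at the resonances", {
  set.seed(9)
  targets <- c(500, 1500, 2500, 3500)
  noise <- waveform(rnorm(44100), 44100)
  fw <- apply_formant_filter(noise, targets, 80)
  n <- length(fw$samples)
  sp <- Mod(stats::fft(fw$samples))[seq_len(n %/% 2)]^2
  hz <- (seq_len(n %/% 2) - 1) * 44100 / n
  for (f in targets) {
    band <- hz > f - 200 & hz < f + 200
    peak_hz <- hz[band][which.max(sp[band])]
    expect_lt(abs(peak_hz - f), 40)
  }
})

test_that("formant filter identity and selectivity", {
  w <- tone_wave(1000, dur = 0.3)
  expect_identical(apply_formant_filter(w, numeric(0)), w)
  g_on <- sqrt(mean(apply_formant_filter(w, 1000, 80)$samples^2))
  w2 <- tone_wave(2000, dur = 0.3)
  g_off <- sqrt(mean(apply_formant_filter(w2, 1000, 80)$samples^2))
  # both outputs are peak-normalized, so compare gains via crest-corrected
  # RMS against the unfiltered tone
  r1 <- apply_formant_filter(waveform(w$samples + w2$samples, 44100),
                             1000, 80)
  n <- length(r1$samples)
  sp <- Mod(stats::fft(r1$samples))[seq_len(n %/% 2)]
  hz <- (seq_len(n %/% 2) - 1) * 44100 / n
  a1 <- max(sp[abs(hz - 1000) < 5])
  a2 <- max(sp[abs(hz - 2000) < 5])
  expect_gt(a1 / a2, 10)
  expect_error(apply_formant_filter(w, 30000), "Nyquist")
})

test_that("contact call synthesis is seed-deterministic", {
  p <- voice_profile("b1", f0_mean = 250)
  set.seed(42); a <- synth_contact_call(p)
  set.seed(42); b <- synth_contact_call(p)
  expect_identical(a$waveform$samples, b$waveform$samples)
  expect_identical(a$ground_truth, b$ground_truth)
  set.seed(43); c3 <- synth_contact_call(p)
  expect_false(identical(a$waveform$samples, c3$waveform$samples))
})

test_that("extracted f0Mean tracks the realized contour mean", {
  # profile built from one reference bird's printed f0 and duration
  p <- voice_profile("Oceano", f0_mean = 251.62, f0_within_sd = 14.74,
                     duration_mean = 0.58, duration_sd = 0.07,
                     vtl = 31.16, snr_db = 25)
  set.seed(7)
  s <- synth_contact_call(p)
  fv <- contact_feature_vector(s$waveform)
  expect_lt(abs(fv$f0Mean - s$ground_truth$f0Mean) / s$ground_truth$f0Mean,
            0.03)
})

test_that("clean low-perturbation calls have high harmonics-to-noise", {
  p <- voice_profile("b1", f0_mean = 250, jitter_level = 0, jitter_sd = 0,
                     shimmer_level = 0, shimmer_sd = 0,
                     am_depth = 0.05, am_depth_sd = 0,
                     snr_db = Inf)
  set.seed(5)
  s <- synth_contact_call(p)
  c0 <- track_f0(s$waveform)
  expect_gt(harmonics_to_noise(s$waveform, c0), 25)
})

test_that("song structure ground truth matches its annotations exactly", {
  profs <- default_profiles("song")
  set.seed(11)
  s <- synth_display_song(profs[[1]])
  syl <- syllable_structure(s$annotations)
  gt <- s$ground_truth
  for (nm in names(syl)) expect_equal(gt[[nm]], syl[[nm]], info = nm)
  expect_lte(gt$SumType1 + gt$SumType2 + gt$SumType3, gt$Dur)
})

test_that("song grammar syllable counts sample around their means", {
  profs <- default_profiles("song")
  soldato <- profs[[which(vapply(profs, `[[`, "", "individual_id") ==
                            "Soldato")]]
  set.seed(21)
  n3 <- vapply(1:50, function(i) {
    synth_display_song(soldato, render = FALSE)$ground_truth$Type3
  }, 0)
  expect_lt(abs(mean(n3) - 3.18) / 3.18, 0.25)
})

test_that("colonies are reproducible and sized by configuration", {
  profs <- null_profiles(2)
  cfg <- colony_config(profs, 2, "contact", seed = 7)
  a <- generate_colony(cfg)
  b <- generate_colony(cfg)
  expect_equal(length(a$waveforms), 4L)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$waveforms[[3]]$samples, b$waveforms[[3]]$samples)

  sizes <- c(9, 14, 20, 25, 31, 19)
  cfg6 <- colony_config(null_profiles(6), sizes, "contact", seed = 1,
                        audio = FALSE)
  gt <- generate_colony(cfg6)$ground_truth
  expect_equal(nrow(gt), 118L)
  expect_equal(as.numeric(table(gt$individual_id)[paste0("bird", 1:6)]),
               sizes)
})

test_that("colony configuration rejects degenerate inputs", {
  p <- null_profiles(2)
  expect_error(colony_config(p[1], 2, "contact", seed = 1), "2 profiles")
  expect_error(colony_config(list(p[[1]], p[[1]]), 2, "contact", seed = 1),
               "duplicate")
  expect_error(colony_config(p, 1, "contact", seed = 1), ">= 2")
  expect_error(colony_config(p, 2, "contact"), "seed")
})

test_that("voice profile invariants are enforced", {
  expect_error(voice_profile("x", f0_mean = 100), "search band")
  expect_error(voice_profile("x", f0_mean = 250, vtl = 0), "vtl")
  expect_error(voice_profile("x", f0_mean = 250, jitter_level = 1.2),
               "jitter")
})
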