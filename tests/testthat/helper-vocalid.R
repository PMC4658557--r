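# Shared fixtures for the test suite. Everything is generated in code.

# A pure tone as a waveform.
tone_wave <- function(freq, dur = 1, sr = 44100, amp = 0.8) {
  waveform(amp * sin(2 * pi * freq * (seq_len(round(dur * sr)) - 1) / sr),
           sr)
}

# A constant-f0 contour for the synthesizer.
flat_contour <- function(f0, dur) {
  data.frame(time = c(0, dur), f0 = c(f0, f0))
}

# Identical profiles for null-colony calibration. A flat contour with
# random-phase frequency modulation keeps the time-of-extremum parameters
# smoothly distributed, so their coefficients of variation are stable.
null_profiles <- function(n = 6) {
  lapply(seq_len(n), function(i) {
    voice_profile(paste0("bird", i), f0_mean = 260, start_offset = 0,
                  end_offset = 0, fm_extent = 6, fm_extent_sd = 1.5)
  })
}

# Six well-separated profiles: adjacent individuals differ by >= 2
# within-individual SDs in f0, vocal tract length and duration.
separable_profiles <- function() {
  f0s <- c(220, 240, 260, 280, 300, 320)
  vtls <- c(24, 26, 28, 30, 32, 34)
  durs <- c(0.40, 0.50, 0.60, 0.70, 0.80, 0.90)
  lapply(1:6, function(i) {
    voice_profile(paste0("bird", i), f0_mean = f0s[i], f0_within_sd = 8,
                  vtl = vtls[i], vtl_within_sd = 0.8,
                  duration_mean = durs[i], duration_sd = 0.05,
                  start_offset = 0, end_offset = 0,
                  fm_extent = 6, fm_extent_sd = 1.5)
  })
}

# A random feature table with g groups of n rows and p numeric columns.
random_feature_table <- function(g = 4, n = 6, p = 3, shift = 0) {
  rows <- lapply(seq_len(g), function(k) {
    X <- matrix(stats::rnorm(n * p, mean = 10 + shift * k), n, p)
    df <- as.data.frame(X)
    names(df) <- paste0("v", seq_len(p))
    df$individual_id <- paste0("g", k)
    df
  })
  do.call(rbind, rows)
}

# Minimal stereo 16-bit PCM WAV writer (the package writer is mono only;
# the reader must down-mix).
write_stereo_wav <- function(left, right, sr, path) {
  stopifnot(length(left) == length(right))
  q <- as.integer(round(pmax(-1, pmin(1,
    as.vector(rbind(left, right)))) * 32767))
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(as.integer(sr), con, 4, endian = "little")
  writeBin(as.integer(sr) * 4L, con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, 4, endian = "little")
  writeBin(q, con, 2, endian = "little")
  path
}

# Frequency of the dominant FFT peak of a waveform.
fft_peak_hz <- function(w) {
  n <- length(w$samples)
  sp <- Mod(stats::fft(w$samples))[seq_len(n %/% 2)]
  (which.max(sp) - 1) * w$sample_rate / n
}
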