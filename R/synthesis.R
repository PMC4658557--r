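## Source-filter call synthesizer: band-limited harmonic pulse-train source
## with controllable per-cycle jitter and shimmer, a cascade of second-order
## formant resonators, amplitude modulation and additive noise. Generates
## contact calls and three-syllable ecstatic display songs with ground-truth
## feature tables, so the whole analysis pipeline is testable without field
## recordings. Ground-truth tables can be generated without rendering audio,
## which makes large multi-seed statistical calibrations cheap.

#' Resonance frequencies of a uniform quarter-wave tube
#'
#' `F_i = (2i - 1) c / (4 VTL)`: the odd resonances of a uniform tube open
#' at one end and closed at the other, the standard vocal-tract model behind
#' the vocal tract length estimate. Consecutive formants are spaced
#' `c / (2 VTL)` apart.
#'
#' @param vtl Vocal tract length in cm (positive).
#' @param k Number of formants.
#' @param c Speed of sound in cm/s (default 35000).
#' @return Increasing vector of `k` formant frequencies in Hz.
#' @examples
#' formants_from_vtl(17.5, 2)  # 500, 1500
#' @export
formants_from_vtl <- function(vtl, k = 4, c = 35000) {
  if (vtl <= 0) stop("vtl must be positive")
  if (k < 1) stop("k must be >= 1")
  (2 * seq_len(k) - 1) * c / (4 * vtl)
}

#' Per-individual voice profile for the synthesizer
#'
#' Bundles the source, filter and temporal parameters that characterize one
#' bird's voice. Each `*_sd` field is the call-to-call (within-individual)
#' spread of the corresponding parameter: the synthesizer redraws those
#' parameters per call from truncated (+/- 3 SD) Gaussians, which is what
#' gives every acoustic parameter a within-individual distribution and makes
#' the generated colonies suitable for studying within/between variation.
#'
#' @param individual_id Label.
#' @param f0_mean Mean fundamental in Hz; must lie in the tracker's
#'   150-350 Hz search band.
#' @param f0_within_sd Call-to-call SD of the call's base f0 (Hz).
#' @param start_offset,end_offset Contour offsets at call start/end relative
#'   to the call's base f0 (Hz).
#' @param fm_rate,fm_rate_sd Frequency-modulation rate (cycles/s) and its
#'   call-to-call SD.
#' @param fm_extent,fm_extent_sd Peak-to-peak frequency-modulation depth
#'   (Hz) and SD. The modulation phase is drawn uniformly per call.
#' @param jitter_level,jitter_sd Target cycle-to-cycle period perturbation
#'   (proportion in `[0, 1)`) and its call-to-call SD.
#' @param shimmer_level,shimmer_sd Target cycle amplitude perturbation
#'   (proportion) and SD.
#' @param vtl,vtl_within_sd Vocal tract length in cm and the call-to-call
#'   spread of its realized (measured) value.
#' @param formant_bandwidths Resonator bandwidths in Hz, one per formant
#'   (recycled). Bandwidths are not reported for this species; the defaults
#'   (80-200 Hz, widening with formant number) are a modelling choice.
#' @param am_rate,am_rate_sd Amplitude-modulation rate (cycles/s) and SD.
#' @param am_depth,am_depth_sd Amplitude-modulation depth (proportion in
#'   `[0, 1)`) and SD.
#' @param duration_mean,duration_sd Call (or type-2 syllable) duration
#'   distribution in seconds.
#' @param snr_db,snr_sd Signal-to-noise ratio of added white noise in dB
#'   (`Inf` = clean) and its call-to-call SD.
#' @param song_grammar `NULL` for contact calls, or a list with per-type
#'   syllable count means/SDs (`n_type1`, `n_type1_sd`, ... `n_type3_sd`),
#'   per-type durations (`dur_type1`, `dur_type1_sd`, `dur_type3`,
#'   `dur_type3_sd`; type-2 durations come from `duration_mean`/
#'   `duration_sd`) and inter-syllable gaps (`gap_mean`, `gap_sd`), all in
#'   seconds.
#' @return List of class `voice_profile`.
#' @export
voice_profile <- function(individual_id, f0_mean, f0_within_sd = 15,
                          start_offset = -10, end_offset = 10,
                          fm_rate = 2, fm_rate_sd = 0.5,
                          fm_extent = 4, fm_extent_sd = 1,
                          jitter_level = 0.01, jitter_sd = 0.003,
                          shimmer_level = 0.15, shimmer_sd = 0.03,
                          vtl = 30, vtl_within_sd = 0.8,
                          formant_bandwidths = c(80, 110, 140, 170, 200),
                          am_rate = 7, am_rate_sd = 1,
                          am_depth = 0.3, am_depth_sd = 0.05,
                          duration_mean = 0.6, duration_sd = 0.1,
                          snr_db = 25, snr_sd = 3, song_grammar = NULL) {
  if (f0_mean < 150 || f0_mean > 350)
    stop("f0_mean must lie within the 150-350 Hz search band")
  if (vtl <= 0) stop("vtl must be positive")
  if (jitter_level < 0 || jitter_level >= 1) stop("jitter_level in [0, 1)")
  if (shimmer_level < 0 || shimmer_level >= 1) stop("shimmer_level in [0, 1)")
  if (am_depth < 0 || am_depth >= 1) stop("am_depth in [0, 1)")
  if (duration_mean <= 0) stop("duration_mean must be positive")
  structure(list(
    individual_id = individual_id, f0_mean = f0_mean,
    f0_within_sd = f0_within_sd, start_offset = start_offset,
    end_offset = end_offset, fm_rate = fm_rate, fm_rate_sd = fm_rate_sd,
    fm_extent = fm_extent, fm_extent_sd = fm_extent_sd,
    jitter_level = jitter_level, jitter_sd = jitter_sd,
    shimmer_level = shimmer_level, shimmer_sd = shimmer_sd,
    vtl = vtl, vtl_within_sd = vtl_within_sd,
    formant_bandwidths = formant_bandwidths,
    am_rate = am_rate, am_rate_sd = am_rate_sd,
    am_depth = am_depth, am_depth_sd = am_depth_sd,
    duration_mean = duration_mean, duration_sd = duration_sd,
    snr_db = snr_db, snr_sd = snr_sd,
    song_grammar = song_grammar), class = "voice_profile")
}

# Gaussian draw truncated at +/- 3 SD.
rnorm_trunc3 <- function(n, mean = 0, sd = 1) {
  z <- stats::rnorm(n)
  z[z > 3] <- 3
  z[z < -3] <- -3
  mean + sd * z
}

# Realized per-call parameters, drawn from the profile's within-individual
# distributions (fixed draw order for reproducibility).
draw_call_params <- function(profile, dur = NULL) {
  base_f0 <- min(max(rnorm_trunc3(1, profile$f0_mean,
                                  profile$f0_within_sd), 160), 340)
  if (is.null(dur))
    dur <- max(0.1, rnorm_trunc3(1, profile$duration_mean,
                                 profile$duration_sd))
  list(
    base_f0 = base_f0, dur = dur,
    fm_rate = max(0.1, rnorm_trunc3(1, profile$fm_rate,
                                    profile$fm_rate_sd)),
    fm_extent = max(0, rnorm_trunc3(1, profile$fm_extent,
                                    profile$fm_extent_sd)),
    fm_phase = stats::runif(1, 0, 2 * pi),
    jitter = min(max(rnorm_trunc3(1, profile$jitter_level,
                                  profile$jitter_sd), 5e-4), 0.3),
    shimmer = min(max(rnorm_trunc3(1, profile$shimmer_level,
                                   profile$shimmer_sd), 5e-3), 0.8),
    vtl = max(5, rnorm_trunc3(1, profile$vtl, profile$vtl_within_sd)),
    am_rate = max(0.5, rnorm_trunc3(1, profile$am_rate,
                                    profile$am_rate_sd)),
    am_depth = min(max(rnorm_trunc3(1, profile$am_depth,
                                    profile$am_depth_sd), 0.02), 0.95),
    snr_db = if (is.finite(profile$snr_db))
      rnorm_trunc3(1, profile$snr_db, profile$snr_sd) else Inf
  )
}

# Intended (perturbation-free) f0 contour of one voiced unit.
intended_contour <- function(profile, cp, time_step = 0.002) {
  t <- seq(0, cp$dur, by = time_step)
  f <- cp$base_f0 +
    profile$start_offset +
    (profile$end_offset - profile$start_offset) * t / cp$dur +
    (cp$fm_extent / 2) * sin(2 * pi * cp$fm_rate * t + cp$fm_phase)
  f <- pmin(pmax(f, 152), 348)  # keep inside the tracker search band
  data.frame(time = t, f0 = f)
}

# Cycle boundaries, perturbed periods and per-pulse amplitudes for a
# contour. The sqrt(pi)/2 factor converts a target mean absolute
# consecutive difference (the local jitter/shimmer definition) into the SD
# of the underlying Gaussian perturbation.
draw_cycles <- function(f0_contour, jitter_level, shimmer_level, duration) {
  f0_at <- function(tt) {
    stats::approx(f0_contour$time, f0_contour$f0, xout = tt, rule = 2)$y
  }
  sd_j <- jitter_level * sqrt(pi) / 2
  sd_s <- shimmer_level * sqrt(pi) / 2
  t_k <- 0
  periods <- numeric(0)
  while (t_k[length(t_k)] < duration) {
    base <- 1 / f0_at(t_k[length(t_k)])
    Tk <- base * (1 + rnorm_trunc3(1, 0, sd_j))
    periods <- c(periods, Tk)
    t_k <- c(t_k, t_k[length(t_k)] + Tk)
  }
  amps <- pmax(0.05, 1 + rnorm_trunc3(length(periods) + 1L, 0, sd_s))
  list(boundaries = t_k, periods = periods, amplitudes = amps)
}

# Render the band-limited harmonic pulse train for a set of cycles.
# Harmonic amplitudes roll off as 1/h up to 45% of the sample rate; the
# per-pulse amplitude is applied in a window centred on its pulse so the
# rendered pulse peak carries that amplitude exactly.
render_cycles <- function(cycles, sample_rate, duration) {
  t_k <- cycles$boundaries
  periods <- cycles$periods
  n_cyc <- length(periods)
  n <- round(duration * sample_rate)
  ts <- (seq_len(n) - 1L) / sample_rate
  cyc <- findInterval(ts, t_k, rightmost.closed = FALSE)
  cyc[cyc < 1L] <- 1L
  cyc[cyc > n_cyc] <- n_cyc
  phase <- (ts - t_k[cyc]) / periods[cyc]
  f_inst <- 1 / periods[cyc]
  x <- numeric(n)
  h_max <- floor(0.45 * sample_rate / min(f_inst))
  for (h in seq_len(h_max)) {
    active <- h * f_inst < 0.45 * sample_rate
    x[active] <- x[active] + cos(2 * pi * h * phase[active]) / h
  }
  nearest_pulse <- cyc + as.integer(phase >= 0.5)  # 1 .. n_cyc + 1
  x <- x * cycles$amplitudes[nearest_pulse]
  0.9 * x / max(abs(x))
}

#' Synthesize a perturbed harmonic source signal
#'
#' Band-limited harmonic pulse train whose instantaneous period follows the
#' given f0 contour. Each cycle's period is perturbed multiplicatively by a
#' truncated Gaussian scaled so that the expected local jitter equals
#' `jitter_level`; per-pulse amplitudes are perturbed likewise for
#' `shimmer_level`. Harmonic amplitudes roll off as `1 / h` (a -6 dB/octave
#' source spectrum) up to 45% of the sample rate.
#'
#' @param f0_contour Data frame with `time` (s) and `f0` (Hz, all positive).
#' @param jitter_level,shimmer_level Target perturbation proportions.
#' @param sample_rate Output rate in Hz.
#' @param duration Signal duration in seconds (default: last contour time).
#' @return A [waveform()] (peak-normalized to 0.9), with the realized cycle
#'   periods and per-pulse amplitudes in attributes `cycle_periods` and
#'   `cycle_amplitudes`.
#' @export
synth_source <- function(f0_contour, jitter_level = 0, shimmer_level = 0,
                         sample_rate = 44100, duration = NULL) {
  if (nrow(f0_contour) == 0L) stop("empty f0 contour")
  if (any(f0_contour$f0 <= 0)) stop("contour f0 values must be positive")
  if (jitter_level >= 1) stop("jitter_level must be < 1")
  if (is.null(duration)) duration <- max(f0_contour$time)
  cycles <- draw_cycles(f0_contour, jitter_level, shimmer_level, duration)
  w <- waveform(render_cycles(cycles, sample_rate, duration), sample_rate)
  attr(w, "cycle_periods") <- cycles$periods
  attr(w, "cycle_amplitudes") <- cycles$amplitudes
  w
}

#' Apply a cascade of formant resonators
#'
#' Each formant is realized as a second-order all-pole resonator with pole
#' radius `exp(-pi B / sr)` at angle `2 pi F / sr`, normalized to unit gain
#' at its resonance; the resonators are applied in cascade.
#'
#' @param w A [waveform()].
#' @param formant_freqs Formant frequencies in Hz (all below Nyquist).
#' @param bandwidths Bandwidths in Hz, recycled to the number of formants.
#' @return The filtered [waveform()] (peak-normalized to 0.9). With an
#'   empty `formant_freqs` the input is returned unchanged.
#' @export
apply_formant_filter <- function(w, formant_freqs, bandwidths = 100) {
  if (length(formant_freqs) == 0L) return(w)
  sr <- w$sample_rate
  if (any(formant_freqs >= sr / 2))
    stop("formant at or above the Nyquist frequency")
  bandwidths <- rep_len(bandwidths, length(formant_freqs))
  x <- w$samples
  for (i in seq_along(formant_freqs)) {
    theta <- 2 * pi * formant_freqs[i] / sr
    r <- exp(-pi * bandwidths[i] / sr)
    a1 <- 2 * r * cos(theta)
    a2 <- -r^2
    # unit gain at resonance
    z <- exp(1i * theta)
    g <- Mod(1 - a1 / z - a2 / z^2)
    x <- as.numeric(stats::filter(g * x, c(a1, a2), method = "recursive"))
  }
  peak <- max(abs(x))
  if (peak > 0) x <- 0.9 * x / peak
  waveform(x, sr, w$call_id, w$individual_id)
}

# Render one voiced unit (a contact call or a type-1/2 syllable) from its
# realized call parameters: source -> formant cascade -> AM -> noise.
render_voiced <- function(profile, cp, contour, cycles, sample_rate) {
  src <- render_cycles(cycles, sample_rate, cp$dur)
  nf <- max(4L, ceiling(sample_rate / 2 / (35000 / (2 * cp$vtl))) - 1L)
  freqs <- formants_from_vtl(cp$vtl, nf)
  freqs <- freqs[freqs < 0.45 * sample_rate]
  w <- apply_formant_filter(waveform(src, sample_rate), freqs,
                            rep_len(profile$formant_bandwidths,
                                    length(freqs)))
  ts <- (seq_along(w$samples) - 1L) / sample_rate
  am <- 1 + cp$am_depth * sin(2 * pi * cp$am_rate * ts)
  x <- w$samples * am
  if (is.finite(cp$snr_db)) {
    p_sig <- mean(x^2)
    x <- x + stats::rnorm(length(x), 0,
                          sqrt(p_sig / 10^(cp$snr_db / 10)))
  }
  0.9 * x / max(abs(x))
}

# Ground-truth feature values of one voiced unit from its realized
# parameters and cycles.
spectral_ground_truth <- function(cp, contour, cycles) {
  out <- f0_statistics(contour, cp$dur)
  out <- c(out, fm_statistics(contour))
  out$Jitter <- mean(abs(diff(cycles$periods))) / mean(cycles$periods)
  out$Shimmer <- mean(abs(diff(cycles$amplitudes))) /
    mean(cycles$amplitudes)
  out$Sonority <- min(cp$snr_db, 40)
  fm <- formants_from_vtl(cp$vtl, 4)
  out$F1Mean <- fm[1L]; out$F2Mean <- fm[2L]
  out$F3Mean <- fm[3L]; out$F4Mean <- fm[4L]
  out$deltaF <- 35000 / (2 * cp$vtl)
  out$VTLest <- cp$vtl
  out
}

am_ground_truth <- function(cp) {
  pp_db <- 20 * log10((1 + cp$am_depth) / max(1 - cp$am_depth, 1e-6))
  list(AMRate = cp$am_rate, AMExtent = pp_db,
       AmpVar = 2 * pp_db * cp$am_rate)
}

#' Synthesize one contact call
#'
#' Draws the call's realized parameters (duration, base f0, modulation,
#' perturbation levels, vocal tract length, noise level) from the profile's
#' within-individual distributions, renders the perturbed harmonic source
#' through the vocal-tract resonator cascade, applies amplitude modulation
#' and additive noise, and returns the call with its ground-truth feature
#' vector (the realized values of all 24 contact-call parameters). Consumes
#' the current RNG stream: seed before calling for reproducibility.
#'
#' @param profile A [voice_profile()].
#' @param sample_rate Output rate in Hz (default 44100).
#' @param call_id Label for the call.
#' @param render If `FALSE`, skip audio rendering and return only the
#'   ground truth (fast path for statistical simulations).
#' @return List with `waveform` (`NULL` when `render = FALSE`) and
#'   `ground_truth` (one-row data frame).
#' @export
synth_contact_call <- function(profile, sample_rate = 44100,
                               call_id = "call", render = TRUE) {
  cp <- draw_call_params(profile)
  contour <- intended_contour(profile, cp)
  cycles <- draw_cycles(contour, cp$jitter, cp$shimmer, cp$dur)
  w <- NULL
  if (render) {
    x <- render_voiced(profile, cp, contour, cycles, sample_rate)
    w <- waveform(x, sample_rate, call_id, profile$individual_id)
  }
  gt <- spectral_ground_truth(cp, contour, cycles)
  gt <- c(gt, am_ground_truth(cp), list(Dur = cp$dur))
  gt_df <- cbind(data.frame(call_id = call_id,
                            individual_id = profile$individual_id,
                            stringsAsFactors = FALSE),
                 as.data.frame(gt[contact_feature_names]))
  list(waveform = w, ground_truth = gt_df)
}

draw_count <- function(mean, sd, min = 0L) {
  max(min, as.integer(round(rnorm_trunc3(1, mean, sd))))
}

#' Synthesize one ecstatic display song
#'
#' Builds a syllable sequence from the profile's `song_grammar`: a run of
#' short voiced type-1 syllables, then alternating long voiced type-2
#' syllables (which carry the spectral ground truth) and unvoiced,
#' inhalation-like type-3 noise bursts, separated by gaps. Returns the
#' waveform, the exact syllable annotations, and the ground-truth feature
#' vector; syllable counts and duration sums in the ground truth equal
#' those recomputable from the annotations.
#'
#' @param profile A [voice_profile()] with a `song_grammar`.
#' @param sample_rate Output rate in Hz (default 44100).
#' @param call_id Label for the song.
#' @param render If `FALSE`, skip audio rendering (annotations and ground
#'   truth are still produced).
#' @return List with `waveform`, `annotations` (data frame in the
#'   [read_annotations()] dialect) and `ground_truth`.
#' @export
synth_display_song <- function(profile, sample_rate = 44100,
                               call_id = "song", render = TRUE) {
  g <- profile$song_grammar
  if (is.null(g)) stop("profile has no song_grammar")
  if (g$n_type2 <= 0 && (is.null(g$n_type2_sd) || g$n_type2_sd <= 0))
    stop("grammar must allow at least one type-2 syllable")
  n1 <- draw_count(g$n_type1, g$n_type1_sd)
  n2 <- draw_count(g$n_type2, g$n_type2_sd, min = 1L)
  n3 <- draw_count(g$n_type3, g$n_type3_sd)
  alt <- as.integer(t(cbind(rep(2L, max(n2, n3)), rep(3L, max(n2, n3)))))
  keep2 <- cumsum(alt == 2L) <= n2
  keep3 <- cumsum(alt == 3L) <= n3
  types <- c(rep(1L, n1),
             alt[(alt == 2L & keep2) | (alt == 3L & keep3)])

  pieces <- list()
  ann <- data.frame(call_id = character(0), onset_s = numeric(0),
                    offset_s = numeric(0), type = integer(0),
                    stringsAsFactors = FALSE)
  t_cursor <- 0
  type2_gt <- list()
  for (ty in types) {
    if (ty == 2L) {
      cp <- draw_call_params(profile)
      cp$dur <- max(0.2, cp$dur)
      dur <- round(cp$dur * sample_rate) / sample_rate
      cp$dur <- dur
      contour <- intended_contour(profile, cp)
      cycles <- draw_cycles(contour, cp$jitter, cp$shimmer, dur)
      type2_gt <- c(type2_gt,
                    list(spectral_ground_truth(cp, contour, cycles)))
      if (render)
        pieces <- c(pieces, list(render_voiced(profile, cp, contour,
                                               cycles, sample_rate)))
    } else if (ty == 1L) {
      cp <- draw_call_params(profile,
                             dur = max(0.05,
                                       rnorm_trunc3(1, g$dur_type1,
                                                    g$dur_type1_sd)))
      dur <- round(cp$dur * sample_rate) / sample_rate
      cp$dur <- dur
      contour <- intended_contour(profile, cp)
      cycles <- draw_cycles(contour, cp$jitter, cp$shimmer, dur)
      if (render)
        pieces <- c(pieces, list(render_voiced(profile, cp, contour,
                                               cycles, sample_rate)))
    } else {
      dur <- max(0.05, rnorm_trunc3(1, g$dur_type3, g$dur_type3_sd))
      n_samp <- round(dur * sample_rate)
      dur <- n_samp / sample_rate
      if (render) {
        # unvoiced inhalation: formant-filtered noise burst
        noise <- waveform(stats::rnorm(n_samp), sample_rate)
        freqs <- formants_from_vtl(profile$vtl, 4)
        syl <- apply_formant_filter(noise, freqs,
                                    rep_len(profile$formant_bandwidths, 4))
        env <- sin(pi * seq(0, 1, length.out = n_samp))
        pieces <- c(pieces, list(0.4 * syl$samples * env))
      } else {
        stats::rnorm(1)  # keep draw order comparable across song shapes
      }
    }
    ann <- rbind(ann, data.frame(call_id = call_id, onset_s = t_cursor,
                                 offset_s = t_cursor + dur, type = ty,
                                 stringsAsFactors = FALSE))
    gap <- max(0.02, rnorm_trunc3(1, g$gap_mean, g$gap_sd))
    gap_n <- round(gap * sample_rate)
    if (render) pieces <- c(pieces, list(numeric(gap_n)))
    t_cursor <- t_cursor + dur + gap_n / sample_rate
  }
  w <- NULL
  if (render) {
    pieces[[length(pieces)]] <- NULL  # drop the trailing gap
    x <- unlist(pieces)
    if (is.finite(profile$snr_db)) {
      p_sig <- mean(x^2)
      x <- x + stats::rnorm(length(x), 0,
                            sqrt(p_sig / 10^(profile$snr_db / 10)))
    }
    x <- 0.9 * x / max(abs(x))
    w <- waveform(x, sample_rate, call_id, profile$individual_id)
    total_dur <- duration(w)
  } else {
    total_dur <- ann$offset_s[nrow(ann)]
  }

  # ground truth: spectral values averaged over the type-2 syllables
  spec <- lapply(names(type2_gt[[1L]]), function(nm) {
    mean(vapply(type2_gt, function(s) s[[nm]], 0))
  })
  names(spec) <- names(type2_gt[[1L]])
  syl <- syllable_structure(ann)
  amr <- max(0.5, rnorm_trunc3(1, profile$am_rate, profile$am_rate_sd))
  amd <- min(max(rnorm_trunc3(1, profile$am_depth, profile$am_depth_sd),
                 0.02), 0.95)
  gt <- c(spec, am_ground_truth(list(am_rate = amr, am_depth = amd)),
          list(Dur = total_dur), syl)
  gt_df <- cbind(data.frame(call_id = call_id,
                            individual_id = profile$individual_id,
                            stringsAsFactors = FALSE),
                 as.data.frame(gt[song_feature_names]))
  list(waveform = w, annotations = ann, ground_truth = gt_df)
}

#' Colony configuration for the synthesizer
#'
#' @param profiles List of [voice_profile()]s with distinct ids (>= 2).
#' @param calls_per_individual Single count or one per profile (>= 2 each:
#'   within-individual variation needs at least two calls).
#' @param call_type `"contact"` or `"song"`.
#' @param seed Mandatory integer seed; identical configurations produce
#'   bit-identical colonies.
#' @param sample_rate Output rate in Hz (default 44100, the field-recording
#'   rate this pipeline models).
#' @param audio If `FALSE`, [generate_colony()] skips audio rendering and
#'   returns only annotations and the ground-truth table.
#' @return List of class `colony_config`.
#' @export
colony_config <- function(profiles, calls_per_individual, call_type =
                            c("contact", "song"), seed,
                          sample_rate = 44100, audio = TRUE) {
  call_type <- match.arg(call_type)
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  ids <- vapply(profiles, function(p) as.character(p$individual_id), "")
  if (anyDuplicated(ids)) stop("duplicate individual_ids")
  counts <- rep_len(as.integer(calls_per_individual), length(profiles))
  if (any(counts < 2L)) stop("calls_per_individual must be >= 2")
  if (missing(seed)) stop("seed is mandatory")
  structure(list(profiles = profiles, calls_per_individual = counts,
                 call_type = call_type, seed = as.integer(seed),
                 sample_rate = sample_rate, audio = isTRUE(audio)),
            class = "colony_config")
}

#' Generate a labelled synthetic colony
#'
#' Synthesizes `calls_per_individual` calls (or songs) for every profile in
#' the configuration, under the configuration's seed. The ground-truth
#' feature table contains the realized parameter values of every call and
#' is directly usable as input to [pic_table()] and [classify_calls()],
#' which allows the statistical pipeline to be exercised independently of
#' the signal-processing stages (set `audio = FALSE` in the configuration
#' for this use).
#'
#' @param config A [colony_config()].
#' @return List with `waveforms` (list of [waveform()]s; `NULL`s when
#'   `audio = FALSE`), `annotations` (data frame; empty for contact
#'   colonies) and `ground_truth` (feature table, one row per call).
#' @export
generate_colony <- function(config) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  waves <- list()
  anns <- list()
  gts <- list()
  for (i in seq_along(config$profiles)) {
    p <- config$profiles[[i]]
    for (j in seq_len(config$calls_per_individual[i])) {
      cid <- sprintf("%s__%03d", p$individual_id, j)
      if (config$call_type == "contact") {
        s <- synth_contact_call(p, config$sample_rate, cid,
                                render = config$audio)
      } else {
        s <- synth_display_song(p, config$sample_rate, cid,
                                render = config$audio)
        anns <- c(anns, list(s$annotations))
      }
      if (config$audio) waves <- c(waves, list(s$waveform))
      gts <- c(gts, list(s$ground_truth))
    }
  }
  ann <- if (length(anns) > 0L) do.call(rbind, anns) else
    data.frame(call_id = character(0), onset_s = numeric(0),
               offset_s = numeric(0), type = integer(0))
  list(waveforms = waves, annotations = ann,
       ground_truth = do.call(rbind, gts))
}

# Build profiles from a long summary table (parameter/individual_id/mean).
profiles_from_summaries <- function(summ, call_type, snr_db = 25) {
  val <- function(ind, par) {
    summ$mean[summ$individual_id == ind & summ$parameter == par]
  }
  sdv <- function(ind, par) {
    summ$sd[summ$individual_id == ind & summ$parameter == par]
  }
  lapply(unique(summ$individual_id), function(ind) {
    f0m <- val(ind, "f0Mean")
    grammar <- NULL
    if (call_type == "song") {
      n1 <- val(ind, "Type1"); n3 <- val(ind, "Type3")
      grammar <- list(
        n_type1 = n1, n_type1_sd = sdv(ind, "Type1"),
        n_type2 = val(ind, "Type2"), n_type2_sd = sdv(ind, "Type2"),
        n_type3 = n3, n_type3_sd = sdv(ind, "Type3"),
        dur_type1 = val(ind, "SumType1") / max(n1, 1),
        dur_type1_sd = 0.05,
        dur_type3 = val(ind, "SumType3") / max(n3, 1),
        dur_type3_sd = 0.1,
        gap_mean = 0.15, gap_sd = 0.05)
    }
    dur_par <- if (call_type == "song") "DurType2" else "Dur"
    voice_profile(
      individual_id = ind, f0_mean = f0m,
      f0_within_sd = sdv(ind, "f0Mean"),
      start_offset = val(ind, "f0Start") - f0m,
      end_offset = val(ind, "f0End") - f0m,
      fm_rate = val(ind, "FMRate"), fm_rate_sd = sdv(ind, "FMRate"),
      fm_extent = val(ind, "FMExtent"),
      fm_extent_sd = sdv(ind, "FMExtent"),
      jitter_level = val(ind, "Jitter"), jitter_sd = sdv(ind, "Jitter"),
      shimmer_level = val(ind, "Shimmer"),
      shimmer_sd = sdv(ind, "Shimmer"),
      vtl = val(ind, "VTLest"), vtl_within_sd = sdv(ind, "VTLest"),
      am_rate = val(ind, "AMRate"), am_rate_sd = sdv(ind, "AMRate"),
      am_depth = 0.3,
      duration_mean = val(ind, dur_par),
      duration_sd = sdv(ind, dur_par),
      snr_db = snr_db, snr_sd = sdv(ind, "Sonority"),
      song_grammar = grammar)
  })
}

#' Default voice profiles for the packaged reference colony
#'
#' Voice profiles transcribed from the packaged per-individual summary
#' statistics of a captive African penguin colony (six contact-call birds,
#' seven display-song birds): each bird's mean f0 and its SD, contour
#' offsets, modulation rates and SDs, jitter/shimmer levels, vocal tract
#' length and durations are taken from the summary tables; quantities the
#' tables do not determine (formant bandwidths, AM depth, noise level,
#' inter-syllable gaps) use the synthesizer defaults.
#'
#' @param call_type `"contact"` or `"song"`.
#' @param snr_db Signal-to-noise ratio applied to every profile
#'   (default 25).
#' @return List of [voice_profile()]s with the colony's group sizes in
#'   attribute `group_sizes`.
#' @export
default_profiles <- function(call_type = c("contact", "song"), snr_db = 25) {
  call_type <- match.arg(call_type)
  summ <- load_summary_table(call_type)
  profs <- profiles_from_summaries(summ, call_type, snr_db)
  ids <- vapply(profs, function(p) p$individual_id, "")
  n <- vapply(ids, function(i) summ$n[summ$individual_id == i][1L], 0)
  attr(profs, "group_sizes") <- stats::setNames(as.integer(n), ids)
  profs
}
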