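## Source-related feature extraction: f0 contour by normalized
## cross-correlation, contour statistics, FM cycle analysis, cycle-level
## pulses, jitter, shimmer and harmonics-to-noise ratio.

#' Pitch tracker settings
#'
#' Defaults follow the analysis protocol for penguin calls: a 0.01 s time
#' step and a 150-350 Hz search band, which brackets the fundamental of both
#' contact calls and display songs. The voicing threshold and octave cost
#' are tracker tuning constants (the correlation a frame must reach to count
#' as voiced, and the per-octave penalty discouraging subharmonic picks).
#'
#' @param time_step Frame step in seconds (default 0.01).
#' @param floor,ceiling Pitch search band in Hz (defaults 150 and 350).
#' @param voicing_threshold Minimum normalized correlation for a voiced
#'   frame (default 0.45).
#' @param octave_cost Penalty per octave below the ceiling (default 0.01).
#' @return List of class `pitch_settings`.
#' @export
pitch_settings <- function(time_step = 0.01, floor = 150, ceiling = 350,
                           voicing_threshold = 0.45, octave_cost = 0.01) {
  if (time_step <= 0) stop("time_step must be positive")
  if (floor <= 0 || ceiling <= floor) stop("need 0 < floor < ceiling")
  structure(list(time_step = time_step, floor = floor, ceiling = ceiling,
                 voicing_threshold = voicing_threshold,
                 octave_cost = octave_cost),
            class = "pitch_settings")
}

#' Track the fundamental frequency contour
#'
#' Framewise normalized cross-correlation over candidate lags spanning the
#' search band, with a window of three floor periods. Within each frame,
#' local correlation maxima are candidates; the winner maximizes correlation
#' minus an octave cost proportional to the candidate's distance (in
#' octaves) below the ceiling, which suppresses subharmonic errors. Frames
#' whose best correlation falls below the voicing threshold are marked
#' unvoiced (`NA`). The voiced track is median-smoothed over 3 points.
#' Candidate lags are refined by parabolic interpolation, so tracked
#' frequencies are not quantized to the sample grid.
#'
#' @param w A [waveform()] of duration at least `3 / floor` seconds.
#' @param settings A [pitch_settings()].
#' @return A data frame of class `pitch_contour`: columns `time` (s, frame
#'   centres at `time_step` spacing) and `f0` (Hz, `NA` when unvoiced),
#'   with the settings stored in attribute `settings`.
#' @export
track_f0 <- function(w, settings = pitch_settings()) {
  sr <- w$sample_rate
  x <- w$samples
  win <- round(3 / settings$floor * sr)
  if (length(x) < win) stop("signal shorter than one analysis window")
  lag_min <- max(2L, floor(sr / settings$ceiling))
  lag_max <- ceiling(sr / settings$floor)
  step <- max(1L, round(settings$time_step * sr))
  starts <- seq(1L, length(x) - win + 1L, by = step)
  times <- (starts - 1L + win / 2) / sr
  f0 <- rep(NA_real_, length(starts))

  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + win - 1L)]
    seg <- seg - mean(seg)
    if (sum(seg^2) == 0) next
    # normalized autocorrelation over the lag band
    n <- length(seg)
    ac <- numeric(lag_max)
    e0 <- cumsum(seg^2)
    for (lag in lag_min:lag_max) {
      a <- seg[1:(n - lag)]
      b <- seg[(lag + 1):n]
      denom <- sqrt(sum(a^2) * sum(b^2))
      ac[lag] <- if (denom > 0) sum(a * b) / denom else 0
    }
    lags <- lag_min:lag_max
    r <- ac[lags]
    # local maxima as candidates
    cand <- which(diff(sign(diff(r))) < 0) + 1L
    if (length(cand) == 0L) cand <- which.max(r)
    freqs <- sr / lags[cand]
    score <- r[cand] - settings$octave_cost *
      log2(settings$ceiling / freqs)
    best <- cand[which.max(score)]
    if (r[best] < settings$voicing_threshold) next
    # parabolic refinement of the correlation peak
    lag_hat <- lags[best]
    if (best > 1L && best < length(r)) {
      y1 <- r[best - 1L]; y2 <- r[best]; y3 <- r[best + 1L]
      den <- y1 - 2 * y2 + y3
      if (den < 0) lag_hat <- lags[best] + 0.5 * (y1 - y3) / den
    }
    f <- sr / lag_hat
    if (f >= settings$floor && f <= settings$ceiling) f0[k] <- f
  }

  voiced <- which(!is.na(f0))
  if (length(voiced) >= 3L)
    f0[voiced] <- stats::runmed(f0[voiced], 3L)
  structure(data.frame(time = times, f0 = f0),
            settings = settings, class = c("pitch_contour", "data.frame"))
}

#' Contour statistics of the fundamental frequency
#'
#' Computes the f0 summary statistics of a call from its tracked contour:
#' start/end/mean/min/max frequency, the times of the extrema as a
#' percentage of call duration (first occurrence on ties), the mean absolute
#' slope between adjacent voiced frames, and the cumulative variation per
#' second (f0Var). Unvoiced gaps are skipped; slopes use the actual time
#' difference across gaps.
#'
#' @param contour A `pitch_contour` from [track_f0()] (or any data frame
#'   with `time` and `f0` columns, `NA` marking unvoiced frames).
#' @param duration Call duration in seconds.
#' @return Named list: `f0Start`, `f0End`, `f0Mean`, `f0Min`, `f0Max`,
#'   `Timef0Min`, `Timef0Max` (percent), `f0AbsSlope`, `f0Var` (Hz/s).
#' @export
f0_statistics <- function(contour, duration) {
  v <- which(!is.na(contour$f0))
  if (length(v) < 2L) stop("need at least 2 voiced frames")
  f <- contour$f0[v]
  t <- contour$time[v]
  dt <- diff(t)
  df <- diff(f)
  t0 <- t[1L]
  list(
    f0Start = f[1L], f0End = f[length(f)],
    f0Mean = mean(f), f0Min = min(f), f0Max = max(f),
    Timef0Min = 100 * (t[which.min(f)] - t0) / duration,
    Timef0Max = 100 * (t[which.max(f)] - t0) / duration,
    f0AbsSlope = mean(abs(df) / dt),
    f0Var = sum(abs(df)) / duration
  )
}

# Detrended mean-crossing cycle analysis shared by FM and AM statistics.
# A complete cycle spans consecutive upward crossings of the mean of the
# detrended series. Crossings are detected with hysteresis (a Schmitt
# trigger at +/- half the minimum extent) so that measurement ripple far
# smaller than a meaningful modulation never registers as cycles.
crossing_cycles <- function(t, y, min_extent = 0) {
  fit <- stats::lm.fit(cbind(1, t), y)
  d <- y - fit$fitted.values
  h <- min_extent / 2
  state <- 0L  # -1 below, +1 above, 0 undecided
  up <- integer(0)
  for (i in seq_along(d)) {
    if (d[i] > h) {
      if (state == -1L) up <- c(up, i)
      state <- 1L
    } else if (d[i] < -h) {
      state <- -1L
    }
  }
  cycles <- list()
  if (length(up) >= 2L) {
    for (j in seq_len(length(up) - 1L)) {
      cycles[[j]] <- up[j]:(up[j + 1L] - 1L)
    }
  }
  list(detrended = d, cycles = cycles, crossings = up)
}

#' Frequency modulation statistics
#'
#' The contour is detrended by a least-squares line; a complete modulation
#' cycle spans consecutive upward crossings of the detrended mean. FMRate is
#' the number of cycles per second of voiced time; FMExtent the mean
#' peak-to-peak excursion within a cycle. A contour with no complete cycle
#' yields (0, 0).
#'
#' @param contour A `pitch_contour` with at least 4 voiced frames.
#' @param min_extent Smallest peak-to-peak excursion (Hz) that counts as a
#'   modulation cycle (default 1); excursions below it are treated as
#'   tracking ripple.
#' @param total_variation If `TRUE`, additionally return the variant that
#'   divides the total modulation excursion by the modulation rate.
#' @return Named list `FMRate` (cycles/s), `FMExtent` (Hz), and (when
#'   requested) `FMExtentTotalVar`.
#' @export
fm_statistics <- function(contour, min_extent = 1, total_variation = FALSE) {
  v <- which(!is.na(contour$f0))
  if (length(v) < 4L) stop("need at least 4 voiced frames")
  t <- contour$time[v]
  f <- contour$f0[v]
  cc <- crossing_cycles(t, f, min_extent)
  # rate over the span the counted cycles actually occupy: robust to the
  # modulation phase at the call edges
  span <- if (length(cc$cycles) > 0L) {
    t[cc$crossings[length(cc$crossings)]] - t[cc$crossings[1L]]
  } else 0
  if (length(cc$cycles) == 0L || span <= 0) {
    out <- list(FMRate = 0, FMExtent = 0)
    if (total_variation) out$FMExtentTotalVar <- 0
    return(out)
  }
  rate <- length(cc$cycles) / span
  extents <- vapply(cc$cycles, function(idx) {
    diff(range(cc$detrended[idx]))
  }, 0)
  out <- list(FMRate = rate, FMExtent = mean(extents))
  if (total_variation)
    out$FMExtentTotalVar <- sum(abs(diff(f))) / rate
  out
}

#' Extract glottal/syringeal pulses from a waveform
#'
#' Cycle-level representation needed by the jitter and shimmer definitions:
#' starting from the strongest peak in the first voiced period, each next
#' pulse is the largest absolute waveform peak in a window centred one local
#' period (interpolated from the contour) after the previous pulse. Pulse
#' times are refined by parabolic interpolation of the absolute peak.
#'
#' @param w A [waveform()].
#' @param contour The `pitch_contour` of `w` with voiced frames.
#' @return List of class `pulse_train`: `pulse_times` (s, strictly
#'   increasing), `cycle_periods` (s, successive differences) and
#'   `cycle_peak_amplitudes` (peak absolute sample per cycle).
#' @export
extract_pulses <- function(w, contour) {
  v <- which(!is.na(contour$f0))
  if (length(v) == 0L) stop("contour has no voiced frames")
  sr <- w$sample_rate
  x <- w$samples
  t_v <- contour$time[v]
  f_v <- contour$f0[v]
  period_at <- function(tt) {
    1 / stats::approx(t_v, f_v, xout = tt, rule = 2)$y
  }
  t_start <- t_v[1L]
  t_end <- t_v[length(t_v)] + period_at(t_v[length(t_v)])
  if (t_end - t_start < 2 * period_at(t_start))
    stop("voiced region shorter than two periods")

  refine <- function(i) {
    if (i <= 1L || i >= length(x)) return(as.numeric(i))
    y1 <- abs(x[i - 1L]); y2 <- abs(x[i]); y3 <- abs(x[i + 1L])
    den <- y1 - 2 * y2 + y3
    if (den < 0) i + 0.5 * (y1 - y3) / den else as.numeric(i)
  }

  # first pulse: strongest peak within one period of the voiced onset
  i0 <- max(1L, round(t_start * sr))
  i1 <- min(length(x), i0 + round(period_at(t_start) * sr))
  seg <- abs(x[i0:i1])
  p <- i0 + which.max(seg) - 1L
  pulses <- refine(p) / sr
  repeat {
    t_prev <- pulses[length(pulses)]
    T_loc <- period_at(t_prev)
    centre <- t_prev + T_loc
    if (centre > t_end) break
    half <- T_loc / 3
    j0 <- max(1L, round((centre - half) * sr))
    j1 <- min(length(x), round((centre + half) * sr))
    if (j1 <= j0) break
    p <- j0 + which.max(abs(x[j0:j1])) - 1L
    t_new <- refine(p) / sr
    if (t_new <= t_prev) break
    pulses <- c(pulses, t_new)
  }
  if (length(pulses) < 3L) stop("too few pulses in voiced region")
  periods <- diff(pulses)
  # cycle amplitude: peak magnitude of the cycle's own pulse, a quarter
  # period around it (avoids attributing the next pulse's peak to this cycle)
  amps <- vapply(seq_len(length(pulses) - 1L), function(k) {
    half <- round(periods[k] / 4 * sr)
    j0 <- max(1L, round(pulses[k] * sr) - half)
    j1 <- min(length(x), round(pulses[k] * sr) + half)
    max(abs(x[j0:j1]))
  }, 0)
  structure(list(pulse_times = pulses, cycle_periods = periods,
                 cycle_peak_amplitudes = amps),
            class = "pulse_train")
}

#' Local jitter
#'
#' Mean absolute difference between consecutive cycle periods divided by the
#' mean period — the cycle-to-cycle perturbation of the fundamental
#' frequency, returned as a proportion.
#'
#' @param pulses A `pulse_train` with at least 3 cycles.
#' @return Non-negative proportion.
#' @export
jitter_local <- function(pulses) {
  p <- pulses$cycle_periods
  if (length(p) < 3L) stop("jitter needs at least 3 cycles")
  mean(abs(diff(p))) / mean(p)
}

#' Local shimmer
#'
#' Mean absolute difference between consecutive cycle peak amplitudes
#' divided by the mean amplitude, returned as a proportion.
#'
#' @param pulses A `pulse_train` with at least 3 cycles.
#' @return Non-negative proportion.
#' @export
shimmer_local <- function(pulses) {
  a <- pulses$cycle_peak_amplitudes
  if (length(a) < 3L) stop("shimmer needs at least 3 cycles")
  if (all(a == 0)) stop("all-zero amplitudes")
  mean(abs(diff(a))) / mean(a)
}

#' Harmonics-to-noise ratio (Sonority)
#'
#' Per voiced frame, the normalized autocorrelation `r` at the lag of the
#' frame's tracked period estimates the fraction of periodic energy; the
#' frame HNR is `10 log10(r / (1 - r))` with `r` clamped to
#' `[1e-6, 1 - 1e-6]`. Sonority is the mean over voiced frames, in dB.
#'
#' @param w A [waveform()].
#' @param contour Its `pitch_contour` with at least one voiced frame.
#' @return Mean HNR in dB.
#' @export
harmonics_to_noise <- function(w, contour) {
  v <- which(!is.na(contour$f0))
  if (length(v) == 0L) stop("no voiced frames")
  sr <- w$sample_rate
  x <- w$samples
  settings <- attr(contour, "settings")
  floor_hz <- if (is.null(settings)) 150 else settings$floor
  win <- round(3 / floor_hz * sr)
  hnr <- vapply(v, function(k) {
    centre <- contour$time[k]
    i0 <- max(1L, round(centre * sr - win / 2))
    i1 <- min(length(x), i0 + win - 1L)
    seg <- x[i0:i1] - mean(x[i0:i1])
    lag <- round(sr / contour$f0[k])
    n <- length(seg)
    if (lag + 1L >= n || sum(seg^2) == 0) return(NA_real_)
    rho <- function(l) {
      a <- seg[1:(n - l)]
      b <- seg[(l + 1):n]
      denom <- sqrt(sum(a^2) * sum(b^2))
      if (denom > 0) sum(a * b) / denom else 0
    }
    # parabolic interpolation over adjacent lags: the true period rarely
    # falls on the sample grid, and the misalignment penalizes r heavily
    # for pulse-like signals
    r3 <- c(rho(max(lag - 1L, 1L)), rho(lag), rho(lag + 1L))
    den <- r3[1L] - 2 * r3[2L] + r3[3L]
    r <- if (den < 0) r3[2L] - (r3[1L] - r3[3L])^2 / (8 * den) else max(r3)
    r <- min(max(r, 1e-6), 1 - 1e-6)
    10 * log10(r / (1 - r))
  }, 0)
  mean(hnr, na.rm = TRUE)
}

#' All source-related statistics of a call
#'
#' Convenience wrapper running [track_f0()], [f0_statistics()],
#' [fm_statistics()], [extract_pulses()], [jitter_local()],
#' [shimmer_local()] and [harmonics_to_noise()] on one waveform.
#'
#' @param w A [waveform()].
#' @param settings A [pitch_settings()].
#' @return Named list of the 14 source-related parameters (f0Start ...
#'   Sonority).
#' @export
source_stats <- function(w, settings = pitch_settings()) {
  contour <- track_f0(w, settings)
  dur <- duration(w)
  out <- f0_statistics(contour, dur)
  out <- c(out, fm_statistics(contour))
  pulses <- extract_pulses(w, contour)
  out$Jitter <- jitter_local(pulses)
  out$Shimmer <- shimmer_local(pulses)
  out$Sonority <- harmonics_to_noise(w, contour)
  out
}
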