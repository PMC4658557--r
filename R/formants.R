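## Filter-related feature extraction: Burg LPC formant tracking,
## octave-jump correction, formant means, formant dispersion (delta F) and
## vocal tract length estimation.

#' Formant tracker settings
#'
#' Defaults follow the penguin analysis protocol: a 0.045 s time step, five
#' formants, and a formant ceiling of 3500 Hz for contact calls or 4000 Hz
#' for display songs (anatomical vocal-tract models of this species place
#' five formants below those ceilings). Window length, pre-emphasis and LPC
#' order follow common formant-analysis practice.
#'
#' @param time_step Frame step in seconds (default 0.045).
#' @param max_formants Number of formants tracked (default 5; the fifth
#'   stabilizes the fit and is not reported).
#' @param ceiling Formant ceiling in Hz; use 3500 for contact calls,
#'   4000 for display songs.
#' @param window_length Analysis window in seconds (default 0.025).
#' @param pre_emphasis_from Pre-emphasis corner frequency in Hz (default 50).
#' @param lpc_order Burg autoregression order (default
#'   `2 * max_formants + 2`).
#' @return List of class `formant_settings`.
#' @export
formant_settings <- function(time_step = 0.045, max_formants = 5,
                             ceiling = 3500, window_length = 0.025,
                             pre_emphasis_from = 50, lpc_order = NULL) {
  if (ceiling <= 0) stop("ceiling must be positive")
  if (max_formants < 1) stop("max_formants must be >= 1")
  if (is.null(lpc_order)) lpc_order <- 2L * max_formants + 2L
  if (lpc_order < 2 * max_formants)
    stop("lpc_order must be at least 2 * max_formants")
  structure(list(time_step = time_step, max_formants = max_formants,
                 ceiling = ceiling, window_length = window_length,
                 pre_emphasis_from = pre_emphasis_from,
                 lpc_order = lpc_order),
            class = "formant_settings")
}

#' Track formant frequencies by Burg LPC
#'
#' The waveform is resampled to twice the formant ceiling, pre-emphasized by
#' a first difference above the pre-emphasis frequency, and analyzed in
#' Gaussian-windowed frames. Each frame is fitted with a Burg
#' autoregression; roots of the prediction polynomial with positive
#' imaginary part give candidate (frequency, bandwidth) pairs. Candidates
#' with 50 Hz < frequency < ceiling and bandwidth < 700 Hz are kept, and the
#' lowest `max_formants` are reported per frame, sorted by frequency.
#'
#' @param w A [waveform()] at least one window long.
#' @param settings A [formant_settings()].
#' @return A `formant_track`: list with `times` (frame centres, s),
#'   `frequencies` and `bandwidths` (frames x max_formants matrices, `NA`
#'   where fewer candidates exist), and the settings.
#' @export
track_formants <- function(w, settings = formant_settings()) {
  if (duration(w) < settings$window_length)
    stop("waveform shorter than one analysis window")
  target_sr <- 2 * settings$ceiling
  ws <- if (w$sample_rate > target_sr) resample_wave(w, target_sr) else w
  sr <- ws$sample_rate
  x <- ws$samples
  # first-difference pre-emphasis: y[n] = x[n] - a x[n-1]
  a <- exp(-2 * pi * settings$pre_emphasis_from / sr)
  x <- c(x[1L], x[-1L] - a * x[-length(x)])

  win <- round(settings$window_length * sr)
  step <- max(1L, round(settings$time_step * sr))
  if (win <= settings$lpc_order)
    stop("analysis frame shorter than the LPC order")
  gw <- exp(-0.5 * ((seq_len(win) - (win + 1) / 2) / (win / 6))^2)
  starts <- seq(1L, max(1L, length(x) - win + 1L), by = step)
  nf <- settings$max_formants
  freqs <- matrix(NA_real_, length(starts), nf)
  bands <- matrix(NA_real_, length(starts), nf)

  for (k in seq_along(starts)) {
    seg <- x[starts[k]:min(length(x), starts[k] + win - 1L)]
    if (length(seg) <= settings$lpc_order) next
    seg <- (seg - mean(seg)) * gw[seq_along(seg)]
    if (sum(seg^2) == 0) next
    fit <- tryCatch(
      stats::ar.burg(seg, aic = FALSE, order.max = settings$lpc_order,
                     demean = FALSE),
      error = function(e) NULL)
    if (is.null(fit) || length(fit$ar) == 0L) next
    # polyroot works in u = z^-1: poles are z = 1/u, radius 1/Mod(u)
    rts <- polyroot(c(1, -fit$ar))
    ang <- Arg(rts)
    keep <- ang > 0
    f <- ang[keep] * sr / (2 * pi)
    bw <- log(Mod(rts[keep])) * sr / pi
    ok <- f > 50 & f < settings$ceiling & bw > 0 & bw < 700
    f <- f[ok]; bw <- bw[ok]
    if (length(f) == 0L) next
    ord <- order(f)
    f <- f[ord][seq_len(min(nf, length(f)))]
    bw <- bw[ord][seq_len(min(nf, length(bw)))]
    freqs[k, seq_along(f)] <- f
    bands[k, seq_along(bw)] <- bw
  }
  structure(list(times = (starts - 1L + win / 2) / sr,
                 frequencies = freqs, bandwidths = bands,
                 settings = settings),
            class = "formant_track")
}

#' Correct octave jumps in a formant track
#'
#' For each formant index, frames whose frequency deviates from the running
#' median (window 5) by more than 40% are replaced by that median. The
#' correction is iterated to a fixed point: each pass cleans the medians
#' that the next pass compares against, so bursts of corrupted frames are
#' repaired progressively. The operation leaves clean tracks unchanged and
#' is idempotent.
#'
#' @param track A `formant_track` with at least 3 frames.
#' @param max_rel_dev Relative deviation triggering replacement
#'   (default 0.4).
#' @return The corrected `formant_track`.
#' @export
correct_octave_jumps <- function(track, max_rel_dev = 0.4) {
  f <- track$frequencies
  if (nrow(f) < 3L) return(track)
  one_pass <- function(f) {
    for (j in seq_len(ncol(f))) {
      col <- f[, j]
      ok <- !is.na(col)
      if (sum(ok) < 3L) next
      med <- stats::runmed(col[ok],
                           k = min(5L, sum(ok) - (sum(ok) + 1L) %% 2L))
      # a run of corrupted frames can poison the running median; formants
      # are stable within a call, so fall back on the column median there
      gmed <- stats::median(col[ok])
      med[abs(med - gmed) / gmed > max_rel_dev] <- gmed
      dev <- abs(col[ok] - med) / med
      col[ok][dev > max_rel_dev] <- med[dev > max_rel_dev]
      f[, j] <- col
    }
    f
  }
  for (i in 1:10) {
    g <- one_pass(f)
    if (identical(g, f)) break
    f <- g
  }
  track$frequencies <- f
  track
}

#' Mean frequencies of the first four formants
#'
#' Arithmetic mean per formant index over the frames where that formant was
#' tracked.
#'
#' @param track A `formant_track`; at least one frame must carry 4 formants.
#' @return Named numeric vector `F1Mean` .. `F4Mean` (Hz).
#' @export
formant_means <- function(track) {
  f <- track$frequencies
  if (ncol(f) < 4L || !any(rowSums(!is.na(f[, 1:4, drop = FALSE])) == 4L))
    stop("no frame carries 4 formants")
  m <- colMeans(f[, 1:4, drop = FALSE], na.rm = TRUE)
  stats::setNames(m, c("F1Mean", "F2Mean", "F3Mean", "F4Mean"))
}

#' Formant dispersion
#'
#' Least-squares regression through the origin of the formant frequencies on
#' the odd quarter-wavelength numbers `(2i - 1) / 2`:
#' `deltaF = sum(F_i x_i) / sum(x_i^2)` with `x_i = (2i - 1) / 2`.
#' For a uniform quarter-wave tube this recovers the formant spacing
#' exactly.
#'
#' @param means Four positive, strictly increasing formant means (Hz).
#' @return Formant dispersion in Hz.
#' @examples
#' formant_dispersion(c(500, 1500, 2500, 3500))  # 1000
#' @export
formant_dispersion <- function(means) {
  means <- as.numeric(means)
  if (length(means) != 4L) stop("need exactly 4 formant means")
  if (any(diff(means) <= 0) || any(means <= 0))
    stop("formant means must be positive and strictly increasing")
  x <- (2 * seq_len(4) - 1) / 2
  sum(means * x) / sum(x^2)
}

#' Estimate vocal tract length from formant dispersion
#'
#' `VTL = c / (2 deltaF)` with c = 35000 cm/s, the approximate speed of
#' sound in the vocal tract, modelling the tract as a uniform tube open at
#' one end and closed at the other.
#'
#' @param deltaF Formant dispersion in Hz (positive).
#' @param c Speed of sound in cm/s (default 35000).
#' @return Estimated vocal tract length in cm.
#' @examples
#' estimate_vtl(1000)  # 17.5 cm
#' @export
estimate_vtl <- function(deltaF, c = 35000) {
  if (deltaF <= 0) stop("deltaF must be positive")
  c / (2 * deltaF)
}

#' All filter-related statistics of a call
#'
#' Runs [track_formants()], [correct_octave_jumps()], [formant_means()],
#' then computes one formant dispersion and one vocal tract length estimate
#' per call from the mean formant values.
#'
#' @param w A [waveform()].
#' @param settings A [formant_settings()].
#' @return Named list: `F1Mean` .. `F4Mean`, `deltaF`, `VTLest`.
#' @export
filter_stats <- function(w, settings = formant_settings()) {
  track <- correct_octave_jumps(track_formants(w, settings))
  m <- formant_means(track)
  dF <- formant_dispersion(m)
  c(as.list(m), list(deltaF = dF, VTLest = estimate_vtl(dF)))
}
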