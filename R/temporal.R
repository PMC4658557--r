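## Temporal feature extraction: duration, intensity contour, amplitude
## modulation statistics, display-song syllable structure, and assembly of
## the complete per-call feature vector.

# Canonical feature column order: 24 parameters measured on contact calls,
# 7 more on display songs.
contact_feature_names <- c(
  "f0Start", "f0End", "f0Mean", "f0Min", "f0Max", "Timef0Min", "Timef0Max",
  "f0AbsSlope", "f0Var", "FMRate", "FMExtent", "Jitter", "Shimmer",
  "Sonority", "AMRate", "AMExtent", "AmpVar",
  "F1Mean", "F2Mean", "F3Mean", "F4Mean", "deltaF", "VTLest", "Dur")
song_feature_names <- c(
  contact_feature_names,
  "Type1", "Type2", "Type3", "SumType1", "SumType2", "SumType3", "DurType2")

#' Names of the per-call acoustic parameters
#'
#' @param call_type `"contact"` (24 parameters) or `"song"` (31: the
#'   contact set plus syllable counts and per-type duration sums).
#' @return Character vector of feature column names in canonical order.
#' @export
feature_names <- function(call_type = c("contact", "song")) {
  call_type <- match.arg(call_type)
  if (call_type == "contact") contact_feature_names else song_feature_names
}

#' Call duration
#'
#' `sample_count / sample_rate`. Calls are assumed pre-trimmed; optionally,
#' leading and trailing frames below `trim_db` relative to the peak RMS are
#' removed first.
#'
#' @param w A [waveform()].
#' @param trim `TRUE` to trim silent padding before measuring.
#' @param trim_db Energy threshold relative to peak, in dB (default -40).
#' @return Duration in seconds.
#' @export
call_duration <- function(w, trim = FALSE, trim_db = -40) {
  if (length(w$samples) == 0L) stop("empty waveform")
  if (!trim) return(duration(w))
  ic <- intensity_contour(w)
  thr <- max(ic$level) + trim_db
  keep <- which(ic$level > thr)
  if (length(keep) == 0L) return(duration(w))
  frame <- ic$time[2L] - ic$time[1L]
  (keep[length(keep)] - keep[1L] + 1L) * frame
}

#' Framewise intensity contour
#'
#' Per-frame RMS level in dB relative to full scale
#' (`20 log10(rms)`), floored at -96 dB.
#'
#' @param w A [waveform()].
#' @param frame Frame length in seconds (default 0.01, non-overlapping).
#' @return Data frame of class `intensity_contour`: `time` (frame centres,
#'   s) and `level` (dB).
#' @export
intensity_contour <- function(w, frame = 0.01) {
  n <- round(frame * w$sample_rate)
  if (length(w$samples) < n) stop("waveform shorter than one frame")
  nf <- length(w$samples) %/% n
  x <- w$samples[seq_len(nf * n)]
  rms <- sqrt(colMeans(matrix(x^2, nrow = n)))
  lvl <- pmax(20 * log10(pmax(rms, 1e-12)), -96)
  structure(data.frame(time = (seq_len(nf) - 0.5) * n / w$sample_rate,
                       level = lvl),
            class = c("intensity_contour", "data.frame"))
}

#' Amplitude modulation statistics
#'
#' Cycle detection identical in mechanism to [fm_statistics()] — detrended
#' mean-crossing pairs — applied to the dB intensity contour. AMRate is
#' cycles per second, AMExtent the mean peak-to-peak excursion per cycle
#' (dB), and AmpVar the cumulative level variation divided by the call
#' duration (dB/s). All three are invariant to global gain.
#'
#' @param ic An [intensity_contour()] with at least 4 frames.
#' @param duration Call duration in seconds.
#' @param min_extent Smallest peak-to-peak level excursion (dB) that counts
#'   as a modulation cycle (default 1); the framewise RMS of even a steady
#'   tone ripples by a fraction of a decibel, which must not register.
#' @return Named list `AMRate`, `AMExtent`, `AmpVar`.
#' @export
am_statistics <- function(ic, duration, min_extent = 1) {
  if (nrow(ic) < 4L) stop("need at least 4 intensity frames")
  cc <- crossing_cycles(ic$time, ic$level, min_extent)
  ampvar <- sum(abs(diff(ic$level))) / duration
  span <- if (length(cc$cycles) > 0L) {
    ic$time[cc$crossings[length(cc$crossings)]] - ic$time[cc$crossings[1L]]
  } else 0
  if (length(cc$cycles) == 0L || span <= 0)
    return(list(AMRate = 0, AMExtent = 0, AmpVar = ampvar))
  extents <- vapply(cc$cycles, function(idx) diff(range(cc$detrended[idx])), 0)
  list(AMRate = length(cc$cycles) / span, AMExtent = mean(extents),
       AmpVar = ampvar)
}

#' Syllable structure of a display song
#'
#' Counts and summed durations of the three syllable types, and the mean
#' duration of the type-2 (long, voiced) syllables.
#'
#' @param annotations Annotation rows of one call (see
#'   [read_annotations()]).
#' @return Named list: `Type1`, `Type2`, `Type3` (counts), `SumType1`,
#'   `SumType2`, `SumType3` (s), `DurType2` (s; `NA` when the song has no
#'   type-2 syllable).
#' @export
syllable_structure <- function(annotations) {
  if (nrow(annotations) == 0L) stop("need at least one annotation")
  annotations <- validate_annotations(annotations)
  dur <- annotations$offset_s - annotations$onset_s
  out <- list()
  for (k in 1:3) {
    sel <- annotations$type == k
    out[[paste0("Type", k)]] <- sum(sel)
    out[[paste0("SumType", k)]] <- sum(dur[sel])
  }
  out$DurType2 <- if (out$Type2 > 0) out$SumType2 / out$Type2 else NA_real_
  out
}

#' Full feature vector of a contact call
#'
#' Assembles the 24 contact-call parameters: source statistics from the f0
#' contour and pulse train, filter statistics from the LPC formant track,
#' amplitude modulation statistics and duration.
#'
#' @param w A [waveform()].
#' @param pitch A [pitch_settings()].
#' @param formant A [formant_settings()] (contact ceiling 3500 Hz by
#'   default).
#' @return One-row data frame with `call_id`, `individual_id` and the 24
#'   feature columns.
#' @export
contact_feature_vector <- function(w, pitch = pitch_settings(),
                                   formant = formant_settings(ceiling = 3500)) {
  dur <- duration(w)
  src <- source_stats(w, pitch)
  flt <- filter_stats(w, formant)
  amp <- am_statistics(intensity_contour(w), dur)
  row <- c(src, amp, flt, list(Dur = dur))
  out <- cbind(data.frame(call_id = w$call_id,
                          individual_id = w$individual_id,
                          stringsAsFactors = FALSE),
               as.data.frame(row[contact_feature_names]))
  rownames(out) <- NULL
  out
}

#' Full feature vector of an ecstatic display song
#'
#' Spectral (source and filter) parameters are measured only on the type-2
#' syllables, where f0 and formants are measurable; when a song contains
#' several type-2 syllables their spectral statistics are arithmetically
#' averaged. Temporal parameters (duration, amplitude modulation, syllable
#' structure) are measured on the whole song. Songs without a type-2
#' syllable are rejected.
#'
#' @param w A [waveform()] holding the whole song.
#' @param annotations Annotation rows for this call.
#' @param pitch A [pitch_settings()].
#' @param formant A [formant_settings()]; the display-song ceiling is
#'   4000 Hz.
#' @return One-row data frame with `call_id`, `individual_id` and the 31
#'   feature columns.
#' @export
song_feature_vector <- function(w, annotations, pitch = pitch_settings(),
                                formant = formant_settings(ceiling = 4000)) {
  syl <- syllable_structure(annotations)
  if (syl$Type2 == 0L)
    stop("song has no type-2 syllable; spectral features undefined")
  ann2 <- annotations[annotations$type == 2L, , drop = FALSE]
  spectral <- lapply(seq_len(nrow(ann2)), function(i) {
    s <- slice_waveform(w, ann2$onset_s[i], ann2$offset_s[i])
    c(source_stats(s, pitch), filter_stats(s, formant))
  })
  spec_names <- names(spectral[[1L]])
  spec_avg <- lapply(spec_names, function(nm) {
    mean(vapply(spectral, function(s) s[[nm]], 0))
  })
  names(spec_avg) <- spec_names
  dur <- duration(w)
  amp <- am_statistics(intensity_contour(w), dur)
  row <- c(spec_avg, amp, list(Dur = dur), syl)
  out <- cbind(data.frame(call_id = w$call_id,
                          individual_id = w$individual_id,
                          stringsAsFactors = FALSE),
               as.data.frame(row[song_feature_names]))
  rownames(out) <- NULL
  out
}
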