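#' Construct a waveform object
#'
#' A `waveform` is the container handed to every feature-extraction routine:
#' a mono amplitude sequence (nominal range -1..1) with its sample rate and
#' the labels that tie a call to the bird that produced it.
#'
#' @param samples Numeric vector of amplitudes; must be finite and non-empty.
#' @param sample_rate Sampling rate in Hz (positive).
#' @param call_id Opaque call label.
#' @param individual_id Opaque individual (bird) label.
#' @return An object of class `waveform` with fields `samples`,
#'   `sample_rate`, `call_id`, `individual_id`.
#' @examples
#' w <- waveform(sin(2 * pi * 250 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration(w)
#' @export
waveform <- function(samples, sample_rate, call_id = NA_character_,
                     individual_id = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("waveform must contain at least one sample")
  if (!all(is.finite(samples))) stop("waveform samples must all be finite")
  sample_rate <- as.numeric(sample_rate)
  if (length(sample_rate) != 1L || !is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(
    list(samples = samples, sample_rate = sample_rate,
         call_id = call_id, individual_id = individual_id),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s)",
              length(x$samples), x$sample_rate, duration(x)))
  if (!is.na(x$call_id)) cat(sprintf("  call_id=%s", x$call_id))
  if (!is.na(x$individual_id)) cat(sprintf("  individual=%s", x$individual_id))
  cat("\n")
  invisible(x)
}

#' Duration of a waveform in seconds
#'
#' @param w A [waveform()].
#' @return Duration in seconds (`length(samples) / sample_rate`).
#' @export
duration <- function(w) length(w$samples) / w$sample_rate

#' Extract a time slice of a waveform
#'
#' Half-open interval `[onset, offset)` in seconds from the start of the
#' waveform, the convention used throughout for syllable boundaries.
#'
#' @param w A [waveform()].
#' @param onset,offset Slice boundaries in seconds, `0 <= onset < offset`.
#' @return A `waveform` holding the slice; labels are inherited.
#' @export
slice_waveform <- function(w, onset, offset) {
  if (onset < 0 || offset <= onset) stop("need 0 <= onset < offset")
  i0 <- floor(onset * w$sample_rate) + 1L
  i1 <- min(length(w$samples), ceiling(offset * w$sample_rate))
  if (i0 > length(w$samples)) stop("slice starts beyond end of waveform")
  waveform(w$samples[i0:i1], w$sample_rate, w$call_id, w$individual_id)
}

## ---- RIFF/WAVE container -------------------------------------------------
## Plain PCM (8/16/24-bit integer) and 32-bit IEEE float chunks; multi-channel
## audio is averaged to mono on read.

#' Read a WAV file
#'
#' Reads a RIFF/WAVE file (PCM 8/16/24-bit integer or 32-bit IEEE float).
#' Multi-channel audio is averaged to a single mono channel; integer samples
#' are rescaled to the nominal -1..1 range.
#'
#' @param path Path to a `.wav` file.
#' @param call_id,individual_id Optional labels attached to the result.
#' @return A [waveform()].
#' @export
read_wav <- function(path, call_id = NA_character_,
                     individual_id = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(body[3:4], "integer", 1, 2,
                             signed = FALSE, endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2,
                       signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)  # skip unknown chunk
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1L)  # chunk padding byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw) || length(data_raw) == 0L)
    stop("WAV file has no audio data: ", path)

  x <- switch(
    as.character(fmt$bits),
    "8" = (as.numeric(readBin(data_raw, "integer", length(data_raw), 1,
                              signed = FALSE)) - 128) / 128,
    "16" = readBin(data_raw, "integer", length(data_raw) %/% 2L, 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      n <- length(data_raw) %/% 3L
      b <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
      v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = {
      if (fmt$audio_format != 3L)
        stop("32-bit WAV supported only as IEEE float")
      readBin(data_raw, "double", length(data_raw) %/% 4L, 4,
              endian = "little")
    },
    stop("unsupported WAV bit depth: ", fmt$bits)
  )
  if (fmt$n_channels > 1L) {
    n <- length(x) %/% fmt$n_channels
    x <- colMeans(matrix(x[seq_len(n * fmt$n_channels)],
                         nrow = fmt$n_channels))
  }
  if (length(x) == 0L) stop("zero-length audio in ", path)
  waveform(x, fmt$sample_rate, call_id, individual_id)
}

#' Write a waveform to a WAV file
#'
#' Writes 16-bit PCM mono, the format of the field recordings this pipeline
#' models. Samples are clipped to \[-1, 1\] before quantization.
#'
#' @param w A [waveform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  x <- pmax(-1, pmin(1, w$samples))
  q <- pmin(as.integer(round(x * 32768)), 32767L)  # same scale as the reader
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                    # PCM
  writeBin(1L, con, 2, endian = "little")                    # mono
  sr <- as.integer(round(w$sample_rate))
  writeBin(sr, con, 4, endian = "little")
  writeBin(sr * 2L, con, 4, endian = "little")               # byte rate
  writeBin(2L, con, 2, endian = "little")                    # block align
  writeBin(16L, con, 2, endian = "little")                   # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, 4, endian = "little")
  writeBin(q, con, 2, endian = "little")
  invisible(path)
}

#' Resample a waveform
#'
#' Band-limited resampling in the frequency domain: the spectrum is computed
#' by FFT, content above the smaller of the two Nyquist frequencies is
#' discarded, and the signal is re-synthesized at the new length. Duration is
#' preserved to within one sample period.
#'
#' @param w A [waveform()].
#' @param target_rate New sampling rate in Hz (positive).
#' @return A `waveform` at `target_rate`.
#' @export
resample_wave <- function(w, target_rate) {
  if (!is.finite(target_rate) || target_rate <= 0)
    stop("target_rate must be positive")
  if (target_rate == w$sample_rate) return(w)
  n <- length(w$samples)
  m <- max(1L, as.integer(round(n * target_rate / w$sample_rate)))
  X <- stats::fft(w$samples)
  Y <- complex(m)
  # number of positive-frequency bins retained (below both Nyquists)
  keep <- min((n - 1L) %/% 2L, (m - 1L) %/% 2L)
  Y[1L] <- X[1L]
  if (keep > 0L) {
    idx <- seq_len(keep)
    Y[1L + idx] <- X[1L + idx]
    Y[m + 1L - idx] <- X[n + 1L - idx]
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  waveform(y, target_rate, w$call_id, w$individual_id)
}

## ---- syllable annotations ------------------------------------------------

#' Read syllable annotations
#'
#' Reads a delimited annotation table with header
#' `call_id,onset_s,offset_s,type`. Times are seconds from call onset,
#' intervals are half-open `[onset, offset)`, and `type` is the display-song
#' syllable class: 1 and 2 exhaled (2 is the long syllable carrying the
#' spectral measurements), 3 the inhaled syllable.
#'
#' @param path Path to a CSV file.
#' @return A data frame with columns `call_id`, `onset_s`, `offset_s`,
#'   `type`, sorted by call and onset.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(df)
}

#' Validate a syllable annotation table
#'
#' Enforces the annotation invariants: required columns, `type` in {1, 2, 3},
#' `0 <= onset < offset`, and no overlapping intervals within a call.
#' Rows are returned sorted by call and onset.
#'
#' @param df Data frame with columns `call_id`, `onset_s`, `offset_s`, `type`.
#' @return The validated, sorted data frame.
#' @export
validate_annotations <- function(df) {
  need <- c("call_id", "onset_s", "offset_s", "type")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  df$type <- as.integer(df$type)
  if (!all(df$type %in% 1:3))
    stop("syllable type must be 1, 2 or 3")
  if (any(df$onset_s < 0) || any(df$offset_s <= df$onset_s))
    stop("annotations must satisfy 0 <= onset < offset")
  df <- df[order(df$call_id, df$onset_s), , drop = FALSE]
  for (cid in unique(df$call_id)) {
    a <- df[df$call_id == cid, , drop = FALSE]
    if (nrow(a) > 1L &&
        any(a$onset_s[-1L] < a$offset_s[-nrow(a)] - 1e-9))
      stop("overlapping syllable annotations in call ", cid)
  }
  rownames(df) <- NULL
  df
}
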