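## Orchestration: packaged reference tables, batch feature extraction over
## waveforms or WAV directories, summary-table PIC reports, and the one-shot
## synthetic-colony analysis.

#' Packaged per-individual summary statistics
#'
#' Long-format table (`parameter`, `individual_id`, `n`, `mean`, `sd`) of
#' the per-individual acoustic parameter summaries for the reference
#' captive colony: 24 parameters over six birds for contact calls, 31 over
#' seven birds for ecstatic display songs. `sd` is the sample SD
#' (n - 1 denominator); `n` the number of calls per bird.
#'
#' @param call_type `"contact"` or `"song"`.
#' @return Data frame.
#' @export
load_summary_table <- function(call_type = c("contact", "song")) {
  call_type <- match.arg(call_type)
  f <- system.file("extdata",
                   paste0(call_type, "_summary_stats.csv"),
                   package = "vocalid", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Packaged reference PIC values
#'
#' Published two-decimal PIC values for every acoustic parameter of the
#' reference colony, used to validate [pic_from_summaries()].
#'
#' @return Data frame with columns `parameter`, `contact`, `song` (`NA`
#'   where a parameter applies only to songs).
#' @export
load_reference_pic <- function() {
  f <- system.file("extdata", "reference_pic.csv", package = "vocalid",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' PIC report from a per-individual summary table
#'
#' Runs [pic_from_summaries()] on every parameter of a long-format summary
#' table (as returned by [load_summary_table()]).
#'
#' @param summaries Data frame with columns `parameter`, `individual_id`,
#'   `n`, `mean`, `sd`.
#' @param threshold PIC selection threshold (default 1.1).
#' @return PIC result table, one row per parameter in first-appearance
#'   order.
#' @export
pic_report_from_summaries <- function(summaries, threshold = 1.1) {
  pars <- unique(summaries$parameter)
  rows <- lapply(pars, function(p) {
    s <- summaries[summaries$parameter == p, , drop = FALSE]
    tryCatch(pic_from_summaries(s, p, threshold),
             error = function(e) data.frame(
               parameter = p, mean_cvw = NA_real_, cvb = NA_real_,
               pic = NA_real_, selected = NA, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract feature vectors from a set of calls
#'
#' Applies [contact_feature_vector()] or [song_feature_vector()] to every
#' waveform. Songs lacking a type-2 syllable (whose spectral parameters are
#' unmeasurable) are skipped with a warning, as are calls on which
#' extraction fails.
#'
#' @param waveforms List of [waveform()]s with `call_id` and
#'   `individual_id` set.
#' @param call_type `"contact"` or `"song"`.
#' @param annotations Annotation table covering every song (required for
#'   `call_type = "song"`).
#' @param pitch,formant Analysis settings; the formant ceiling defaults to
#'   3500 Hz for contact calls and 4000 Hz for songs.
#' @return Feature table: one row per successfully analyzed call.
#' @export
extract_features <- function(waveforms, call_type = c("contact", "song"),
                             annotations = NULL,
                             pitch = pitch_settings(), formant = NULL) {
  call_type <- match.arg(call_type)
  if (is.null(formant))
    formant <- formant_settings(
      ceiling = if (call_type == "contact") 3500 else 4000)
  if (call_type == "song" && is.null(annotations))
    stop("song feature extraction requires a syllable annotation table ",
         "(columns call_id, onset_s, offset_s, type)")
  rows <- lapply(waveforms, function(w) {
    tryCatch({
      if (call_type == "contact") {
        contact_feature_vector(w, pitch, formant)
      } else {
        ann <- annotations[annotations$call_id == w$call_id, , drop = FALSE]
        song_feature_vector(w, ann, pitch, formant)
      }
    }, error = function(e) {
      warning("skipping call ", w$call_id, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("no call could be analyzed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a synthetic colony to disk
#'
#' Emits one WAV per call (named `<individual>__<call>.wav`), the syllable
#' annotation CSV (songs) and the ground-truth feature CSV.
#'
#' @param config A [colony_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the list returned by [generate_colony()].
#' @export
write_colony <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  colony <- generate_colony(config)
  for (w in colony$waveforms)
    write_wav(w, file.path(dir, paste0(w$call_id, ".wav")))
  if (nrow(colony$annotations) > 0L)
    utils::write.csv(colony$annotations,
                     file.path(dir, "annotations.csv"), row.names = FALSE)
  utils::write.csv(colony$ground_truth,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(colony)
}

#' Read a colony of WAV files back as labelled waveforms
#'
#' Expects the `<individual>__<call>.wav` naming convention used by
#' [write_colony()].
#'
#' @param dir Directory of WAV files.
#' @return List of [waveform()]s.
#' @export
read_colony <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.wav$", full.names = TRUE))
  if (length(files) == 0L) stop("no WAV files in ", dir)
  lapply(files, function(f) {
    stem <- sub("\\.wav$", "", basename(f))
    ind <- sub("__.*$", "", stem)
    read_wav(f, call_id = stem, individual_id = ind)
  })
}

#' One-shot vocal-individuality analysis of a synthetic colony
#'
#' Generates a colony, optionally runs the full acoustic feature extraction
#' on the synthesized audio (otherwise the ground-truth table is analyzed
#' directly), and applies the statistical pipeline: PIC gate, stepwise
#' discriminant selection, leave-one-out cross-validated classification,
#' proportional chance criterion and Yates-corrected chi-square test.
#'
#' @param config A [colony_config()].
#' @param from_audio If `TRUE`, features are measured from the synthesized
#'   waveforms; if `FALSE` (default) the generator's ground-truth table is
#'   used, exercising the statistics independently of the DSP stages.
#' @param ... Passed to [classify_calls()].
#' @return List with `features` (the analyzed table), `pic` and `report`
#'   (the [classify_calls()] result).
#' @export
run_individuality_analysis <- function(config, from_audio = FALSE, ...) {
  colony <- generate_colony(config)
  features <- if (from_audio) {
    extract_features(colony$waveforms, config$call_type,
                     annotations = colony$annotations)
  } else {
    colony$ground_truth
  }
  report <- classify_calls(features, ...)
  list(features = features, pic = report$pic, report = report)
}
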