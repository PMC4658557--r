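#' Within-individual coefficient of variation (small-sample corrected)
#'
#' CVw = 100 * (sd / mean) * (1 + 1 / (4 n)). The correction compensates the
#' downward bias of the sample CV at the small per-individual sample sizes
#' typical of field recordings.
#'
#' @param mean Group mean (must be strictly positive; the CV is undefined
#'   otherwise).
#' @param sd Group sample standard deviation (n - 1 denominator).
#' @param n Number of calls for the individual (>= 2).
#' @return CVw as a percentage.
#' @examples
#' cv_within(288.6, 18.28, 9)
#' @export
cv_within <- function(mean, sd, n) {
  if (any(n < 2)) stop("cv_within needs n >= 2")
  if (any(sd < 0)) stop("sd must be non-negative")
  if (any(mean <= 0)) stop("cv_within undefined for non-positive mean")
  100 * (sd / mean) * (1 + 1 / (4 * n))
}

#' Between-individual coefficient of variation
#'
#' CVb = 100 * SD / mean, both computed over the total sample (all calls of
#' all individuals pooled), SD with the n - 1 denominator. No small-sample
#' correction is applied to CVb.
#'
#' @param values Numeric vector of one parameter across the total sample.
#' @return CVb as a percentage.
#' @export
cv_between <- function(values) {
  if (length(values) < 3L) stop("cv_between needs at least 3 values")
  m <- mean(values)
  if (m <= 0) stop("cv_between undefined for non-positive mean")
  100 * stats::sd(values) / m
}

#' Summarize a feature table by individual
#'
#' @param table Data frame with an `individual_id` column.
#' @param parameter Name of the feature column to summarize.
#' @return Data frame with columns `individual_id`, `mean`, `sd`
#'   (n - 1 denominator), `n`.
#' @export
group_summarize <- function(table, parameter) {
  x <- table[[parameter]]
  if (is.null(x)) stop("no such column: ", parameter)
  ids <- unique(table$individual_id)
  out <- data.frame(
    individual_id = ids,
    mean = vapply(ids, function(i) mean(x[table$individual_id == i]), 0),
    sd = vapply(ids, function(i) stats::sd(x[table$individual_id == i]), 0),
    n = vapply(ids, function(i) sum(table$individual_id == i), 0L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

pic_result <- function(parameter, mean_cvw, cvb, threshold) {
  pic <- if (mean_cvw == 0) Inf else cvb / mean_cvw
  data.frame(parameter = parameter, mean_cvw = mean_cvw, cvb = cvb,
             pic = pic, selected = is.finite(pic) && pic >= threshold ||
               is.infinite(pic),
             stringsAsFactors = FALSE)
}

#' Potential of Individual Coding from raw per-call measurements
#'
#' PIC = CVb / mean(CVw): the ratio of between-individual variation (over the
#' pooled sample) to the unweighted mean of the per-individual
#' small-sample-corrected within CVs. PIC > 1 indicates that a parameter
#' varies more between than within individuals and so has the potential to
#' encode caller identity.
#'
#' @param table Feature table: one row per call, an `individual_id` column,
#'   and numeric feature columns. Every individual needs n >= 2 calls.
#' @param parameter Feature column to analyze.
#' @param threshold Selection threshold on PIC (default 1.1).
#' @return One-row data frame: `parameter`, `mean_cvw`, `cvb`, `pic`,
#'   `selected`. A degenerate table with zero within-individual variation
#'   yields `pic = Inf` with `selected = TRUE`.
#' @seealso [pic_from_summaries()] for the algebraically identical
#'   computation from printed group summaries.
#' @export
pic_from_raw <- function(table, parameter, threshold = 1.1) {
  g <- group_summarize(table, parameter)
  if (nrow(g) < 2L) stop("need at least 2 individuals")
  if (any(g$n < 2L)) stop("every individual needs at least 2 calls")
  if (any(g$mean <= 0))
    stop("PIC undefined: non-positive group mean for ", parameter)
  mean_cvw <- mean(cv_within(g$mean, g$sd, g$n))
  cvb <- cv_between(table[[parameter]])
  pic_result(parameter, mean_cvw, cvb, threshold)
}

#' Potential of Individual Coding from group summaries
#'
#' Computes PIC from per-individual means, sample SDs and group sizes alone,
#' as printed in a descriptive-statistics table. The total-sample moments are
#' reconstructed exactly from the group summaries:
#' N = sum(n_i); m = sum(n_i m_i) / N;
#' SS = sum((n_i - 1) s_i^2 + n_i (m_i - m)^2); SD_total = sqrt(SS / (N - 1)).
#' When the summaries are computed from a raw table, the result is
#' algebraically identical to [pic_from_raw()].
#'
#' @param summaries Data frame with columns `mean`, `sd`, `n` (one row per
#'   individual); an optional `individual_id` column is ignored.
#' @param parameter Label for the reported row.
#' @param threshold Selection threshold on PIC (default 1.1).
#' @return One-row data frame as in [pic_from_raw()].
#' @examples
#' # f0Mean of six penguins' contact calls
#' s <- data.frame(mean = c(288.6, 285.04, 256.14, 294.03, 251.62, 285.46),
#'                 sd = c(18.28, 18.28, 23.24, 13.63, 14.74, 16.06),
#'                 n = c(9, 14, 20, 25, 31, 19))
#' pic_from_summaries(s, "f0Mean")
#' @export
pic_from_summaries <- function(summaries, parameter = "parameter",
                               threshold = 1.1) {
  need <- c("mean", "sd", "n")
  if (!all(need %in% names(summaries)))
    stop("summaries must have columns mean, sd, n")
  if (nrow(summaries) < 2L) stop("need at least 2 group summaries")
  if (any(summaries$n < 2)) stop("every group needs n >= 2")
  if (any(summaries$mean <= 0))
    stop("PIC undefined: non-positive group mean for ", parameter)
  m_i <- summaries$mean; s_i <- summaries$sd; n_i <- summaries$n
  mean_cvw <- mean(cv_within(m_i, s_i, n_i))
  N <- sum(n_i)
  m <- sum(n_i * m_i) / N
  ss <- sum((n_i - 1) * s_i^2 + n_i * (m_i - m)^2)
  cvb <- 100 * sqrt(ss / (N - 1)) / m
  pic_result(parameter, mean_cvw, cvb, threshold)
}

#' PIC for every feature column of a table
#'
#' @param table Feature table as in [pic_from_raw()].
#' @param parameters Character vector of columns to analyze; defaults to all
#'   numeric columns except identifiers.
#' @param threshold Selection threshold on PIC (default 1.1).
#' @return Data frame with one row per parameter, in input column order.
#'   Parameters whose group means are not strictly positive are reported with
#'   `NA` values rather than dropped.
#' @export
pic_table <- function(table, parameters = NULL, threshold = 1.1) {
  if (is.null(parameters)) {
    num <- vapply(table, is.numeric, TRUE)
    parameters <- setdiff(names(table)[num], c("call_id", "individual_id"))
  }
  rows <- lapply(parameters, function(p) {
    tryCatch(pic_from_raw(table, p, threshold),
             error = function(e) {
               data.frame(parameter = p, mean_cvw = NA_real_, cvb = NA_real_,
                          pic = NA_real_, selected = NA,
                          stringsAsFactors = FALSE)
             })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select parameters passing the PIC gate
#'
#' @param results A PIC result table ([pic_table()] or rbound rows of
#'   [pic_from_summaries()]).
#' @param threshold Gate on PIC (default 1.1).
#' @return Character vector of parameter names with `pic >= threshold`, in
#'   the original row order. `NA` PIC values never pass.
#' @export
select_parameters <- function(results, threshold = 1.1) {
  keep <- !is.na(results$pic) & results$pic >= threshold
  results$parameter[keep]
}
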