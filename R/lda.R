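## Stepwise linear discriminant analysis with Wilks' lambda selection,
## leave-one-out cross-validation, proportional chance criterion and a
## Yates-corrected chi-square significance test.

# Within-group and total SSCP matrices for the given columns.
sscp_matrices <- function(table, columns) {
  X <- as.matrix(table[, columns, drop = FALSE])
  g <- factor(table$individual_id)
  grand <- colMeans(X)
  Tm <- crossprod(sweep(X, 2, grand))
  W <- matrix(0, ncol(X), ncol(X))
  for (lev in levels(g)) {
    Xi <- X[g == lev, , drop = FALSE]
    W <- W + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  list(W = W, T = Tm)
}

# Wilks' lambda = det(W) / det(T) for the given variable set.
wilks_lambda <- function(table, columns) {
  if (length(columns) == 0L) return(1)
  m <- sscp_matrices(table, columns)
  dW <- determinant(m$W, logarithm = TRUE)
  dT <- determinant(m$T, logarithm = TRUE)
  if (dW$sign <= 0 || dT$sign <= 0) return(NA_real_)
  exp(as.numeric(dW$modulus - dT$modulus))
}

#' Stepwise variable selection by Wilks' lambda
#'
#' Forward selection with backward checks, the classic stepwise discriminant
#' procedure: at each step the candidate whose entry most reduces Wilks'
#' lambda is entered if its partial F-to-enter reaches `f_enter`
#' (F = ((lambda_old / lambda_new) - 1) * (N - g - p) / (g - 1), with p
#' variables already entered); entered variables whose F-to-remove falls
#' below `f_remove` are then removed. Ties break by candidate column order.
#' Candidates whose entry makes the within-group scatter singular
#' (collinearity) are skipped with a warning.
#'
#' @param table Feature table with `individual_id` and numeric columns.
#' @param candidates Character vector of candidate columns.
#' @param f_enter,f_remove Partial-F thresholds (default 3.84, the 0.05
#'   chi-square bound on one degree of freedom).
#' @return List with `selected` (character vector, entry order) and `trace`
#'   (data frame of steps: `action`, `parameter`, `wilks_lambda`,
#'   `F_statistic`).
#' @export
stepwise_select <- function(table, candidates, f_enter = 3.84,
                            f_remove = 3.84) {
  stopifnot(all(candidates %in% names(table)))
  g <- length(unique(table$individual_id))
  if (g < 2L) stop("need at least 2 groups")
  N <- nrow(table)
  selected <- character(0)
  lambda <- 1
  trace <- data.frame(action = character(0), parameter = character(0),
                      wilks_lambda = numeric(0), F_statistic = numeric(0),
                      stringsAsFactors = FALSE)
  warned <- character(0)

  partial_f <- function(l_old, l_new, p_after) {
    # p_after = number of variables in the larger model
    dfe <- N - g - p_after + 1
    if (dfe <= 0 || !is.finite(l_new) || l_new <= 0) return(NA_real_)
    (l_old / l_new - 1) * dfe / (g - 1)
  }

  repeat {
    changed <- FALSE
    # entry step
    pool <- setdiff(candidates, selected)
    if (length(pool) > 0L) {
      fs <- vapply(pool, function(v) {
        l_new <- wilks_lambda(table, c(selected, v))
        if (is.na(l_new)) {
          if (!(v %in% warned)) {
            warning("skipping collinear candidate: ", v, call. = FALSE)
            warned <<- c(warned, v)
          }
          return(-Inf)
        }
        partial_f(lambda, l_new, length(selected) + 1L)
      }, 0)
      fs[is.na(fs)] <- -Inf
      best <- which.max(fs)  # first max = column-order tie-break
      if (fs[best] >= f_enter) {
        v <- pool[best]
        selected <- c(selected, v)
        lambda <- wilks_lambda(table, selected)
        trace <- rbind(trace, data.frame(
          action = "enter", parameter = v, wilks_lambda = lambda,
          F_statistic = fs[best], stringsAsFactors = FALSE))
        changed <- TRUE
      }
    }
    # removal step
    if (length(selected) > 1L) {
      repeat {
        fr <- vapply(selected, function(v) {
          l_without <- wilks_lambda(table, setdiff(selected, v))
          partial_f(l_without, lambda, length(selected))
        }, 0)
        if (all(!is.finite(fr))) break
        fr[!is.finite(fr)] <- Inf  # undecidable removals are kept
        worst <- which.min(fr)
        if (fr[worst] < f_remove) {
          v <- selected[worst]
          selected <- setdiff(selected, v)
          lambda <- wilks_lambda(table, selected)
          trace <- rbind(trace, data.frame(
            action = "remove", parameter = v, wilks_lambda = lambda,
            F_statistic = fr[worst], stringsAsFactors = FALSE))
          changed <- TRUE
        } else break
      }
    }
    if (!changed) break
  }
  list(selected = selected, trace = trace)
}

#' Fit a linear discriminant classifier
#'
#' Classical LDA with pooled within-class covariance: a call with feature
#' vector x is assigned to the class k maximizing
#' `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log(prior_k)`.
#' If the pooled covariance is numerically singular a ridge of
#' `1e-8 * mean(diag)` is added (with a warning).
#'
#' @param table Feature table with `individual_id`.
#' @param selected Character vector of feature columns to use.
#' @param priors `"proportional"` (class priors equal to group shares, the
#'   default, consistent with the group-size chance criterion), `"equal"`,
#'   or a named numeric vector summing to 1.
#' @return An object of class `vocalid_lda`.
#' @export
fit_lda <- function(table, selected, priors = "proportional") {
  if (length(selected) == 0L) stop("no variables selected")
  X <- as.matrix(table[, selected, drop = FALSE])
  g <- factor(table$individual_id)
  if (any(table(g) < 2L)) stop("every group needs at least 2 rows")
  k <- nlevels(g)
  N <- nrow(X)
  means <- matrix(unlist(lapply(levels(g), function(lev) {
    colMeans(X[g == lev, , drop = FALSE])
  })), nrow = k, ncol = ncol(X), byrow = TRUE,
  dimnames = list(levels(g), colnames(X)))
  W <- sscp_matrices(table, selected)$W
  S <- W / (N - k)
  solvable <- function(M) {
    tryCatch(is.finite(rcond(M)) && rcond(M) > 1e-12,
             error = function(e) FALSE)
  }
  ridge <- 1e-8 * mean(diag(S))
  tries <- 0L
  while (!solvable(S) && tries < 8L) {
    warning(sprintf("pooled covariance singular; ridge %.3g added", ridge),
            call. = FALSE)
    S <- S + diag(ridge, ncol(S))
    ridge <- ridge * 100
    tries <- tries + 1L
  }
  pr <- if (identical(priors, "proportional")) {
    as.numeric(table(g)) / N
  } else if (identical(priors, "equal")) {
    rep(1 / k, k)
  } else {
    if (is.null(names(priors)) || !setequal(names(priors), levels(g)))
      stop("numeric priors must be named by group")
    as.numeric(priors[levels(g)])
  }
  if (abs(sum(pr) - 1) > 1e-8) stop("priors must sum to 1")
  Sinv <- solve(S)
  structure(list(selected = selected, levels = levels(g), means = means,
                 cov = S, cov_inv = Sinv, priors = pr),
            class = "vocalid_lda")
}

#' Predict individual identity with a fitted LDA model
#'
#' @param object A `vocalid_lda` model.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Character vector of predicted individual labels.
#' @export
predict.vocalid_lda <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$selected, drop = FALSE])
  A <- object$cov_inv %*% t(object$means)            # p x k
  c0 <- -0.5 * colSums(t(object$means) * A) + log(object$priors)
  scores <- X %*% A + matrix(c0, nrow(X), length(c0), byrow = TRUE)
  object$levels[max.col(scores, ties.method = "first")]
}

#' Leave-one-out cross-validated classification
#'
#' Each call is classified by a model refitted on all remaining calls.
#' Variable selection (if any) is performed once on the full table and held
#' fixed across folds, matching standard stepwise-DFA practice; the optimism
#' this introduces relative to fully nested selection is documented in the
#' methods vignette.
#'
#' @inheritParams fit_lda
#' @return List with `predicted` (character vector, one per row) and
#'   `confusion` (true x predicted contingency table). Folds that would
#'   reduce a group below 2 rows are skipped with a warning (`NA`
#'   prediction).
#' @export
loocv <- function(table, selected, priors = "proportional") {
  n <- nrow(table)
  truth <- as.character(table$individual_id)
  pred <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    rest <- table[-i, , drop = FALSE]
    if (min(table(rest$individual_id)) < 2L) {
      warning("fold ", i, " skipped: a group would drop below 2 rows",
              call. = FALSE)
      next
    }
    fit <- fit_lda(rest, selected, priors)
    pred[i] <- predict(fit, table[i, , drop = FALSE])
  }
  lev <- sort(unique(truth))
  confusion <- table(factor(truth, lev), factor(pred, lev))
  list(predicted = pred, confusion = confusion)
}

#' Proportional chance criterion
#'
#' Expected percent-correct of group-size-informed random assignment,
#' `100 * sum((n_i / N)^2)` — the appropriate chance level when individuals
#' contribute unequal numbers of calls.
#'
#' @param sizes Positive group sizes.
#' @return Chance level as a percentage.
#' @examples
#' chance_level(c(9, 14, 20, 25, 31, 19))  # 18.84
#' @export
chance_level <- function(sizes) {
  if (length(sizes) == 0L || any(sizes <= 0)) stop("sizes must be positive")
  100 * sum((sizes / sum(sizes))^2)
}

#' Yates-corrected chi-square test of classification accuracy
#'
#' Two-cell goodness-of-fit test of observed correct/incorrect counts against
#' the chance expectation, with continuity correction: each cell contributes
#' `(max(|O - E| - 0.5, 0))^2 / E`; df = 1. Significance is judged at
#' `alpha` (default 0.001, critical value 10.828).
#'
#' @param correct Number of correctly classified calls.
#' @param total Total number of calls.
#' @param chance_proportion Chance proportion in (0, 1).
#' @param alpha Significance level (default 0.001).
#' @return List with `statistic`, `df`, `p_value` and `significant`.
#' @export
yates_chi2 <- function(correct, total, chance_proportion, alpha = 0.001) {
  if (correct < 0 || correct > total) stop("need 0 <= correct <= total")
  if (chance_proportion <= 0 || chance_proportion >= 1)
    stop("chance_proportion must be in (0, 1)")
  O <- c(correct, total - correct)
  E <- c(chance_proportion, 1 - chance_proportion) * total
  if (any(E == 0)) stop("expected count of zero")
  stat <- sum(pmax(abs(O - E) - 0.5, 0)^2 / E)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, df = 1L, p_value = p, significant = p < alpha)
}

#' PIC-gated stepwise discriminant classification of calls
#'
#' The full statistical pipeline applied to a feature table: PIC gate
#' (parameters with PIC >= `pic_threshold`), stepwise Wilks'-lambda
#' selection at `f_enter`/`f_remove`, LDA fit, leave-one-out
#' cross-validation, proportional chance criterion and Yates-corrected
#' chi-square significance.
#'
#' @param table Feature table: one row per call, `individual_id` plus
#'   numeric feature columns.
#' @param parameters Candidate feature columns (default: all numeric
#'   non-identifier columns).
#' @param pic_threshold PIC gate (default 1.1).
#' @param f_enter,f_remove Stepwise partial-F thresholds (default 3.84).
#' @param priors Prior mode passed to [fit_lda()].
#' @param alpha Significance level for the chi-square test (default 0.001).
#' @return An object of class `classification_report`: confusion matrices
#'   and percent correct for resubstitution and leave-one-out
#'   cross-validation, chance level, chi-square test, the PIC table, the
#'   gated and stepwise-selected parameter sets, and the stepwise trace.
#' @export
classify_calls <- function(table, parameters = NULL, pic_threshold = 1.1,
                           f_enter = 3.84, f_remove = 3.84,
                           priors = "proportional", alpha = 0.001) {
  if (is.null(parameters)) {
    num <- vapply(table, is.numeric, TRUE)
    parameters <- setdiff(names(table)[num], c("call_id", "individual_id"))
  }
  pic <- pic_table(table, parameters, pic_threshold)
  gated <- select_parameters(pic, pic_threshold)
  if (length(gated) < 2L) {
    warning("fewer than 2 parameters pass the PIC gate; ",
            "using all candidates", call. = FALSE)
    gated <- parameters
  }
  sw <- stepwise_select(table, gated, f_enter, f_remove)
  selected <- if (length(sw$selected) > 0L) sw$selected else gated
  fit <- fit_lda(table, selected, priors)
  truth <- as.character(table$individual_id)
  lev <- sort(unique(truth))
  resub_pred <- predict(fit, table)
  resub_conf <- table(factor(truth, lev), factor(resub_pred, lev))
  cv <- loocv(table, selected, priors)
  sizes <- as.numeric(table(factor(truth, lev)))
  chance <- chance_level(sizes)
  n_correct_cv <- sum(diag(cv$confusion))
  n_scored <- sum(!is.na(cv$predicted))
  chi <- yates_chi2(n_correct_cv, n_scored, chance / 100, alpha)
  # the scientific question is whether calls classify better than chance;
  # a below-chance deviation (a leave-one-out artifact of uninformative
  # features) is not evidence of identity coding
  above_chance <- n_correct_cv > chance / 100 * n_scored
  structure(list(
    pic = pic, gated_parameters = gated,
    stepwise_selected = sw$selected, trace = sw$trace, model = fit,
    confusion = resub_conf,
    percent_correct = 100 * sum(diag(resub_conf)) / length(truth),
    confusion_cv = cv$confusion,
    percent_correct_cv = 100 * n_correct_cv / n_scored,
    chance_percent = chance, yates_chi2 = chi$statistic,
    p_value = chi$p_value, significant = chi$significant && above_chance,
    group_sizes = stats::setNames(sizes, lev)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Individual classification report\n")
  cat(sprintf("  groups: %d, calls: %d\n", length(x$group_sizes),
              sum(x$group_sizes)))
  cat(sprintf("  PIC-gated parameters: %d; stepwise-selected: %d\n",
              length(x$gated_parameters), length(x$stepwise_selected)))
  cat(sprintf("  correct: %.1f%% (resubstitution), %.1f%% (leave-one-out)\n",
              x$percent_correct, x$percent_correct_cv))
  cat(sprintf("  chance: %.2f%%;  Yates chi2 = %.1f (df 1), %s at the %s level\n",
              x$chance_percent, x$yates_chi2,
              if (x$significant) "significant" else "not significant",
              format(0.001)))
  invisible(x)
}
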