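test_that("stepwise selection enters the informative variable first", {
  set.seed(41)
  tab <- random_feature_table(g = 4, n = 20, p = 4)
  tab$signal <- rnorm(nrow(tab)) +
    5 * as.integer(factor(tab$individual_id))
  sw <- stepwise_select(tab, c("v1", "v2", "v3", "v4", "signal"))
  expect_equal(sw$selected[1], "signal")
  expect_true(all(diff(c(1, sw$trace$wilks_lambda[
    sw$trace$action == "enter"])) <= 1e-12))
})

test_that("all-noise candidates are almost never entered", {
  set.seed(42)
  entered <- vapply(1:20, function(i) {
    tab <- random_feature_table(g = 6, n = 20, p = 5)
    length(stepwise_select(tab, paste0("v", 1:5))$selected)
  }, 0)
  expect_gte(mean(entered == 0), 0.7)
  expect_lte(mean(entered), 0.5)
})

test_that("duplicated collinear columns enter only once", {
  set.seed(43)
  tab <- random_feature_table(g = 3, n = 15, p = 2)
  tab$v1 <- tab$v1 + 4 * as.integer(factor(tab$individual_id))
  tab$dup <- tab$v1
  sw <- suppressWarnings(stepwise_select(tab, c("v1", "dup", "v2")))
  expect_equal(sum(sw$selected %in% c("v1", "dup")), 1L)
})

test_that("LDA decision boundary sits between symmetric classes", {
  set.seed(44)
  tab <- data.frame(v1 = c(rnorm(200, -10), rnorm(200, 10)),
                    individual_id = rep(c("a", "b"), each = 200))
  fit <- fit_lda(tab, "v1")
  probe <- data.frame(v1 = c(-0.5, 0.5))
  expect_equal(predict(fit, probe), c("a", "b"))
  # unequal priors shift the boundary toward the rarer class: more of the
  # axis is claimed by the common class
  grid <- data.frame(v1 = seq(-2, 2, by = 0.01))
  fit_eq <- fit_lda(tab, "v1", priors = "equal")
  fit9 <- fit_lda(tab, "v1", priors = c(a = 0.9, b = 0.1))
  expect_gt(sum(predict(fit9, grid) == "a"),
            sum(predict(fit_eq, grid) == "a"))
})

test_that("LDA predictions agree with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(45)
  tab <- random_feature_table(g = 4, n = 25, p = 3, shift = 0.8)
  fit <- fit_lda(tab, c("v1", "v2", "v3"), priors = "proportional")
  ours <- predict(fit, tab)
  m <- MASS::lda(individual_id ~ v1 + v2 + v3, data = tab)
  theirs <- as.character(predict(m, tab)$class)
  expect_identical(ours, theirs)
})

test_that("leave-one-out equals an explicit refit-per-row loop", {
  set.seed(46)
  tab <- random_feature_table(g = 3, n = 10, p = 2, shift = 1)
  cv <- loocv(tab, c("v1", "v2"))
  brute <- vapply(seq_len(nrow(tab)), function(i) {
    predict(fit_lda(tab[-i, ], c("v1", "v2")), tab[i, ])
  }, "")
  expect_identical(cv$predicted, brute)
  expect_equal(sum(cv$confusion), nrow(tab))
  expect_equal(as.numeric(rowSums(cv$confusion)),
               as.numeric(table(tab$individual_id)))
})

test_that("perfectly separated clusters cross-validate at 100%", {
  set.seed(47)
  tab <- data.frame(v1 = c(rnorm(20, 0), rnorm(20, 50)),
                    individual_id = rep(c("a", "b"), each = 20))
  cv <- loocv(tab, "v1")
  expect_equal(sum(diag(cv$confusion)), 40L)
})

test_that("proportional chance criterion matches hand evaluation", {
  expect_equal(chance_level(c(9, 14, 20, 25, 31, 19)),
               100 * 2624 / 13924)
  expect_lt(abs(chance_level(c(9, 14, 20, 25, 31, 19)) - 18.84), 0.01)
  expect_equal(chance_level(rep(7, 5)), 20)
  expect_equal(chance_level(10), 100)
  expect_error(chance_level(numeric(0)), "positive")
  # balanced groups minimize chance for fixed G
  set.seed(48)
  for (i in 1:20) {
    sizes <- sample(2:40, 5)
    expect_gte(chance_level(sizes), chance_level(rep(mean(sizes), 5)))
  }
})

test_that("Yates chi-square handles expectation, clamping and significance", {
  at_exp <- yates_chi2(20, 100, 0.2)
  expect_lt(at_exp$statistic, 0.05)
  expect_false(at_exp$significant)
  big <- yates_chi2(78, 118, 0.1884)
  expect_gt(big$statistic, 150)
  expect_true(big$significant)
  clamp <- yates_chi2(24, 120, 0.2)  # |O - E| = 0 exactly
  expect_equal(clamp$statistic, 0)
  expect_error(yates_chi2(10, 5, 0.2), "correct")
})

test_that("LOOCV accuracy does not beat resubstitution on null colonies", {
  set.seed(49)
  deltas <- vapply(1:15, function(i) {
    tab <- random_feature_table(g = 4, n = 12, p = 4)
    fit <- fit_lda(tab, paste0("v", 1:4))
    resub <- mean(predict(fit, tab) == tab$individual_id)
    cv <- loocv(tab, paste0("v", 1:4))
    cvacc <- mean(cv$predicted == tab$individual_id)
    resub - cvacc
  }, 0)
  expect_gte(mean(deltas), 0)
})

test_that("the full report classifies a separable colony above chance", {
  cfg <- colony_config(separable_profiles(), c(9, 14, 20, 25, 31, 19),
                       "contact", seed = 50, audio = FALSE)
  res <- suppressWarnings(run_individuality_analysis(cfg))
  r <- res$report
  expect_s3_class(r, "classification_report")
  expect_gt(r$percent_correct_cv, r$chance_percent + 30)
  expect_true(r$significant)
  expect_equal(sum(r$group_sizes), 118)
  expect_output(print(r), "leave-one-out")
})
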