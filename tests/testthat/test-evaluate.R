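# Threshold classification, ROC-optimal threshold, repeated stratified
# CV, and group statistics.

test_that("confusion-cell metrics match hand-enumerated cases", {
  ls1 <- labeled_scores(c(0.2, 0.3, 0.5, 0.6), c(F, F, T, T))
  expect_equal(classify(ls1, 0.4),
               c(sensitivity = 1, specificity = 1, accuracy = 1))
  expect_equal(classify(ls1, 0.7),
               c(sensitivity = 0, specificity = 1, accuracy = 0.5))
  ls2 <- labeled_scores(c(0.2, 0.5, 0.3, 0.6), c(F, F, T, T))
  expect_equal(classify(ls2, 0.4),
               c(sensitivity = 0.5, specificity = 0.5, accuracy = 0.5))
  expect_error(classify(labeled_scores(1:3, c(T, T, T)), 0.5),
               "both classes")
})

test_that("ROC threshold selection matches the worked examples", {
  sep <- labeled_scores(c(0.1, 0.2, 0.8, 0.9), c(F, F, T, T))
  r <- roc_optimal_threshold(sep)
  expect_equal(r$optimal_accuracy, 1)
  expect_gt(r$optimal_threshold, 0.2)
  expect_lt(r$optimal_threshold, 0.8)

  same <- labeled_scores(rep(0.4, 6), c(F, F, T, T, T, T))
  expect_equal(roc_optimal_threshold(same)$optimal_accuracy, 4 / 6)

  ex <- labeled_scores(c(0.1, 0.4, 0.5, 0.45, 0.7, 0.8),
                       c(F, F, F, T, T, T))
  expect_equal(roc_optimal_threshold(ex)$optimal_accuracy, 5 / 6)
})

test_that("ROC optimum equals an exhaustive brute-force sweep", {
  set.seed(31)
  brute <- function(ls) {
    u <- sort(unique(ls$scores))
    thr <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
    max(vapply(thr, function(th) classify(ls, th)["accuracy"], numeric(1)))
  }
  for (i in 1:200) {
    n_pos <- sample(2:25, 1); n_neg <- sample(2:25, 1)
    ls <- labeled_scores(
      c(rnorm(n_neg, 0), rnorm(n_pos, runif(1, 0, 2))),
      rep(c(FALSE, TRUE), c(n_neg, n_pos)))
    r <- roc_optimal_threshold(ls)
    expect_equal(r$optimal_accuracy, brute(ls), tolerance = 1e-12)
    # the returned threshold reproduces the reported accuracy exactly
    expect_equal(unname(classify(ls, r$optimal_threshold)["accuracy"]),
                 r$optimal_accuracy, tolerance = 1e-12)
  }
})

test_that("stratified CV partitions records and is seed-deterministic", {
  set.seed(4)
  ls <- labeled_scores(c(rnorm(11, 0), rnorm(13, 1.5)),
                       rep(c(FALSE, TRUE), c(11, 13)))
  cv1 <- stratified_cv(ls, n_folds = 2, n_runs = 5, seed = 3)
  cv2 <- stratified_cv(ls, n_folds = 2, n_runs = 5, seed = 3)
  expect_identical(cv1, cv2)
  expect_equal(nrow(cv1$per_fold), 10)
  expect_equal(cv1$averages[["accuracy"]],
               mean(cv1$per_fold$accuracy))
  # every record lands in exactly one validation fold per run, with
  # class proportions balanced to within one record
  fold <- wentaf:::.stratified_folds(ls$labels, ls$record_ids, 2, 42)
  expect_setequal(fold, c(1L, 2L))
  expect_lte(abs(sum(ls$labels & fold == 1) - sum(ls$labels & fold == 2)), 1)
  expect_error(stratified_cv(labeled_scores(1:4, c(F, F, F, T))),
               "at least n_folds")
})

test_that("CV averages are invariant to record order", {
  set.seed(6)
  sc <- c(rnorm(12, 0), rnorm(12, 2))
  lb <- rep(c(FALSE, TRUE), each = 12)
  ids <- sprintf("r%02d", 1:24)
  perm <- sample(24)
  cv_a <- stratified_cv(labeled_scores(sc, lb, ids), seed = 5)
  cv_b <- stratified_cv(labeled_scores(sc[perm], lb[perm], ids[perm]),
                        seed = 5)
  expect_equal(cv_a$averages, cv_b$averages, tolerance = 1e-12)
})

test_that("well-separated scores cross-validate nearly perfectly", {
  set.seed(8)
  ls <- labeled_scores(c(rnorm(25, 0, 0.1), rnorm(25, 1, 0.1)),
                       rep(c(FALSE, TRUE), each = 25))
  cv <- stratified_cv(ls, seed = 2)
  expect_gte(cv$averages[["accuracy"]], 0.98)
})

test_that("group statistics match the standard tests", {
  g <- c(1, 2, 3, 4)
  ls_same <- labeled_scores(c(g, g), rep(c(FALSE, TRUE), each = 4))
  gs <- group_stats(ls_same)
  expect_equal(gs$t_statistic, 0, tolerance = 1e-12)
  expect_equal(gs$p_value, 1, tolerance = 1e-12)

  set.seed(12)
  a <- rnorm(30); b <- rnorm(30, 2)
  gs2 <- group_stats(labeled_scores(c(a, b),
                                    rep(c(FALSE, TRUE), each = 30)))
  expect_lt(gs2$p_value, 0.001)
  # cross-check against stats::t.test directly
  expect_equal(gs2$p_value, t.test(b, a, var.equal = TRUE)$p.value)
  expect_gt(gs2$shapiro_p_pos, 0.01)

  # heteroscedastic groups are flagged by Levene
  gs3 <- group_stats(labeled_scores(
    c(rep(1, 10) + rnorm(10, sd = 1e-6), rnorm(10, 1, 1)),
    rep(c(FALSE, TRUE), each = 10)))
  expect_lt(gs3$levene_p, 0.05)

  expect_error(group_stats(labeled_scores(rep(1, 8),
                                          rep(c(F, T), each = 4))),
               "zero variance")
})

test_that("the experiment driver produces one consistent row per family", {
  ex <- cohort_experiment(seed = 7)
  expect_equal(nrow(ex$table), 6)
  expect_setequal(ex$table$family, wavelet_families())
  expect_true(all(ex$table$we_mean_pos > ex$table$we_mean_neg))
  expect_true(all(ex$table$accuracy >= 0 & ex$table$accuracy <= 1))
  expect_equal(dim(ex$scores), c(6, 50))
  expect_false(anyNA(ex$scores))
})

test_that("frequency-selective families classify the cohort alike", {
  ex <- cohort_experiment(seed = 7)
  selective <- c("db5", "coif3", "bior4.4", "sym5")
  agree <- mean(apply(ex$predictions[selective, ], 2,
                      function(col) length(unique(col)) == 1))
  expect_gte(agree, 0.95)
})
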