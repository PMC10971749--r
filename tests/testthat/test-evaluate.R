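test_that("stratified folds balance sizes and classes and respect seeds", {
  y <- rep(c(0L, 1L), c(116L, 104L))
  f <- stratified_kfold(y, k = 10L, seed = 3L)
  expect_identical(sort(unique(f)), 1:10)
  sizes <- tabulate(f, 10L)
  expect_lte(max(sizes) - min(sizes), 1L)
  per_class <- table(y, f)
  expect_lte(max(per_class[1, ]) - min(per_class[1, ]), 1L)
  expect_lte(max(per_class[2, ]) - min(per_class[2, ]), 1L)
  expect_identical(stratified_kfold(y, 10L, seed = 3L), f)
  expect_false(identical(stratified_kfold(y, 10L, seed = 4L), f))
  expect_error(stratified_kfold(rep(c(0L, 1L), c(5L, 100L)), k = 10L),
               "at least")
})

test_that("grouped folds never split a subject across folds", {
  subj <- rep(sprintf("s%02d", 1:30), each = 4L)
  y <- rep(rep(c(0L, 1L), c(16L, 14L)), each = 4L)
  f <- stratified_kfold(y, k = 5L, seed = 1L, group_ids = subj)
  spread <- tapply(f, subj, function(v) length(unique(v)))
  expect_true(all(spread == 1L))
})

test_that("metrics reproduce the published confusion-matrix arithmetic", {
  cm <- matrix(c(111L, 3L, 5L, 101L), nrow = 2,
               dimnames = list(actual = c("healthy", "depressed"),
                               predicted = c("healthy", "depressed")))
  m <- cm_metrics(cm)
  expect_equal(m$accuracy, 100 * 212 / 220)
  expect_equal(round(m$accuracy, 2), 96.36)
  expect_gt(m$kappa, 0.9)

  perfect <- matrix(c(10L, 0L, 0L, 10L), 2)
  mp <- cm_metrics(perfect)
  expect_equal(mp$accuracy, 100)
  expect_equal(mp$kappa, 1)

  constant <- matrix(c(12L, 8L, 0L, 0L), 2)   # everything called healthy
  expect_equal(cm_metrics(constant)$kappa, 0)
})

test_that("metric identities hold over random confusion matrices", {
  set.seed(50)
  for (i in 1:200) {
    cm <- matrix(sample(0:30, 4L, replace = TRUE), 2)
    if (sum(cm) == 0) next
    m <- cm_metrics(cm)
    expect_equal(m$accuracy, 100 * sum(diag(cm)) / sum(cm))
    for (v in c(m$precision, m$recall, m$f_measure)) {
      expect_gte(v, 0); expect_lte(v, 1)
    }
    expect_gte(m$kappa, -1); expect_lte(m$kappa, 1)
    # recall weighted by true-class support equals accuracy/100
    expect_equal(m$recall, sum(diag(cm)) / sum(cm))
  }
})

test_that("Welch t-tests match hand arithmetic and an identical-group null", {
  a <- c(1, 2, 3); b <- c(2, 4, 9)
  fm <- new_fm_for_test <- structure(list(
    instances = data.frame(subject_id = sprintf("s%d", 1:6),
                           label = rep(c(1L, 0L), each = 3L),
                           window_index = 0L),
    values = matrix(c(a, b), ncol = 1, dimnames = list(NULL, "x"))
  ), class = "feature_matrix")
  tt <- feature_ttests(fm)
  # textbook Welch: t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)
  t_manual <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  df_manual <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(tt$t, t_manual, tolerance = 1e-12)
  expect_equal(tt$df, df_manual, tolerance = 1e-12)
  expect_equal(tt$p_value, 2 * pt(-abs(t_manual), df_manual),
               tolerance = 1e-12)

  fm$values <- matrix(c(a, a), ncol = 1, dimnames = list(NULL, "x"))
  tt0 <- feature_ttests(fm)
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p_value, 1)

  summ <- attr(tt, "summaries")[[1]]
  expect_named(summ, c("depressed", "healthy"))
  expect_length(summ$depressed$quartiles, 3L)
})

test_that("ROC/AUC behave canonically and agree with pROC", {
  set.seed(51)
  y <- rbinom(100, 1, 0.45)
  perfect <- as.numeric(y) + runif(100, 0, 0.5)  # separated score bands
  expect_equal(roc_curve(perfect, y)$auc, 1)

  scores <- rnorm(100) + 1.2 * y
  r <- roc_curve(scores, y)
  expect_gte(r$auc, 0); expect_lte(r$auc, 1)
  # invariant under strictly monotone transforms
  expect_equal(roc_curve(exp(scores / 3), y)$auc, r$auc, tolerance = 1e-12)
  # independent implementation
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(r$auc, ref, tolerance = 1e-9)
})

test_that("cross-validation pools fold confusions exactly", {
  fm <- separable_fm()
  rep10 <- run_cv(fm, "common_majority", "bftree", seed = 1L)
  expect_identical(Reduce(`+`, rep10$fold_confusions), rep10$confusion)
  expect_identical(sum(rep10$confusion), 220L)
  expect_equal(rep10$accuracy,
               100 * sum(diag(rep10$confusion)) / 220)
  expect_gte(rep10$accuracy, 90)
  expect_identical(rep10$fvl %% 3L, 0L)
})

test_that("per-fold selection and subject grouping run leak-free", {
  fm <- separable_fm()
  repf <- run_cv(fm, "common_majority", "bftree", seed = 2L,
                 selection_scope = "per_fold", group_by_subject = TRUE)
  expect_gte(repf$accuracy, 85)
  expect_identical(sum(repf$confusion), 220L)
})

test_that("permuted labels collapse performance to chance", {
  fm <- separable_fm()
  set.seed(99)
  fm$instances$label <- sample(fm$instances$label)
  repp <- run_cv(fm, "none", "bftree", seed = 1L)
  expect_lt(abs(repp$kappa), 0.15)
})

test_that("nested CV picks the better strategy and never leaks outer rows", {
  fm <- separable_fm()
  rn <- run_nested_cv(fm, "bftree", outer_k = 5L, inner_k = 3L, seed = 1L,
                      candidate_modes = c("common_majority", "none"))
  expect_identical(sum(rn$confusion), 220L)
  expect_gte(rn$accuracy, 90)
  expect_length(rn$chosen_modes, 5L)

  # agreement with plain CV on a cleanly separable cohort
  rep10 <- run_cv(fm, "common_majority", "bftree", seed = 1L)
  expect_lte(abs(rn$accuracy - rep10$accuracy), 5)
})
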