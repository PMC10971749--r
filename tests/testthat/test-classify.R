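test_that("kNN votes match a brute-force distance oracle", {
  # two tight clusters in 2-D
  x <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1),
             c(5, 5), c(5.1, 5), c(5, 5.1))
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  m <- knn_train(x, y, k = 3L)
  q <- rbind(c(0.05, 0.05), c(5.05, 5.05), c(2.4, 2.4))
  # oracle: normalize with training bounds, rank squared distances
  lo <- apply(x, 2, min); span <- apply(x, 2, max) - lo
  xn <- sweep(sweep(x, 2, lo), 2, span, "/")
  qn <- sweep(sweep(q, 2, lo), 2, span, "/")
  oracle <- apply(qn, 1, function(r) {
    nn <- order(colSums((t(xn) - r)^2))[1:3]
    as.integer(mean(y[nn]) > 0.5)
  })
  expect_identical(predict_model(m, q), oracle)
  expect_equal(predict_model(m, q, type = "prob"), c(0, 1, oracle[3]))
})

test_that("kNN handles duplicated training points and k = 1 self-match", {
  x <- matrix(c(1, 1, 1, 4), ncol = 1)
  y <- c(1L, 1L, 1L, 0L)
  m <- knn_train(x, y, k = 3L)
  expect_identical(predict_model(m, matrix(1)), 1L)

  set.seed(40)
  xr <- matrix(rnorm(40), 20, 2)
  yr <- rbinom(20, 1, 0.5)
  m1 <- knn_train(xr, yr, k = 1L)
  expect_identical(predict_model(m1, xr), yr)

  expect_error(knn_train(xr, yr, k = 21L), "exceeds")
  expect_error(knn_train(xr[0, , drop = FALSE], integer(0)), "empty")
})

test_that("AdaBoost solves a one-threshold problem in one round", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  m <- adaboost_train(x, y, rounds = 10L)
  expect_length(m$stumps, 1L)         # perfect stump stops boosting
  expect_identical(predict_model(m, x), y)
})

test_that("boosting beats the best single stump on an interval concept", {
  # y = 1 only in the middle: no single threshold separates it
  x <- matrix(1:8, ncol = 1)
  y <- c(0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L)
  stump_acc <- mean(predict_model(adaboost_train(x, y, rounds = 1L), x) == y)
  boost_acc <- mean(predict_model(adaboost_train(x, y, rounds = 10L), x) == y)
  expect_equal(stump_acc, 0.75)
  expect_gt(boost_acc, stump_acc)
})

test_that("sample weights stay positive and normalized every round", {
  set.seed(41)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- as.integer(x[, 1] + 0.8 * rnorm(60) > 0)
  m <- adaboost_train(x, y, rounds = 10L)
  expect_gt(length(m$weight_trace), 1L)
  for (w in m$weight_trace) {
    expect_true(all(w > 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
  expect_error(adaboost_train(x, rep(1L, 60)), "both classes")
})

test_that("a threshold-separable problem yields a depth-one tree", {
  set.seed(42)
  x <- matrix(c(rnorm(30, -3), rnorm(30, 3)), ncol = 1)
  y <- rep(c(0L, 1L), each = 30)
  m <- bftree_train(x, y)
  expect_identical(m$e_star, 1L)
  expect_identical(predict_model(m, x), y)
})

test_that("best-first growth expands by decreasing impurity gain on a
           staged fixture", {
  # feature 1 splits everything; feature 2 only resolves a quarter
  set.seed(43)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  x1 <- ifelse(y == 1L, 1, -1) + 0.05 * rnorm(n)
  x2 <- rnorm(n)
  x2[1:20] <- ifelse(y[1:20] == 1L, 1, -1) * 0.1   # weak secondary signal
  m <- bftree_train(cbind(x1, x2), y, prune = FALSE, min_leaf = 1L)
  gains <- m$expansion_gains
  expect_true(all(diff(gains) <= 1e-9))
})

test_that("unpruned trees fit any consistent training set perfectly", {
  set.seed(44)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- rbinom(60, 1, 0.5)
  m <- bftree_train(x, y, prune = FALSE, min_leaf = 1L)
  expect_identical(predict_model(m, x), y)
})

test_that("pruning collapses pure-noise labels to the root", {
  roots <- 0L
  for (i in 1:100) {
    set.seed(i)
    x <- matrix(rnorm(40 * 5), 40, 5)
    y <- rep(c(0L, 1L), 20)
    if (bftree_train(x, y, seed = i)$e_star == 0L) roots <- roots + 1L
  }
  expect_gte(roots, 90L)
})

test_that("fits and predictions are deterministic and column-permutation
           equivariant", {
  set.seed(45)
  x <- matrix(rnorm(80 * 4), 80, 4)
  y <- as.integer(x[, 2] - x[, 4] + rnorm(80, sd = 0.4) > 0)
  xt <- matrix(rnorm(20 * 4), 20, 4)
  perm <- c(3L, 1L, 4L, 2L)
  for (algo in c("knn", "adaboost", "bftree")) {
    p1 <- predict_model(train_classifier(algo, x, y), xt)
    p2 <- predict_model(train_classifier(algo, x, y), xt)
    expect_identical(p1, p2)
    p3 <- predict_model(train_classifier(algo, x[, perm], y), xt[, perm])
    expect_identical(p3, p1)
  }
})

test_that("each classifier reaches 85% (tree: 90%) on the separable cohort", {
  fm <- separable_fm()
  accs <- vapply(c(bftree = "bftree", knn = "knn", adaboost = "adaboost"),
                 function(algo) {
                   run_cv(fm, "common_majority", algo, seed = 1L)$accuracy
                 }, numeric(1))
  expect_gte(accs[["bftree"]], 90)
  expect_true(all(accs >= 85))
})
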