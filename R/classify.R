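#' Train a classifier by name
#'
#' Unified front door to the three from-scratch classifiers: `"knn"`
#' (k-nearest neighbours, k = 3), `"adaboost"` (AdaBoost.M1 over decision
#' stumps) and `"bftree"` (best-first decision tree with internal
#' cross-validated pruning). All models share the [predict_model()] contract.
#'
#' @param algo One of `"knn"`, `"adaboost"`, `"bftree"`.
#' @param x Numeric training matrix (instances x features).
#' @param y Integer class labels (0 = healthy, 1 = depressed).
#' @param ... Passed to the specific trainer.
#' @return A fitted model (class `depscreen_model`).
#' @export
train_classifier <- function(algo = c("bftree", "knn", "adaboost"), x, y, ...) {
  algo <- match.arg(algo)
  switch(algo,
         knn = knn_train(x, y, ...),
         adaboost = adaboost_train(x, y, ...),
         bftree = bftree_train(x, y, ...))
}

#' Predict classes or class-1 scores from a fitted model
#'
#' @param model A model from [train_classifier()].
#' @param x Numeric matrix of rows to classify.
#' @param type `"class"` for 0/1 labels, `"prob"` for the score of the
#'   positive (depressed) class in `[0, 1]`.
#' @return Numeric vector, one value per row of `x`.
#' @export
predict_model <- function(model, x, type = c("class", "prob")) {
  type <- match.arg(type)
  UseMethod("predict_model")
}

as_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
}

# ---------------------------------------------------------------------------
# k-nearest neighbours
# ---------------------------------------------------------------------------

#' k-nearest-neighbour classifier
#'
#' Stores the training rows after min-max normalization (bounds learned on
#' the training data; a constant column maps to 0). Prediction takes the
#' majority vote of the `k` training rows nearest in Euclidean distance;
#' distance ties are broken towards the lower training-row index, and an
#' even vote falls to the label of the single nearest neighbour.
#'
#' @param x Numeric training matrix.
#' @param y 0/1 labels.
#' @param k Number of neighbours (default 3).
#' @return A `knn_model`.
#' @export
knn_train <- function(x, y, k = 3L) {
  x <- as_matrix(x)
  if (nrow(x) == 0L) stop("empty training set", call. = FALSE)
  if (k > nrow(x)) stop("k exceeds the number of training rows", call. = FALSE)
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  span <- ifelse(hi - lo > 0, hi - lo, 1)
  structure(list(algo = "knn", k = as.integer(k), lo = lo, span = span,
                 xn = sweep(sweep(x, 2L, lo), 2L, span, "/"),
                 y = as.integer(y), classes = c(0L, 1L)),
            class = c("knn_model", "depscreen_model"))
}

#' @export
predict_model.knn_model <- function(model, x, type = c("class", "prob")) {
  type <- match.arg(type)
  x <- as_matrix(x)
  xn <- sweep(sweep(x, 2L, model$lo), 2L, model$span, "/")
  out <- numeric(nrow(xn))
  for (i in seq_len(nrow(xn))) {
    d2 <- colSums((t(model$xn) - xn[i, ])^2)
    nn <- order(d2)[seq_len(model$k)]  # stable: ties -> lower row index
    votes1 <- sum(model$y[nn] == 1L)
    if (type == "prob") {
      out[i] <- votes1 / model$k
    } else {
      out[i] <- if (votes1 * 2L == model$k) model$y[nn[1L]]
                else as.integer(votes1 * 2L > model$k)
    }
  }
  if (type == "class") as.integer(out) else out
}

# ---------------------------------------------------------------------------
# AdaBoost.M1 with decision stumps
# ---------------------------------------------------------------------------

# Best weighted-error decision stump. Candidate thresholds sit at midpoints
# of consecutive distinct sorted values of each column; each side predicts
# either class (both polarities searched). Ties are broken towards the
# lower column index, then the lower threshold.
best_stump <- function(x, y, w) {
  n <- nrow(x)
  ys <- ifelse(y == 1L, 1, -1)
  best <- list(err = Inf)
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    xv <- x[ord, j]
    wv <- w[ord] * ys[ord]
    # err(thr, polarity +) = P_w(y=+1, x<=thr) + P_w(y=-1, x>thr)
    cum_pos <- cumsum(pmax(wv, 0))            # weight of +1s up to i
    tot_neg <- sum(pmax(-wv, 0))
    cum_neg <- cumsum(pmax(-wv, 0))
    distinct <- which(diff(xv) > 0)
    if (length(distinct) == 0L) next
    err_right_pos <- cum_pos[distinct] + (tot_neg - cum_neg[distinct])
    for (m in seq_along(distinct)) {
      i <- distinct[m]
      thr <- (xv[i] + xv[i + 1L]) / 2
      e_pos <- err_right_pos[m]          # left -> -1 is wrong for +1s, etc.
      for (pol in c(1, -1)) {
        err <- if (pol == 1) e_pos else sum(w) - e_pos
        if (err < best$err - 1e-12) {
          best <- list(col = j, threshold = thr, polarity = pol, err = err)
        }
      }
    }
  }
  best
}

stump_predict <- function(stump, x) {
  # polarity +1: right side (x > thr) predicts class 1
  side <- ifelse(x[, stump$col] > stump$threshold, 1, -1)
  side * stump$polarity
}

#' AdaBoost classifier over decision stumps
#'
#' AdaBoost.M1 with one-split decision stumps as weak learners and
#' reweighting (not resampling). Learner weight is
#' \eqn{\alpha = \tfrac12 \ln((1-\epsilon)/\epsilon)}. A perfect stump
#' (\eqn{\epsilon = 0}) is kept with a capped weight and stops the boosting;
#' a stump no better than chance (\eqn{\epsilon \ge 0.5}) stops before being
#' added. Sample weights stay positive and renormalize to 1 every round.
#'
#' @param x Numeric training matrix.
#' @param y 0/1 labels; both classes must be present.
#' @param rounds Maximum number of boosting rounds (default 10).
#' @return An `adaboost_model`.
#' @export
adaboost_train <- function(x, y, rounds = 10L) {
  x <- as_matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("AdaBoost requires both classes in the training data", call. = FALSE)
  }
  n <- nrow(x)
  w <- rep(1 / n, n)
  ys <- ifelse(y == 1L, 1, -1)
  stumps <- list()
  alphas <- numeric(0)
  weight_trace <- list()
  for (t in seq_len(rounds)) {
    st <- best_stump(x, y, w)
    if (!is.finite(st$err)) break
    eps <- st$err / sum(w)
    if (eps >= 0.5 - 1e-12) break
    h <- stump_predict(st, x)
    if (eps <= 1e-12) {
      stumps[[length(stumps) + 1L]] <- st
      alphas <- c(alphas, 0.5 * log((1 - 1e-8) / 1e-8))  # capped
      weight_trace[[length(weight_trace) + 1L]] <- w
      break
    }
    alpha <- 0.5 * log((1 - eps) / eps)
    stumps[[length(stumps) + 1L]] <- st
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * ys * h)
    w <- w / sum(w)
    weight_trace[[length(weight_trace) + 1L]] <- w
  }
  structure(list(algo = "adaboost", stumps = stumps, alphas = alphas,
                 majority = as.integer(mean(y) >= 0.5),
                 weight_trace = weight_trace),
            class = c("adaboost_model", "depscreen_model"))
}

#' @export
predict_model.adaboost_model <- function(model, x, type = c("class", "prob")) {
  type <- match.arg(type)
  x <- as_matrix(x)
  if (length(model$stumps) == 0L) {
    cls <- rep(model$majority, nrow(x))
    return(if (type == "class") cls else as.numeric(cls))
  }
  score <- rep(0, nrow(x))
  for (t in seq_along(model$stumps)) {
    score <- score + model$alphas[t] * stump_predict(model$stumps[[t]], x)
  }
  margin <- score / sum(model$alphas)     # in [-1, 1]
  if (type == "prob") (margin + 1) / 2 else as.integer(margin > 0)
}

# ---------------------------------------------------------------------------
# Best-first decision tree
# ---------------------------------------------------------------------------

gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Best binary split of the rows in `idx`: over all columns, thresholds at
# midpoints of consecutive distinct values; gain is the decrease in
# count-weighted Gini impurity. Ties -> lower column index, lower threshold.
best_split <- function(x, y, idx, min_leaf) {
  best <- list(gain = 0)
  n <- length(idx)
  for (j in seq_len(ncol(x))) {
    ord <- idx[order(x[idx, j])]
    xv <- x[ord, j]
    yv <- y[ord]
    cum1 <- cumsum(yv == 1L)
    tot1 <- cum1[n]
    cand <- which(diff(xv) > 0)
    cand <- cand[cand >= min_leaf & (n - cand) >= min_leaf]
    if (length(cand) == 0L) next
    parent <- n * gini(c(n - tot1, tot1))
    for (i in cand) {
      l1 <- cum1[i]; r1 <- tot1 - l1
      child <- i * gini(c(i - l1, l1)) + (n - i) * gini(c(n - i - r1, r1))
      gain <- parent - child
      if (gain > best$gain + 1e-12) {
        best <- list(gain = gain, col = j, threshold = (xv[i] + xv[i + 1L]) / 2)
      }
    }
  }
  best
}

# Grow a best-first tree: repeatedly expand the frontier leaf with the
# largest impurity decrease. Returns a flat node table; each internal node
# records the expansion rank at which it was split, so the tree can be
# evaluated truncated to its first E expansions.
grow_bftree <- function(x, y, min_leaf = 2L, max_expansions = Inf) {
  nodes <- list(list(idx = seq_len(nrow(x)), counts = c(sum(y == 0L), sum(y == 1L)),
                     split = NULL, rank = NA_integer_,
                     left = NA_integer_, right = NA_integer_))
  frontier <- 1L   # node ids still expandable
  gains <- list()
  expansion_gains <- numeric(0)
  compute <- function(id) best_split(x, y, nodes[[id]]$idx, min_leaf)
  gains[[1L]] <- compute(1L)
  rank <- 0L
  while (length(frontier) > 0L && rank < max_expansions) {
    g <- vapply(frontier, function(id) gains[[id]]$gain, numeric(1))
    if (max(g) <= 0) break
    pick <- frontier[which.max(g)]   # first max: earliest-created leaf wins
    rank <- rank + 1L
    sp <- gains[[pick]]
    idx <- nodes[[pick]]$idx
    left_idx <- idx[x[idx, sp$col] <= sp$threshold]
    right_idx <- setdiff(idx, left_idx)
    lid <- length(nodes) + 1L
    rid <- length(nodes) + 2L
    nodes[[pick]]$split <- list(col = sp$col, threshold = sp$threshold)
    nodes[[pick]]$rank <- rank
    nodes[[pick]]$left <- lid
    nodes[[pick]]$right <- rid
    nodes[[lid]] <- list(idx = left_idx,
                         counts = c(sum(y[left_idx] == 0L), sum(y[left_idx] == 1L)),
                         split = NULL, rank = NA_integer_,
                         left = NA_integer_, right = NA_integer_)
    nodes[[rid]] <- list(idx = right_idx,
                         counts = c(sum(y[right_idx] == 0L), sum(y[right_idx] == 1L)),
                         split = NULL, rank = NA_integer_,
                         left = NA_integer_, right = NA_integer_)
    expansion_gains <- c(expansion_gains, sp$gain)
    frontier <- setdiff(frontier, pick)
    for (id in c(lid, rid)) {
      gains[[id]] <- compute(id)
      if (gains[[id]]$gain > 0) frontier <- c(frontier, id)
    }
  }
  for (i in seq_along(nodes)) nodes[[i]]$idx <- NULL
  list(nodes = nodes, n_expansions = rank, expansion_gains = expansion_gains)
}

# Predict from a grown tree truncated to its first `e` expansions.
tree_predict <- function(tree, x, e = Inf, type = "class") {
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    id <- 1L
    repeat {
      node <- tree$nodes[[id]]
      if (is.null(node$split) || is.na(node$rank) || node$rank > e) break
      id <- if (x[i, node$split$col] <= node$split$threshold) node$left
            else node$right
    }
    counts <- tree$nodes[[id]]$counts
    out[i] <- if (type == "prob") {
      if (sum(counts) == 0) 0.5 else counts[2L] / sum(counts)
    } else {
      # majority class; ties -> class 0
      as.integer(counts[2L] > counts[1L])
    }
  }
  if (type == "class") as.integer(out) else out
}

#' Best-first decision tree with cross-validated pruning
#'
#' Grows a binary tree on numeric features by best-first expansion: the
#' frontier leaf whose best split yields the largest decrease in
#' count-weighted Gini impurity is expanded next, until leaves are pure,
#' smaller than `2 * min_leaf`, or offer no impurity decrease. Pruning runs
#' an internal `pruning_folds`-fold cross-validation over the number of
#' expansions: the root is kept unless the best tree size beats it by more
#' than two cross-fold standard deviations of the CV error, otherwise the
#' smallest size within one such spread of the minimum wins (a conservative
#' one-SE-style rule, so chance dips on uninformative data do not grow the
#' tree). The tree is then regrown on all data stopped after the chosen
#' number of expansions `E*`.
#'
#' @param x Numeric training matrix.
#' @param y 0/1 labels; both classes must be present.
#' @param min_leaf Minimum instances in a leaf (default 2).
#' @param pruning_folds Folds of the internal pruning CV (default 5);
#'   set `prune = FALSE` to keep the fully grown tree.
#' @param prune Whether to prune (default TRUE).
#' @param seed Seed for the internal pruning-fold shuffle.
#' @return A `bftree_model`.
#' @export
bftree_train <- function(x, y, min_leaf = 2L, pruning_folds = 5L,
                         prune = TRUE, seed = 1L) {
  x <- as_matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("tree induction requires both classes in the training data",
         call. = FALSE)
  }
  if (min_leaf > nrow(x)) stop("min_leaf exceeds training size", call. = FALSE)
  e_star <- Inf
  pruning_folds <- min(pruning_folds, min(table(y)))  # tiny-class guard
  if (prune && pruning_folds >= 2L) {
    folds <- stratified_kfold(y, k = pruning_folds, seed = seed)
    max_e <- 0L
    fold_errors <- list()
    for (f in seq_len(pruning_folds)) {
      tr <- which(folds != f)
      va <- which(folds == f)
      if (length(unique(y[tr])) < 2L) next
      tree <- grow_bftree(x[tr, , drop = FALSE], y[tr], min_leaf)
      errs <- vapply(0:tree$n_expansions, function(e) {
        mean(tree_predict(tree, x[va, , drop = FALSE], e) != y[va])
      }, numeric(1))
      fold_errors[[length(fold_errors) + 1L]] <- errs
      max_e <- max(max_e, tree$n_expansions)
    }
    if (length(fold_errors) > 0L) {
      # per-E fold errors (constant once a fold's tree stops growing)
      fold_mat <- vapply(fold_errors, function(errs) {
        vapply(0:max_e, function(e) errs[min(e, length(errs) - 1L) + 1L],
               numeric(1))
      }, numeric(max_e + 1L))
      fold_mat <- matrix(fold_mat, nrow = max_e + 1L)
      curve <- rowMeans(fold_mat)
      # Conservative size choice. The minimum of the CV curve over many
      # candidate sizes is biased low on uninformative data, so (a) the
      # root is kept unless the best tree beats it by more than two
      # cross-fold standard deviations of the error, and (b) otherwise the
      # smallest tree within one spread of the minimum is kept.
      e_min <- which.min(curve)
      spread <- stats::sd(fold_mat[e_min, ])
      if (!is.finite(spread)) spread <- 0
      e_star <- if (curve[1L] <= curve[e_min] + 2 * spread) 0L
                else which(curve <= curve[e_min] + spread)[1L] - 1L
    }
  }
  tree <- grow_bftree(x, y, min_leaf, max_expansions = e_star)
  structure(list(algo = "bftree", tree = tree, e_star = tree$n_expansions,
                 expansion_gains = tree$expansion_gains),
            class = c("bftree_model", "depscreen_model"))
}

#' @export
predict_model.bftree_model <- function(model, x, type = c("class", "prob")) {
  type <- match.arg(type)
  tree_predict(model$tree, as_matrix(x), type = type)
}

#' @export
print.depscreen_model <- function(x, ...) {
  detail <- switch(x$algo,
                   knn = sprintf("k=%d, %d stored rows", x$k, nrow(x$xn)),
                   adaboost = sprintf("%d stumps", length(x$stumps)),
                   bftree = sprintf("%d expansions", x$e_star))
  cat(sprintf("<depscreen_model:%s> %s\n", x$algo, detail))
  invisible(x)
}
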