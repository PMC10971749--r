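#' Stratified k-fold assignment
#'
#' Assigns instances to `k` folds so that fold sizes differ by at most one
#' and each class's instances are spread across folds within one instance of
#' proportionality. With `group_ids`, whole groups (e.g. all windows of a
#' subject) are assigned to a single fold, stratified by the group's label —
#' the leak-free protocol when several windows per subject enter the matrix.
#'
#' @param labels 0/1 class labels, one per instance.
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @param group_ids Optional vector of group identifiers, one per instance.
#' @return Integer vector of fold ids (1..k), one per instance.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L, group_ids = NULL) {
  labels <- as.integer(labels)
  if (!is.null(group_ids)) {
    grp <- unique(group_ids)
    grp_label <- labels[match(grp, group_ids)]
    gf <- stratified_kfold(grp_label, k, seed)
    return(gf[match(group_ids, grp)])
  }
  if (any(table(labels) < k)) {
    stop(sprintf("each class needs at least k=%d instances", k), call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(labels))
  ptr <- 0L
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((ptr + seq_along(idx) - 1L) %% k) + 1L
    ptr <- (ptr + length(idx)) %% k
  }
  fold
}

#' Confusion matrix from actual and predicted labels
#'
#' @param actual,predicted 0/1 label vectors.
#' @return 2x2 integer matrix indexed (actual, predicted) over
#'   (healthy, depressed).
#' @export
confusion_matrix <- function(actual, predicted) {
  cm <- matrix(0L, 2L, 2L,
               dimnames = list(actual = c("healthy", "depressed"),
                               predicted = c("healthy", "depressed")))
  for (i in seq_along(actual)) {
    cm[actual[i] + 1L, predicted[i] + 1L] <- cm[actual[i] + 1L, predicted[i] + 1L] + 1L
  }
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy (percent), support-weighted precision, recall and F-measure
#' (the per-class values averaged with weights proportional to each class's
#' true count), and Cohen's kappa. A class never predicted contributes
#' precision 0; the degenerate kappa with chance agreement 1 is defined
#' as 0.
#'
#' @param cm 2x2 confusion matrix indexed (actual, predicted).
#' @return Named list: `accuracy` (percent), `precision`, `recall`,
#'   `f_measure`, `kappa`, plus the per-class rates.
#' @export
cm_metrics <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n <= 0) stop("empty confusion matrix", call. = FALSE)
  acc <- 100 * sum(diag(cm)) / n
  support <- rowSums(cm)
  prec <- vapply(1:2, function(c) {
    d <- sum(cm[, c]); if (d == 0) 0 else cm[c, c] / d
  }, numeric(1))
  rec <- vapply(1:2, function(c) {
    d <- sum(cm[c, ]); if (d == 0) 0 else cm[c, c] / d
  }, numeric(1))
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wt <- support / n
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) 0 else (po - pe) / (1 - pe)
  list(accuracy = acc,
       precision = sum(wt * prec), recall = sum(wt * rec),
       f_measure = sum(wt * f1), kappa = kappa,
       per_class = data.frame(class = c("healthy", "depressed"),
                              precision = prec, recall = rec, f = f1,
                              support = support))
}

#' ROC curve and AUC from class-1 scores
#'
#' Sweeps every unique score as a decision threshold (predict depressed when
#' score > threshold) and integrates the resulting curve by the trapezoid
#' rule over the false-positive rate.
#'
#' @param scores Numeric scores, higher = more depressed-like.
#' @param labels 0/1 actual labels.
#' @return List with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both classes", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- vapply(thr, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & labels == 0L) / n_neg,
      tpr = sum(pred & labels == 1L) / n_pos)
  }, numeric(2))
  fpr <- pts["fpr", ]
  tpr <- pts["tpr", ]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Per-feature Welch t-tests between groups
#'
#' Welch's two-sample t-test (unequal variances, Welch-Satterthwaite
#' degrees of freedom) for every requested feature column, depressed versus
#' healthy instances, with Benjamini-Hochberg q-values added alongside the
#' raw p-values. Per-group quartiles and kernel-density points sufficient to
#' draw violin plots are attached as the `"summaries"` attribute.
#'
#' @param fm A [feature_matrix].
#' @param columns Feature columns to test (default all).
#' @return data.frame with `column`, `t`, `df`, `p_value`, `q_value`.
#' @export
feature_ttests <- function(fm, columns = NULL) {
  columns <- columns %||% colnames(fm$values)
  y <- fm$instances$label
  if (sum(y == 0L) < 2L || sum(y == 1L) < 2L) {
    stop("each group needs at least two instances", call. = FALSE)
  }
  res <- lapply(columns, function(cl) {
    a <- fm$values[y == 1L, cl]
    b <- fm$values[y == 0L, cl]
    tt <- stats::t.test(a, b)           # Welch by default
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value,
         summary = lapply(list(depressed = a, healthy = b), function(v) {
           d <- stats::density(v, n = 64L)
           list(quartiles = unname(stats::quantile(v, c(0.25, 0.5, 0.75))),
                density_x = d$x, density_y = d$y)
         }))
  })
  out <- data.frame(
    column = columns,
    t = vapply(res, `[[`, numeric(1), "t"),
    df = vapply(res, `[[`, numeric(1), "df"),
    p_value = vapply(res, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "summaries") <- lapply(res, `[[`, "summary")
  out
}

new_eval_report <- function(mode, algo, selection, fold_cms, pooled_cm,
                            metrics, roc, ttests, seed, extra = list()) {
  structure(c(list(
    mode = mode, algo = algo,
    selection_mode = selection$mode %||% NA_character_,
    fvl = selection$fvl %||% NA_integer_,
    final_columns = selection$final_columns,
    fold_confusions = fold_cms,
    confusion = pooled_cm,
    accuracy = metrics$accuracy, precision = metrics$precision,
    recall = metrics$recall, f_measure = metrics$f_measure,
    kappa = metrics$kappa,
    roc = roc, ttests = ttests, seed = seed
  ), extra), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s | %s | selection=%s (fvl=%s)\n",
              x$mode, x$algo, x$selection_mode, x$fvl))
  cat(sprintf("  accuracy %.2f%% | precision %.3f | recall %.3f | F %.3f | kappa %.3f | AUC %.3f\n",
              x$accuracy, x$precision, x$recall, x$f_measure, x$kappa,
              x$roc$auc))
  print(x$confusion)
  invisible(x)
}

fit_predict_fold <- function(fm, cols, train_rows, test_rows, algo, ...) {
  xtr <- fm$values[train_rows, cols, drop = FALSE]
  xte <- fm$values[test_rows, cols, drop = FALSE]
  model <- train_classifier(algo, xtr, fm$instances$label[train_rows], ...)
  list(class = predict_model(model, xte, "class"),
       prob = predict_model(model, xte, "prob"))
}

#' Stratified 10-fold cross-validated evaluation
#'
#' Runs the selection strategy and a classifier under stratified k-fold
#' cross-validation, pooling the held-out predictions of all folds into one
#' confusion matrix, metric set and ROC curve. With
#' `selection_scope = "global"` (the default) feature selection is computed
#' once on the whole matrix before the folds are formed — the conventional
#' workflow when selection is treated as part of feature definition; with
#' `"per_fold"` it is recomputed on each fold's training rows, which avoids
#' selection leakage and is the recommended protocol.
#'
#' @param fm A [feature_matrix].
#' @param selection_mode Strategy passed to [select_features()].
#' @param algo Classifier name for [train_classifier()].
#' @param k Number of folds.
#' @param seed Fold-assignment (and model) seed.
#' @param selection_scope `"global"` or `"per_fold"`.
#' @param group_by_subject Keep all windows of a subject in one fold.
#' @param quorum Majority quorum for `common_majority` selection.
#' @param ... Extra arguments for the classifier trainer.
#' @return An `eval_report`.
#' @export
run_cv <- function(fm, selection_mode = "common_majority",
                   algo = "bftree", k = 10L, seed = 1L,
                   selection_scope = c("global", "per_fold"),
                   group_by_subject = FALSE, quorum = 2L, ...) {
  selection_scope <- match.arg(selection_scope)
  y <- fm$instances$label
  folds <- stratified_kfold(
    y, k, seed,
    group_ids = if (group_by_subject) fm$instances$subject_id else NULL
  )
  sel_global <- select_features(fm, selection_mode, quorum)
  fold_cms <- list()
  pred_class <- integer(nrow(fm$values))
  pred_prob <- numeric(nrow(fm$values))
  for (f in seq_len(k)) {
    test_rows <- which(folds == f)
    train_rows <- which(folds != f)
    sel <- if (selection_scope == "global") sel_global
           else select_features(fm, selection_mode, quorum, rows = train_rows)
    pr <- fit_predict_fold(fm, sel$final_columns, train_rows, test_rows,
                           algo, ...)
    pred_class[test_rows] <- pr$class
    pred_prob[test_rows] <- pr$prob
    fold_cms[[f]] <- confusion_matrix(y[test_rows], pr$class)
  }
  pooled <- Reduce(`+`, fold_cms)
  new_eval_report(
    mode = "10fold", algo = algo, selection = sel_global,
    fold_cms = fold_cms, pooled_cm = pooled, metrics = cm_metrics(pooled),
    roc = roc_curve(pred_prob, y),
    ttests = feature_ttests(fm, sel_global$final_columns),
    seed = seed,
    extra = list(selection_scope = selection_scope,
                 group_by_subject = group_by_subject,
                 selection = sel_global)
  )
}

#' Nested cross-validated evaluation
#'
#' Outer stratified folds estimate performance; on each outer-training set
#' an inner stratified CV (selection always refit on inner-training rows)
#' picks the selection strategy by pooled inner accuracy, ties going to the
#' candidate with fewer final columns and then to the earlier candidate in
#' `candidate_modes`. The winning strategy is refit on the whole
#' outer-training set, and outer held-out predictions are pooled. The inner
#' loop never sees outer test rows.
#'
#' @param fm A [feature_matrix].
#' @param algo Classifier name.
#' @param outer_k,inner_k Outer/inner fold counts.
#' @param seed Seed for both fold layers.
#' @param candidate_modes Selection strategies the inner loop chooses among.
#' @param group_by_subject Keep all windows of a subject in one outer fold.
#' @param quorum Majority quorum for `common_majority`.
#' @param ... Extra classifier arguments.
#' @return An `eval_report`; `$chosen_modes` records the per-outer-fold
#'   winners.
#' @export
run_nested_cv <- function(fm, algo = "bftree", outer_k = 10L, inner_k = 5L,
                          seed = 1L,
                          candidate_modes = c("common_majority",
                                              "early_fusion", "late_fusion",
                                              "none"),
                          group_by_subject = FALSE, quorum = 2L, ...) {
  y <- fm$instances$label
  outer <- stratified_kfold(
    y, outer_k, seed,
    group_ids = if (group_by_subject) fm$instances$subject_id else NULL
  )
  fold_cms <- list()
  chosen <- character(outer_k)
  pred_class <- integer(nrow(fm$values))
  pred_prob <- numeric(nrow(fm$values))
  for (f in seq_len(outer_k)) {
    test_rows <- which(outer == f)
    train_rows <- which(outer != f)
    inner <- stratified_kfold(y[train_rows], inner_k, seed + f)
    score <- numeric(length(candidate_modes))
    fvls <- integer(length(candidate_modes))
    for (m in seq_along(candidate_modes)) {
      ok <- 0L; tot <- 0L; fvl_m <- NA_integer_
      for (g in seq_len(inner_k)) {
        itr <- train_rows[inner != g]
        iva <- train_rows[inner == g]
        sel <- tryCatch(
          select_features(fm, candidate_modes[m], quorum, rows = itr),
          error = function(e) NULL)
        if (is.null(sel)) next
        fvl_m <- sel$fvl
        pr <- fit_predict_fold(fm, sel$final_columns, itr, iva, algo, ...)
        ok <- ok + sum(pr$class == y[iva])
        tot <- tot + length(iva)
      }
      score[m] <- if (tot > 0L) ok / tot else -Inf
      fvls[m] <- fvl_m
    }
    # best inner accuracy; ties -> fewer features, then candidate order
    best <- order(-score, fvls, seq_along(candidate_modes))[1L]
    chosen[f] <- candidate_modes[best]
    sel <- select_features(fm, chosen[f], quorum, rows = train_rows)
    pr <- fit_predict_fold(fm, sel$final_columns, train_rows, test_rows,
                           algo, ...)
    pred_class[test_rows] <- pr$class
    pred_prob[test_rows] <- pr$prob
    fold_cms[[f]] <- confusion_matrix(y[test_rows], pr$class)
  }
  pooled <- Reduce(`+`, fold_cms)
  sel_desc <- list(mode = paste0("nested(", paste(unique(chosen),
                                                  collapse = "/"), ")"),
                   fvl = NA_integer_, final_columns = NULL)
  new_eval_report(
    mode = "nested", algo = algo, selection = sel_desc,
    fold_cms = fold_cms, pooled_cm = pooled, metrics = cm_metrics(pooled),
    roc = roc_curve(pred_prob, y),
    ttests = NULL, seed = seed,
    extra = list(chosen_modes = chosen, inner_k = inner_k,
                 group_by_subject = group_by_subject)
  )
}
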