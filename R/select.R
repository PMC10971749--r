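#' Correlation-based feature-subset merit
#'
#' Hall's CFS merit of a candidate subset of `k` feature columns:
#' \deqn{M = k \bar{r}_{cf} / \sqrt{k + k(k-1)\bar{r}_{ff}}}
#' where \eqn{\bar{r}_{cf}} is the mean absolute point-biserial correlation
#' of each feature with the binary class label and \eqn{\bar{r}_{ff}} the
#' mean absolute pairwise Pearson correlation between the features. High
#' merit rewards subsets that track the class while being mutually
#' non-redundant. The merit of the empty set is 0.
#'
#' @param x Numeric matrix whose columns are the candidate subset.
#' @param y Class labels (0/1), one per row of `x`.
#' @return The merit (dimensionless scalar).
#' @export
cfs_merit <- function(x, y) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  k <- ncol(x)
  if (k == 0L) return(0)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds <= 0)) {
    bad <- colnames(x)[sds <= 0] %||% which(sds <= 0)
    stop(sprintf("zero-variance feature column: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  r_cf <- mean(abs(stats::cor(x, as.numeric(y))))
  if (k == 1L) return(r_cf)
  cm <- abs(stats::cor(x))
  r_ff <- mean(cm[upper.tri(cm)])
  k * r_cf / sqrt(k + k * (k - 1) * r_ff)
}

subset_key <- function(idx) paste0("s", paste(sort(idx), collapse = ","))

#' Best-first forward search over feature subsets
#'
#' Searches the subset lattice from the empty set, always expanding the open
#' subset of highest [cfs_merit()] by adding one feature at a time, and
#' terminating after `stale_limit` consecutive expansions that fail to
#' improve the best merit seen. Merit ties between candidate features are
#' broken towards the lower column index, making the search deterministic.
#'
#' @param x Numeric matrix of candidate feature columns.
#' @param y Class labels (0/1).
#' @param stale_limit Consecutive non-improving expansions tolerated before
#'   the search stops.
#' @return A list with `subset` (integer column indices, ascending), `names`
#'   (their column names, if present) and `merit`.
#' @export
best_first_search <- function(x, y, stale_limit = 5L) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  p <- ncol(x)
  if (p < 1L) stop("at least one candidate feature is required", call. = FALSE)
  merit_of <- function(idx) cfs_merit(x[, idx, drop = FALSE], y)

  visited <- new.env(parent = emptyenv())
  open_sets <- list(integer(0))
  open_merit <- 0
  assign(subset_key(integer(0)), TRUE, envir = visited)
  best_set <- integer(0)
  best_merit <- 0
  stale <- 0L

  while (length(open_sets) > 0L && stale < stale_limit) {
    pick <- which.max(open_merit)  # first maximum: earliest-inserted wins ties
    current <- open_sets[[pick]]
    open_sets <- open_sets[-pick]
    open_merit <- open_merit[-pick]

    improved <- FALSE
    for (f in seq_len(p)) {       # ascending index order fixes merit ties
      if (f %in% current) next
      child <- sort(c(current, f))
      key <- subset_key(child)
      if (!is.null(visited[[key]])) next
      assign(key, TRUE, envir = visited)
      m <- merit_of(child)
      open_sets[[length(open_sets) + 1L]] <- child
      open_merit <- c(open_merit, m)
      if (m > best_merit + 1e-12) {
        best_merit <- m
        best_set <- child
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  list(subset = best_set,
       names = if (!is.null(colnames(x))) colnames(x)[best_set] else NULL,
       merit = best_merit)
}

new_selection_result <- function(mode, per_electrode_subsets, merits,
                                 common_features, final_columns) {
  structure(list(
    mode = mode,
    per_electrode_subsets = per_electrode_subsets,
    merits = merits,
    common_features = common_features,
    final_columns = final_columns,
    fvl = length(final_columns)
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> mode=%s fvl=%d\n", x$mode, x$fvl))
  if (!is.null(x$per_electrode_subsets)) {
    for (e in names(x$per_electrode_subsets)) {
      cat(sprintf("  %s: %s (merit %.4f)\n", e,
                  paste(x$per_electrode_subsets[[e]], collapse = ", "),
                  x$merits[[e]]))
    }
  }
  if (!is.null(x$common_features)) {
    cat("  common:", paste(x$common_features, collapse = ", "), "\n")
  }
  invisible(x)
}

electrode_block <- function(fm, electrode) {
  cols <- paste(electrode, FEATURE_NAMES, sep = "_")
  cols[cols %in% colnames(fm$values)]
}

electrodes_of <- function(fm) {
  # feature names themselves contain underscores, so strip the known
  # feature suffix rather than splitting on the last "_"
  suffix <- paste0("_(", paste(FEATURE_NAMES, collapse = "|"), ")$")
  unique(sub(suffix, "", colnames(fm$values)))
}

per_electrode_search <- function(fm, rows = NULL) {
  rows <- rows %||% seq_len(nrow(fm$values))
  y <- fm$instances$label[rows]
  electrodes <- electrodes_of(fm)
  subsets <- list()
  merits <- list()
  for (e in electrodes) {
    cols <- electrode_block(fm, e)
    res <- best_first_search(fm$values[rows, cols, drop = FALSE], y)
    subsets[[e]] <- sub(paste0("^", e, "_"), "", res$names)
    merits[[e]] <- res$merit
  }
  list(subsets = subsets, merits = merits, electrodes = electrodes)
}

#' Majority-rule fusion of per-electrode feature subsets
#'
#' A feature name enters the common set when it appears in the selected
#' subset of at least `quorum` electrodes (default 2 of 3). The fused
#' column set contains every (electrode, common feature) pair, so the final
#' feature-vector length is `|common| * |electrodes|`.
#'
#' @param subsets Named list: electrode -> character vector of feature names.
#' @param quorum Minimum number of electrode subsets a feature must appear in.
#' @param electrodes Electrode order for the fused columns (default the
#'   names of `subsets`).
#' @return A `selection_result` with mode `"common_majority"`.
#' @export
fuse_majority <- function(subsets, quorum = 2L, electrodes = names(subsets)) {
  if (length(subsets) < quorum) {
    stop("need at least `quorum` electrode subsets", call. = FALSE)
  }
  counts <- table(unlist(lapply(subsets, unique)))
  common <- FEATURE_NAMES[FEATURE_NAMES %in%
                            names(counts)[counts >= quorum]]
  if (length(common) == 0L) {
    stop("majority fusion selected no common features", call. = FALSE)
  }
  final <- as.vector(vapply(electrodes,
                            function(e) paste(e, common, sep = "_"),
                            character(length(common))))
  new_selection_result("common_majority", subsets, NULL, common, final)
}

#' Feature selection strategies
#'
#' Four strategies over a [feature_matrix]:
#' * `common_majority` — CFS with best-first search run independently on
#'   each electrode's 12 columns, fused by the majority rule
#'   ([fuse_majority()]);
#' * `early_fusion` — one joint CFS search over all columns;
#' * `late_fusion` — the per-electrode subsets concatenated with their
#'   electrode tags;
#' * `none` — all columns pass through.
#'
#' @param fm A [feature_matrix].
#' @param mode Strategy name.
#' @param quorum Majority quorum (`common_majority` only).
#' @param rows Optional row subset (e.g. a training fold) on which the
#'   selection statistics are computed.
#' @return A `selection_result` with fields `mode`, `per_electrode_subsets`,
#'   `merits`, `common_features`, `final_columns` and `fvl`.
#' @export
select_features <- function(fm,
                            mode = c("common_majority", "early_fusion",
                                     "late_fusion", "none"),
                            quorum = 2L, rows = NULL) {
  mode <- match.arg(mode)
  switch(mode,
         common_majority = select_common_majority(fm, quorum, rows),
         early_fusion = select_early_fusion(fm, rows),
         late_fusion = select_late_fusion(fm, rows),
         none = new_selection_result("none", NULL, NULL, NULL,
                                     colnames(fm$values)))
}

#' @rdname select_features
#' @export
select_common_majority <- function(fm, quorum = 2L, rows = NULL) {
  pes <- per_electrode_search(fm, rows)
  out <- fuse_majority(pes$subsets, quorum, pes$electrodes)
  out$merits <- pes$merits
  out
}

#' @rdname select_features
#' @export
select_early_fusion <- function(fm, rows = NULL) {
  rows <- rows %||% seq_len(nrow(fm$values))
  res <- best_first_search(fm$values[rows, , drop = FALSE],
                           fm$instances$label[rows])
  if (length(res$subset) == 0L) {
    stop("early-fusion selection returned no features", call. = FALSE)
  }
  new_selection_result("early_fusion", NULL, list(joint = res$merit),
                       NULL, res$names)
}

#' @rdname select_features
#' @export
select_late_fusion <- function(fm, rows = NULL) {
  pes <- per_electrode_search(fm, rows)
  if (all(lengths(pes$subsets) == 0L)) {
    stop("late-fusion selection returned no features", call. = FALSE)
  }
  final <- unlist(lapply(pes$electrodes, function(e) {
    if (length(pes$subsets[[e]])) paste(e, pes$subsets[[e]], sep = "_")
    else character(0)
  }))
  new_selection_result("late_fusion", pes$subsets, pes$merits, NULL, final)
}
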