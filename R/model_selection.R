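#' Classification metrics from confusion counts
#'
#' Precision (positive predictive value), recall (sensitivity), F-score and
#' Matthews correlation coefficient from a binary confusion table. A
#' degenerate denominator (e.g. no positive predictions) yields 0 for the
#' affected metric, with a warning.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts; their total must be
#'   positive.
#' @return Named list with `precision`, `recall`, `f_score`, `mcc`.
#' @export
#' @examples
#' compute_metrics(tp = 5, fp = 0, tn = 5, fn = 0)
compute_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("negative confusion count")
  if (sum(counts) == 0) stop("all-zero confusion counts")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("degenerate denominator for ", what, "; returning 0")
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f_score <- safe_div(2 * precision * recall, precision + recall, "F-score")
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) {
    warning("degenerate denominator for MCC; returning 0")
    0
  } else {
    (tp * tn - fp * fn) / mcc_den
  }
  list(precision = precision, recall = recall, f_score = f_score,
       mcc = mcc)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair statistic: the fraction of
#' (positive, negative) instance pairs in which the positive instance
#' scores higher, ties counting one half. Invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (logical, 0/1, or a two-level factor whose
#'   second level is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2L]
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both label values must be present")
  r <- rank(scores)   # midranks: tied pairs count 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Bootstrap cross-validation of a binary classifier
#'
#' Repeated stratified random resampling: in each of `n_runs x n_folds`
#' folds, 80% of each class is drawn (without replacement) as the training
#' portion and the remaining 20% is the test portion. When the classifier
#' family carries a hyperparameter grid, the grid is searched within each
#' fold's training portion (inner stratified 75/25 split, scored by AUC)
#' before the fold model is fitted. Per-fold precision, recall, F-score,
#' MCC (predicted label at probability 0.5) and AUC are recorded.
#'
#' @param x Feature matrix (rows = instances).
#' @param y Binary labels: logical, or factor/character with exactly two
#'   values; `TRUE`/the specific class is the positive class.
#' @param spec A [classifier_spec()].
#' @param n_runs,n_folds Resampling plan; the default 10 x 5 yields 50
#'   per-fold records.
#' @param seed Integer seed.
#' @param train_frac Training fraction per fold (default 0.8).
#' @return A `cv_metrics` data.frame with columns `run`, `fold`,
#'   `precision`, `recall`, `f_score`, `mcc`, `auc`.
#' @export
bootstrap_cv <- function(x, y, spec = classifier_spec("RF"),
                         n_runs = 10L, n_folds = 5L, seed = 1L,
                         train_frac = 0.8) {
  x <- as.matrix(x)
  y <- as_binary_factor(y)
  if (min(table(y)) < 2L) stop("each class needs at least 2 instances")
  recs <- vector("list", n_runs * n_folds)
  i <- 0L
  for (run in seq_len(n_runs)) {
    for (fold in seq_len(n_folds)) {
      i <- i + 1L
      set.seed(seed + 1000L * run + fold)
      idx <- stratified_split(y, train_frac)
      m <- fit_with_grid(x[idx$train, , drop = FALSE], y[idx$train], spec)
      p <- predict_prob(m, x[idx$test, , drop = FALSE])
      truth <- y[idx$test] == "pos"
      pred <- p >= 0.5
      met <- suppressWarnings(compute_metrics(
        tp = sum(pred & truth), fp = sum(pred & !truth),
        tn = sum(!pred & !truth), fn = sum(!pred & truth)))
      recs[[i]] <- data.frame(run = run, fold = fold,
                              precision = met$precision,
                              recall = met$recall, f_score = met$f_score,
                              mcc = met$mcc,
                              auc = compute_auc(p, truth))
    }
  }
  out <- do.call(rbind, recs)
  class(out) <- c("cv_metrics", "data.frame")
  out
}

as_binary_factor <- function(y) {
  if (is.logical(y)) {
    return(factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos")))
  }
  if (is.factor(y)) y <- as.character(y)
  vals <- sort(unique(y))
  if (length(vals) != 2L) stop("labels must take exactly 2 values")
  factor(ifelse(y == vals[2L], "pos", "neg"), levels = c("neg", "pos"))
}

# Stratified train/test index split; guarantees both classes present on
# both sides (classes have >= 2 members by the caller's check).
stratified_split <- function(y, train_frac) {
  train <- unlist(lapply(levels(y), function(lv) {
    members <- which(y == lv)
    n_train <- min(max(1L, round(train_frac * length(members))),
                   length(members) - 1L)
    sample(members, n_train)
  }))
  list(train = train, test = setdiff(seq_along(y), train))
}

# Grid search by AUC on an inner stratified split, then refit on the full
# training portion with the winning parameters.
fit_with_grid <- function(x, y, spec) {
  pts <- grid_points(spec)
  if (length(pts) > 1L) {
    inner <- stratified_split(y, 0.75)
    aucs <- vapply(pts, function(params) {
      m <- fit_classifier(x[inner$train, , drop = FALSE], y[inner$train],
                          spec, params)
      tryCatch(
        compute_auc(predict_prob(m, x[inner$test, , drop = FALSE]),
                    y[inner$test] == "pos"),
        error = function(e) NA_real_)
    }, 0)
    pts <- pts[which.max(aucs)]
  }
  fit_classifier(x, y, spec, pts[[1L]])
}

#' Paired Wilcoxon signed-rank comparison of per-fold scores
#'
#' Two-sided paired signed-rank test on the fold-wise differences. Zero
#' differences are dropped (classic procedure); if all differences are
#' zero, `p = 1` is returned with a warning. The p-value is exact for up to
#' 25 non-zero differences without ties in their absolute values, and uses
#' the normal approximation with continuity correction otherwise.
#'
#' @param aucs_a,aucs_b Paired per-fold score vectors of equal length
#'   (at least 5).
#' @return Two-sided p-value.
#' @export
wilcoxon_compare <- function(aucs_a, aucs_b) {
  stopifnot(length(aucs_a) == length(aucs_b), length(aucs_a) >= 5L)
  d <- aucs_a - aucs_b
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
}

#' Per-property forest importance and single-property AUC
#'
#' Scores each feature block individually: the random-forest Gini
#' importance of a block is the sum of the per-bit impurity decreases,
#' normalized so the block importances sum to 1, and the block AUC is a
#' [bootstrap_cv()] run on that block's columns alone.
#'
#' @param features A `tf_features` matrix.
#' @param y Binary labels (see [bootstrap_cv()]).
#' @param spec A [classifier_spec()]; importances require a forest family,
#'   otherwise they are `NA` and only AUCs are computed.
#' @param n_runs,n_folds,seed Passed to [bootstrap_cv()].
#' @return Data.frame with `property`, `importance`, `mean_auc`, ordered by
#'   decreasing `mean_auc`.
#' @export
property_importance <- function(features, y, spec = classifier_spec("RF"),
                                n_runs = 10L, n_folds = 5L, seed = 1L) {
  blocks <- attr(features, "blocks")
  if (is.null(blocks)) stop("features has no blocks attribute")
  yf <- as_binary_factor(y)
  importance <- rep(NA_real_, length(blocks))
  if (spec$family == "RF") {
    set.seed(seed)
    forest <- randomForest::randomForest(as.matrix(features), yf,
                                         ntree = spec$ntree,
                                         importance = FALSE)
    gini <- forest$importance[, "MeanDecreaseGini"]
    importance <- vapply(blocks, function(idx) sum(gini[idx]), 0)
    importance <- importance / sum(importance)
  } else {
    message("importance unavailable for family ", spec$family,
            "; computing AUC only")
  }
  mean_auc <- vapply(names(blocks), function(prop) {
    cv <- bootstrap_cv(select_blocks(features, prop), yf, spec,
                       n_runs = n_runs, n_folds = n_folds, seed = seed)
    mean(cv$auc)
  }, 0)
  out <- data.frame(property = names(blocks),
                    importance = unname(importance),
                    mean_auc = unname(mean_auc),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_auc), ]
}

#' Forward best-first feature-set search
#'
#' Greedy search over property blocks: start from the block with the best
#' mean cross-validated AUC, then at each step add the remaining block that
#' maximizes the mean AUC of the enlarged set. Every step is recorded even
#' when the AUC decreases; each step's fold AUCs are compared to the
#' previous step's by a paired Wilcoxon signed-rank test. The selected
#' subset is the prefix of the trace with maximal mean AUC.
#'
#' @param features A `tf_features` matrix.
#' @param y Binary labels (see [bootstrap_cv()]).
#' @param properties Candidate property names; default all blocks of
#'   `features`.
#' @param spec A [classifier_spec()].
#' @param n_runs,n_folds,seed Cross-validation plan per candidate set.
#' @return A `feature_search` object: the trace data.frame (`step`,
#'   `property`, `mean_auc`, `p_vs_prev`) with the selected subset in
#'   `attr(, "selected")` and per-step fold AUCs in `attr(, "fold_aucs")`.
#' @export
forward_best_first <- function(features, y, properties = NULL,
                               spec = classifier_spec("RF"),
                               n_runs = 10L, n_folds = 5L, seed = 1L) {
  blocks <- attr(features, "blocks")
  if (is.null(properties)) properties <- names(blocks)
  stopifnot(length(properties) >= 1L,
            all(properties %in% names(blocks)))
  yf <- as_binary_factor(y)
  chosen <- character()
  trace <- list()
  fold_aucs <- list()
  prev_aucs <- NULL
  for (step in seq_along(properties)) {
    remaining <- setdiff(properties, chosen)
    cand_cv <- lapply(remaining, function(prop) {
      bootstrap_cv(select_blocks(features, c(chosen, prop)), yf, spec,
                   n_runs = n_runs, n_folds = n_folds, seed = seed)
    })
    means <- vapply(cand_cv, function(cv) mean(cv$auc), 0)
    best <- which.max(means)
    chosen <- c(chosen, remaining[best])
    aucs <- cand_cv[[best]]$auc
    p_prev <- if (is.null(prev_aucs)) NA_real_ else
      suppressWarnings(wilcoxon_compare(aucs, prev_aucs))
    trace[[step]] <- data.frame(step = step, property = remaining[best],
                                mean_auc = means[best],
                                p_vs_prev = p_prev,
                                stringsAsFactors = FALSE)
    fold_aucs[[step]] <- aucs
    prev_aucs <- aucs
  }
  out <- do.call(rbind, trace)
  best_prefix <- which.max(out$mean_auc)
  structure(out,
            selected = out$property[seq_len(best_prefix)],
            fold_aucs = fold_aucs,
            class = c("feature_search", "data.frame"))
}

#' @export
print.feature_search <- function(x, ...) {
  cat("forward best-first search (", nrow(x), " steps); selected: ",
      paste(attr(x, "selected"), collapse = " + "), "\n", sep = "")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
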