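#' Balanced specific-vs-rest tasks by random majority-side splitting
#'
#' For one regulatory-function case (e.g. Pioneers vs Rest) the larger of
#' the two sides {specific class, union of the other classes} is randomly
#' partitioned, without replacement, into
#' `k = max(1, round(larger / smaller))` near-equal subsets (the remainder
#' spread one-per-subset), and each subset is paired with the entire smaller
#' side. With the training class sizes 45/47/77/288 this yields 9, 9, 5 and
#' 2 balanced tasks for the P, S, M+ and M- cases respectively; for the M-
#' case the specific class itself is the larger side and is the one split.
#'
#' @param labels Named character vector (tf_id -> label in `P`, `S`, `M+`,
#'   `M-`) or a `tf_records` table whose labeled rows are used.
#' @param case_name The specific class: `"P"`, `"S"`, `"M+"` or `"M-"`.
#' @param seed Integer seed controlling the random partition.
#' @return A `balanced_tasks` list; each element has `case_name`,
#'   `positives`, `negatives`, `split_index` and `seed`.
#' @export
make_balanced_tasks <- function(labels, case_name, seed) {
  if (inherits(labels, "tf_records")) labels <- labeled_classes(labels)
  stopifnot(is.character(labels), !is.null(names(labels)),
            case_name %in% TF_CLASSES)
  labels <- labels[labels %in% TF_CLASSES]
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  specific <- names(labels)[labels == case_name]
  rest <- names(labels)[labels != case_name]
  if (!length(specific)) stop("empty class: ", case_name)
  split_specific <- length(specific) > length(rest)
  larger <- if (split_specific) specific else rest
  smaller <- if (split_specific) rest else specific
  k <- max(1L, round(length(larger) / length(smaller)))
  set.seed(seed)
  shuffled <- sample(larger)
  sizes <- rep(length(larger) %/% k, k)
  extra <- length(larger) %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  tasks <- lapply(seq_len(k), function(i) {
    subset_i <- shuffled[(ends[i] - sizes[i] + 1L):ends[i]]
    structure(
      list(case_name = case_name,
           positives = if (split_specific) subset_i else specific,
           negatives = if (split_specific) rest else subset_i,
           split_index = i, seed = seed),
      class = "balanced_task")
  })
  structure(tasks, class = "balanced_tasks")
}

#' @export
print.balanced_tasks <- function(x, ...) {
  sz <- vapply(x, function(t) length(t$positives) + length(t$negatives), 0L)
  cat("balanced_tasks [", x[[1L]]$case_name, " vs Rest]: ", length(x),
      " splits, sizes ", paste(sz, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Classifier specification
#'
#' Names a base classifier family and its hyperparameters or search grid.
#' The default is the random forest used for the final classification
#' (Gini split criterion, 500 trees). Support vector classifiers and kNN
#' carry the canonical grids (`C` and `gamma` in `2^-4 .. 2^4`, polynomial
#' degree in `{2, 3}`, `k` in `{3, 5, 7, 9}`) that [bootstrap_cv()] searches
#' by AUC on the training portion of each fold.
#'
#' @param family One of `"RF"`, `"SVC-RBF"`, `"SVC-poly"`, `"SVC-linear"`,
#'   `"kNN"`, `"GNB"`.
#' @param ntree Trees per forest (RF only).
#' @param grid Optional named list of candidate parameter values overriding
#'   the family default (`cost`, `gamma`, `degree`, `k`).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(family = c("RF", "SVC-RBF", "SVC-poly",
                                       "SVC-linear", "kNN", "GNB"),
                            ntree = 500L, grid = NULL) {
  family <- match.arg(family)
  default_grid <- switch(family,
    "SVC-RBF" = list(cost = 2^(-4:4), gamma = 2^(-4:4)),
    "SVC-poly" = list(cost = 2^(-4:4), degree = c(2, 3)),
    "SVC-linear" = list(cost = 2^(-4:4)),
    "kNN" = list(k = c(3, 5, 7, 9)),
    list()
  )
  if (!is.null(grid)) {
    unknown <- setdiff(names(grid), names(default_grid))
    if (length(unknown)) {
      stop("grid parameter(s) not valid for ", family, ": ",
           paste(unknown, collapse = ", "))
    }
    if (any(!lengths(grid))) stop("empty candidate set in grid")
    default_grid[names(grid)] <- grid
  }
  structure(list(family = family, ntree = as.integer(ntree),
                 grid = default_grid),
            class = "classifier_spec")
}

# Cartesian product of the grid as a list of parameter sets; list(list())
# when there is nothing to search.
grid_points <- function(spec) {
  if (!length(spec$grid)) return(list(list()))
  g <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

# Fit one binary classifier; y is a factor with levels c("neg", "pos").
fit_classifier <- function(x, y, spec, params = list()) {
  x <- as.matrix(x)
  model <- switch(spec$family,
    RF = randomForest::randomForest(x, y, ntree = spec$ntree),
    "SVC-RBF" = e1071::svm(x, y, kernel = "radial",
                           cost = params$cost %||% 1,
                           gamma = params$gamma %||% (1 / ncol(x)),
                           probability = TRUE, scale = FALSE),
    "SVC-poly" = e1071::svm(x, y, kernel = "polynomial",
                            cost = params$cost %||% 1,
                            degree = params$degree %||% 3,
                            coef0 = 0, probability = TRUE, scale = FALSE),
    "SVC-linear" = e1071::svm(x, y, kernel = "linear",
                              cost = params$cost %||% 1,
                              probability = TRUE, scale = FALSE),
    kNN = list(train = x, cl = y, k = params$k %||% 5),
    GNB = e1071::naiveBayes(
      as.data.frame(lapply(as.data.frame(x), factor, levels = 0:1)), y)
  )
  structure(list(family = spec$family, model = model, params = params,
                 features = colnames(x)),
            class = "tf_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Positive-class probability for new data.
predict_prob <- function(fit, x) {
  x <- as.matrix(x)[, fit$features, drop = FALSE]
  switch(fit$family,
    RF = stats::predict(fit$model, x, type = "prob")[, "pos"],
    GNB = stats::predict(
      fit$model,
      as.data.frame(lapply(as.data.frame(x), factor, levels = 0:1)),
      type = "raw")[, "pos"],
    kNN = {
      pred <- class::knn(fit$model$train, x, fit$model$cl,
                         k = fit$model$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "pos", p, 1 - p)
    },
    {
      pr <- stats::predict(fit$model, x, probability = TRUE)
      attr(pr, "probabilities")[, "pos"]
    }
  )
}

#' Train the per-split classifiers of one specific-vs-rest case
#'
#' Fits one classifier per balanced task. Refitting with the same seed and
#' inputs reproduces identical predictions.
#'
#' @param tasks A `balanced_tasks` list from [make_balanced_tasks()].
#' @param features A `tf_features` matrix covering every task TF.
#' @param spec A [classifier_spec()]; default random forest. Fixed
#'   hyperparameters are taken from the first grid point when a grid is
#'   present.
#' @param seed Integer seed for the stochastic fit.
#' @return A `case_ensemble`: fitted models plus the case name, feature
#'   names and seed.
#' @export
train_case_ensemble <- function(tasks, features,
                                spec = classifier_spec("RF"), seed = 1L) {
  stopifnot(inherits(tasks, "balanced_tasks"))
  ids <- unique(unlist(lapply(tasks, function(t) c(t$positives,
                                                   t$negatives))))
  missing <- setdiff(ids, rownames(features))
  if (length(missing)) {
    stop("task TF(s) absent from feature matrix: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  params <- grid_points(spec)[[1L]]
  models <- lapply(tasks, function(task) {
    if (!length(task$positives) || !length(task$negatives)) {
      stop("degenerate task (single class) in split ", task$split_index)
    }
    x <- features[c(task$positives, task$negatives), , drop = FALSE]
    y <- factor(rep(c("pos", "neg"),
                    c(length(task$positives), length(task$negatives))),
                levels = c("neg", "pos"))
    set.seed(seed + task$split_index)
    fit_classifier(x, y, spec, params)
  })
  structure(list(case_name = tasks[[1L]]$case_name, models = models,
                 feature_names = colnames(features), spec = spec,
                 seed = seed),
            class = "case_ensemble")
}

#' @export
print.case_ensemble <- function(x, ...) {
  cat("case_ensemble [", x$case_name, " vs Rest]: ", length(x$models),
      " ", x$spec$family, " models over ", length(x$feature_names),
      " features\n", sep = "")
  invisible(x)
}

#' Train the full four-case one-vs-rest ensemble
#'
#' Convenience wrapper: builds balanced tasks and a case ensemble for each
#' regulatory-function class. Splits are drawn independently per case from
#' the master seed. Each case may use its own feature-block subset (the
#' selected lists from the forward search), given as `blocks_per_case`.
#'
#' @param labels Named label vector or labeled `tf_records`.
#' @param features A `tf_features` matrix.
#' @param spec A [classifier_spec()].
#' @param seed Master integer seed.
#' @param blocks_per_case Optional named list (case -> character vector of
#'   property names) restricting the features used per case.
#' @return A `tf_ensemble`: named list of four `case_ensemble` objects.
#' @export
train_tf_ensemble <- function(labels, features,
                              spec = classifier_spec("RF"), seed = 1L,
                              blocks_per_case = NULL) {
  ensembles <- lapply(seq_along(TF_CLASSES), function(i) {
    case <- TF_CLASSES[i]
    feats <- if (!is.null(blocks_per_case) && !is.null(blocks_per_case[[case]]))
      select_blocks(features, blocks_per_case[[case]]) else features
    tasks <- make_balanced_tasks(labels, case, seed = seed + i)
    train_case_ensemble(tasks, feats, spec, seed = seed + 100L * i)
  })
  structure(stats::setNames(ensembles, TF_CLASSES), class = "tf_ensemble")
}

#' @export
print.tf_ensemble <- function(x, ...) {
  cat("tf_ensemble:",
      paste(vapply(x, function(e) paste0(e$case_name, "(",
                                         length(e$models), ")"), ""),
            collapse = " "), "\n")
  invisible(x)
}

#' Average per-case probability for new TFs
#'
#' @param object A `case_ensemble`.
#' @param features A `tf_features` matrix of TFs to score.
#' @param ... Unused.
#' @return Numeric vector: the mean positive-class probability over the
#'   case's split models, named by `tf_id`.
#' @export
predict.case_ensemble <- function(object, features, ...) {
  probs <- vapply(object$models, function(m) predict_prob(m, features),
                  numeric(nrow(features)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(features))
  stats::setNames(rowMeans(probs), rownames(features))
}

#' Final four-way classification with averaged probabilities and margins
#'
#' Each TF is scored by every case's split models; per case the positive
#' probabilities are averaged, the final label is the case with the highest
#' average probability (ties broken in the fixed order P, S, M+, M- with a
#' warning) and the margin is the difference between the two largest
#' average probabilities.
#'
#' @param object A `tf_ensemble`.
#' @param features A `tf_features` matrix of TFs to classify.
#' @param ... Unused.
#' @return An `ensemble_prediction` data.frame: `tf_id`, one average
#'   probability column per class, `final_label`, `margin`.
#' @export
predict.tf_ensemble <- function(object, features, ...) {
  if (!all(TF_CLASSES %in% names(object))) {
    stop("missing case bundle(s): ",
         paste(setdiff(TF_CLASSES, names(object)), collapse = ", "))
  }
  avg <- vapply(TF_CLASSES, function(case) {
    feats <- features[, object[[case]]$feature_names, drop = FALSE]
    predict.case_ensemble(object[[case]], feats)
  }, numeric(nrow(features)))
  if (is.null(dim(avg))) avg <- matrix(avg, nrow = nrow(features),
                                       dimnames = list(NULL, TF_CLASSES))
  top <- apply(avg, 1L, which.max)   # which.max = first max: P,S,M+,M- order
  tie <- apply(avg, 1L, function(p) sum(p == max(p)) > 1L)
  if (any(tie)) {
    warning(sum(tie), " tie(s) at argmax resolved in order P, S, M+, M-")
  }
  margin <- apply(avg, 1L, function(p) {
    s <- sort(p, decreasing = TRUE)
    s[1L] - s[2L]
  })
  out <- data.frame(tf_id = rownames(features), avg,
                    final_label = TF_CLASSES[top], margin = margin,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ensemble_prediction", "data.frame")
  out
}

#' Summarize predictions by TFClass group
#'
#' Reproduces the layout of a per-structural-class results table: for each
#' TFClass group (class-level code when resolvable under `registry`,
#' otherwise the superclass) the per-label counts, the mean winning average
#' probability and the mean margin.
#'
#' @param predictions An `ensemble_prediction` data.frame.
#' @param codes Named character vector of TFClass codes (tf_id -> code).
#' @param registry Registry used to resolve the grouping code; default
#'   [tfclass_registry()].
#' @return A data.frame with one row per TFClass group.
#' @export
summarize_by_class <- function(predictions, codes,
                               registry = tfclass_registry()) {
  stopifnot(nrow(predictions) > 0L)
  code <- codes[predictions$tf_id]
  group <- vapply(code, function(cd) {
    parts <- parse_tfclass_code(cd)
    prefixes <- vapply(seq_along(parts),
                       function(k) paste(parts[seq_len(k)], collapse = "."),
                       "")
    hit <- prefixes[prefixes %in% registry$classes]
    if (length(hit)) hit[length(hit)] else paste0(parts[1L], ".0")
  }, "")
  win <- apply(as.matrix(predictions[, TF_CLASSES]), 1L, max)
  out <- do.call(rbind, lapply(split(seq_along(group), group), function(i) {
    counts <- table(factor(predictions$final_label[i], levels = TF_CLASSES))
    data.frame(tfclass = group[i[1L]], n = length(i),
               n_P = counts[["P"]], n_S = counts[["S"]],
               n_Mplus = counts[["M+"]], n_Mminus = counts[["M-"]],
               mean_prob = mean(win[i]),
               mean_margin = mean(predictions$margin[i]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$tfclass), ]
  rownames(out) <- NULL
  out
}
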