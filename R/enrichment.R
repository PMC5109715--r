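#' Two-sided Fisher exact test on a 2 x 2 table
#'
#' The p-value sums the hypergeometric probabilities of all tables with the
#' same margins that are as or more extreme than the observed one (the
#' classic two-sided `fisher.test` convention). The direction compares the
#' observed in-category/with-feature cell `a` to its expectation under
#' independence, `rowtotal x coltotal / total`.
#'
#' @param a,b,c,d Non-negative integer cells: `a` = in-category with
#'   feature, `b` = in-category without, `c` = out-of-category with,
#'   `d` = out-of-category without.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `p_value`, `direction` (`"enriched"`/`"depleted"`),
#'   `expected` (expectation of `a`), `observed` and `odds_ratio`.
#' @export
#' @examples
#' fisher_2x2(278, 56, 257, 584)  # strongly enriched
fisher_2x2 <- function(a, b, c, d,
                       alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("negative cell count")
  if (sum(cells) == 0) stop("empty table")
  m <- matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE)
  ft <- stats::fisher.test(m, alternative = alternative)
  expected <- (a + b) * (a + c) / sum(cells)
  list(p_value = ft$p.value,
       direction = if (a > expected) "enriched" else "depleted",
       expected = expected, observed = a,
       odds_ratio = unname(ft$estimate))
}

new_enrichment_result <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("enrichment_result", "data.frame")
  df
}

#' @export
print.enrichment_result <- function(x, ...) {
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-class enrichment of a binary TF property
#'
#' For each regulatory-function class, tests whether TFs of that class
#' carry the feature more (or less) often than expected from the overall
#' feature frequency: observed = TFs in the class with the feature,
#' expected = class total x feature total / N, p from the induced 2 x 2
#' Fisher test.
#'
#' @param class_assignments Named character vector (tf_id -> class).
#' @param feature_flags Named logical vector over the same TFs.
#' @param adjust Add Benjamini-Hochberg adjusted p-values across the
#'   classes (default `TRUE`).
#' @param alternative Passed to [fisher_2x2()].
#' @param log_base Base of the observed/expected log-ratio (default 2).
#' @return An `enrichment_result` data.frame: `label`, `n_class`,
#'   `observed`, `expected`, `p_value`, `direction`, `log_ratio`,
#'   `p_adjusted`.
#' @export
property_enrichment <- function(class_assignments, feature_flags,
                                adjust = TRUE, alternative = "two.sided",
                                log_base = 2) {
  ids <- names(class_assignments)
  stopifnot(!is.null(ids), !is.null(names(feature_flags)))
  missing <- setdiff(ids, names(feature_flags))
  if (length(missing)) {
    stop("TF(s) without a feature flag: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  flags <- feature_flags[ids]
  n_total <- length(ids)
  n_feature <- sum(flags)
  rows <- lapply(unique(class_assignments), function(cls) {
    in_cls <- class_assignments == cls
    if (!sum(in_cls)) {
      warning("empty class ", cls, " skipped")
      return(NULL)
    }
    a <- sum(in_cls & flags)
    ft <- fisher_2x2(a, sum(in_cls) - a, n_feature - a,
                     n_total - sum(in_cls) - n_feature + a,
                     alternative = alternative)
    data.frame(label = cls, n_class = sum(in_cls), observed = a,
               expected = ft$expected, p_value = ft$p_value,
               direction = ft$direction,
               log_ratio = safe_log_ratio(a, ft$expected, log_base),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjusted <- benjamini_adjust(out$p_value)
  new_enrichment_result(out)
}

safe_log_ratio <- function(observed, expected, base = 2) {
  if (expected <= 0) return(NA_real_)
  if (observed == 0) {
    warning("observed = 0; log-ratio is -Inf")
    return(-Inf)
  }
  log(observed / expected, base = base)
}

#' Enrichment of TF-TF interactions for a pair of regulatory classes
#'
#' The pair universe is every unordered pair of classified TFs; each pair
#' either is or is not a (class_a, class_b) combination, and either does or
#' does not appear in the interaction set. The induced 2 x 2 table is
#' tested with the Fisher exact test.
#'
#' @param pairs An `interaction_pairs` object.
#' @param class_assignments Named character vector (tf_id -> class) defining
#'   the universe of classified TFs.
#' @param class_a,class_b The class combination to test (may be equal).
#' @param alternative Passed to [fisher_2x2()].
#' @param log_base Base of the log-ratio.
#' @return One-row `enrichment_result` data.frame.
#' @export
pair_class_enrichment <- function(pairs, class_assignments, class_a,
                                  class_b, alternative = "two.sided",
                                  log_base = 2) {
  ids <- names(class_assignments)
  n <- length(ids)
  n_a <- sum(class_assignments == class_a)
  n_b <- sum(class_assignments == class_b)
  if (n_a < 1L || n_b < 1L) {
    stop("class with no members: ",
         if (n_a < 1L) class_a else class_b)
  }
  total_pairs <- n * (n - 1) / 2
  combo_pairs <- if (class_a == class_b) n_a * (n_a - 1) / 2 else n_a * n_b
  # interactions restricted to the classified universe
  p <- pairs$pairs
  keep <- p$a %in% ids & p$b %in% ids
  cls_a <- class_assignments[p$a[keep]]
  cls_b <- class_assignments[p$b[keep]]
  n_int <- sum(keep)
  is_combo <- (cls_a == class_a & cls_b == class_b) |
    (cls_a == class_b & cls_b == class_a)
  a_cell <- sum(is_combo)
  ft <- fisher_2x2(a_cell, combo_pairs - a_cell, n_int - a_cell,
                   total_pairs - combo_pairs - n_int + a_cell,
                   alternative = alternative)
  new_enrichment_result(data.frame(
    label = paste(class_a, class_b, sep = ":"),
    n_class = combo_pairs, observed = a_cell, expected = ft$expected,
    p_value = ft$p_value, direction = ft$direction,
    log_ratio = suppressWarnings(
      safe_log_ratio(a_cell, ft$expected, log_base)),
    stringsAsFactors = FALSE))
}

#' Per-TF partner-class log-ratio
#'
#' For one TF, the log-ratio of the observed number of interaction
#' partners in a class to the expected number, where the expectation is the
#' TF's total partner count times the class's share of the other
#' classified TFs.
#'
#' @param tf TF identifier (must be classified).
#' @param pairs An `interaction_pairs` object.
#' @param class_assignments Named character vector (tf_id -> class).
#' @param partner_class The partner class of interest.
#' @param base Logarithm base (default 2).
#' @return The log-ratio; `-Inf` with a warning when no partner falls in
#'   the class.
#' @export
partner_log_ratio <- function(tf, pairs, class_assignments, partner_class,
                              base = 2) {
  ids <- names(class_assignments)
  if (!tf %in% ids) stop("TF ", tf, " is not classified")
  n_class <- sum(class_assignments[setdiff(ids, tf)] == partner_class)
  if (!n_class) stop("partner class ", partner_class, " is empty")
  p <- pairs$pairs
  partners <- c(p$b[p$a == tf], p$a[p$b == tf])
  partners <- partners[partners %in% ids]
  if (!length(partners)) stop("TF ", tf, " has no classified partners")
  observed <- sum(class_assignments[partners] == partner_class)
  expected <- length(partners) * n_class / (length(ids) - 1)
  safe_log_ratio(observed, expected, base)
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate adjustment; monotone and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (empty input gives an empty vector).
#' @export
benjamini_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric())
  # fisher.test tail sums can exceed 1 by floating-point error
  if (any(p_values < 0 | p_values > 1 + 1e-8, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pmin(p_values, 1), method = "BH")
}

#' Property enrichment in time-course regulated TF sets
#'
#' Tests every binary property for enrichment or depletion in the up- and
#' down-regulated TF sets (pooled over time points), within each
#' regulatory-function class and over all classified TFs (`"All"`), against
#' the full annotated background. P-values are Benjamini-Hochberg adjusted
#' over the whole analysis (one correction family; set
#' `adjust_scope = "per_block"` to correct within each class-direction
#' block instead). Rows are kept only when the occurrence rule holds:
#' observed count at least `min_obs` for enrichments, expected count at
#' least `min_obs` for depletions.
#'
#' @param sets A `timecourse_sets` object, or a list with character vectors
#'   `up` and `down` (already pooled).
#' @param class_assignments Named character vector (tf_id -> class) over
#'   the background TFs.
#' @param property_flags Logical matrix (background TFs x properties), e.g.
#'   from [annotation_property_flags()].
#' @param min_obs Occurrence filter threshold (default 9).
#' @param alternative Passed to [fisher_2x2()].
#' @param adjust_scope `"global"` (default) or `"per_block"` scope of the
#'   Benjamini-Hochberg family.
#' @return An `enrichment_result` data.frame with columns `class`,
#'   `direction`, `term`, `observed`, `expected`, `p_value`, `p_adjusted`,
#'   `enrichment` and `log_ratio`.
#' @export
timecourse_enrichment <- function(sets, class_assignments, property_flags,
                                  min_obs = 9L,
                                  alternative = "two.sided",
                                  adjust_scope = c("global", "per_block")) {
  adjust_scope <- match.arg(adjust_scope)
  if (inherits(sets, "timecourse_sets")) {
    sets <- list(up = unique(unlist(sets$up)),
                 down = unique(unlist(sets$down)))
  }
  stopifnot(all(c("up", "down") %in% names(sets)))
  bg_ids <- rownames(property_flags)
  stopifnot(!is.null(bg_ids), !is.null(names(class_assignments)))
  absent <- setdiff(unlist(sets), bg_ids)
  if (length(absent)) {
    stop("set member(s) absent from background: ",
         paste(utils::head(absent, 3L), collapse = ", "))
  }
  classes <- c(sort(unique(class_assignments)), "All")
  blocks <- list()
  for (dirn in c("up", "down")) {
    for (cls in classes) {
      cls_ids <- if (cls == "All") {
        intersect(bg_ids, names(class_assignments))
      } else {
        names(class_assignments)[class_assignments == cls]
      }
      cls_ids <- intersect(cls_ids, bg_ids)
      set_ids <- intersect(sets[[dirn]], cls_ids)
      if (!length(set_ids) || !length(cls_ids)) next
      in_set <- cls_ids %in% set_ids
      rows <- lapply(colnames(property_flags), function(term) {
        has <- property_flags[cls_ids, term]
        a <- sum(in_set & has)
        ft <- fisher_2x2(a, sum(in_set) - a, sum(has) - a,
                         sum(!in_set & !has), alternative = alternative)
        data.frame(class = cls, direction = dirn, term = term,
                   observed = a, expected = ft$expected,
                   p_value = ft$p_value, enrichment = ft$direction,
                   log_ratio = suppressWarnings(
                     safe_log_ratio(a, ft$expected)),
                   stringsAsFactors = FALSE)
      })
      block <- do.call(rbind, rows)
      if (adjust_scope == "per_block") {
        block$p_adjusted <- benjamini_adjust(block$p_value)
      }
      blocks[[paste(dirn, cls)]] <- block
    }
  }
  out <- do.call(rbind, blocks)
  if (!is.null(out)) {
    if (adjust_scope == "global") {
      out$p_adjusted <- benjamini_adjust(out$p_value)
    }
    keep <- ifelse(out$enrichment == "enriched",
                   out$observed >= min_obs,
                   out$expected >= min_obs)
    out <- out[keep, , drop = FALSE]
  }
  if (is.null(out)) {
    out <- data.frame(class = character(), direction = character(),
                      term = character(), observed = integer(),
                      expected = numeric(), p_value = numeric(),
                      enrichment = character(), log_ratio = numeric(),
                      p_adjusted = numeric(), stringsAsFactors = FALSE)
  }
  new_enrichment_result(out)
}
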