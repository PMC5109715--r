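#' @keywords internal
"_PACKAGE"

# Canonical orderings used throughout the package.
PTM_TYPES <- c("Phosphorylation", "Acetylation", "Methylation",
               "Ubiquitination", "Sumoylation", "O-GlcNAc")
TF_CLASSES <- c("P", "S", "M+", "M-")
UNLABELED <- "unlabeled"

ptm_columns <- function() paste0("ptm_", tolower(gsub("-", "", PTM_TYPES)))

#' Construct a table of transcription-factor annotation records
#'
#' One row per TF, holding the raw annotation from which binary feature
#' vectors are built: the TFClass code, Pfam domain counts, DNA-binding and
#' protein-protein-interaction status and counts, six post-translational
#' modification flags (phosphorylation, acetylation, methylation,
#' ubiquitination, sumoylation, O-GlcNAc), the phosphorylation-site count,
#' the count of the frequent zinc-finger domains (zf-C2H2 + zf-H2C2_2), and
#' an optional regulatory-function label (`"P"`, `"S"`, `"M+"`, `"M-"`, or
#' `"unlabeled"`).
#'
#' @param tf_id Character vector of unique TF identifiers (opaque strings).
#' @param tfclass_code Dotted TFClass codes.
#' @param pfam_counts List of named non-negative integer vectors
#'   (domain name -> count); `NULL`/empty entries mean no annotated domains.
#' @param has_dbd,has_ppi Logical flags.
#' @param n_dbd,n_ppi,n_phospho_sites,n_zf_frequent Non-negative integer
#'   counts.
#' @param ptm_flags Logical matrix (or data.frame) with six columns in the
#'   order phosphorylation, acetylation, methylation, ubiquitination,
#'   sumoylation, O-GlcNAc.
#' @param label Regulatory-function labels; default all `"unlabeled"`.
#' @return A `tf_records` data.frame.
#' @export
tf_records <- function(tf_id, tfclass_code, pfam_counts = NULL,
                       has_dbd = FALSE, n_dbd = 0L,
                       has_ppi = FALSE, n_ppi = 0L,
                       ptm_flags = NULL, n_phospho_sites = 0L,
                       n_zf_frequent = 0L, label = UNLABELED) {
  n <- length(tf_id)
  if (is.null(pfam_counts)) pfam_counts <- rep(list(integer()), n)
  if (is.null(ptm_flags)) {
    ptm_flags <- matrix(FALSE, n, 6L)
  }
  ptm_flags <- as.matrix(ptm_flags)
  stopifnot(ncol(ptm_flags) == 6L)
  df <- data.frame(
    tf_id = as.character(tf_id),
    tfclass_code = as.character(tfclass_code),
    has_dbd = rep_len(as.logical(has_dbd), n),
    n_dbd = rep_len(as.integer(n_dbd), n),
    has_ppi = rep_len(as.logical(has_ppi), n),
    n_ppi = rep_len(as.integer(n_ppi), n),
    n_phospho_sites = rep_len(as.integer(n_phospho_sites), n),
    n_zf_frequent = rep_len(as.integer(n_zf_frequent), n),
    label = rep_len(as.character(label), n),
    stringsAsFactors = FALSE
  )
  df$pfam_counts <- rep_len(pfam_counts, n)
  colnames(ptm_flags) <- ptm_columns()
  df <- cbind(df, as.data.frame(ptm_flags))
  class(df) <- c("tf_records", "data.frame")
  validate_tf_records(df)
}

#' Validate a `tf_records` table
#'
#' Checks identifier uniqueness, the dotted-code grammar, non-negative
#' counts, flag/count consistency (`has_dbd == FALSE` forces `n_dbd == 0`)
#' and the label alphabet.
#'
#' @param records A `tf_records` data.frame.
#' @return The validated records, invisibly unchanged.
#' @export
validate_tf_records <- function(records) {
  stopifnot(is.data.frame(records))
  dup <- duplicated(records$tf_id)
  if (any(dup)) {
    stop("duplicate tf_id: ",
         paste(unique(records$tf_id[dup]), collapse = ", "))
  }
  bad <- !grepl("^[0-9]+(\\.[0-9]+)*$", records$tfclass_code)
  if (any(bad)) {
    stop("malformed TFClass code in row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(records$tfclass_code[bad]), collapse = ", "))
  }
  counts <- c("n_dbd", "n_ppi", "n_phospho_sites", "n_zf_frequent")
  for (col in counts) {
    if (any(records[[col]] < 0L)) stop("negative ", col)
  }
  if (any(!records$has_dbd & records$n_dbd > 0L)) {
    stop("n_dbd > 0 for a record with has_dbd = FALSE")
  }
  bad_pf <- vapply(records$pfam_counts, function(p) {
    length(p) && (is.null(names(p)) || any(p < 0) || anyDuplicated(names(p)))
  }, NA)
  if (any(bad_pf)) {
    stop("pfam_counts must be uniquely named non-negative vectors (row(s) ",
         paste(which(bad_pf), collapse = ", "), ")")
  }
  ok_lab <- records$label %in% c(TF_CLASSES, UNLABELED)
  if (!all(ok_lab)) {
    stop("unknown label(s): ",
         paste(unique(records$label[!ok_lab]), collapse = ", "))
  }
  invisible(records)
}

#' @export
print.tf_records <- function(x, ...) {
  lab <- table(factor(x$label, levels = c(TF_CLASSES, UNLABELED)))
  cat("tf_records:", nrow(x), "TFs (",
      paste(names(lab), lab, sep = "=", collapse = ", "), ")\n")
  NextMethod()
}

# label vector keyed by tf_id, labeled records only
labeled_classes <- function(records) {
  keep <- records$label %in% TF_CLASSES
  stats::setNames(records$label[keep], records$tf_id[keep])
}

#' Binary property flags derived from annotation records
#'
#' Builds the per-TF logical matrix used as background for property and
#' time-course enrichment: one column per Pfam domain (presence), one per PTM
#' type, plus `PPI` and `DBD`.
#'
#' @param records A `tf_records` table.
#' @param domains Domains to include; default all domains observed in
#'   `records`, in decreasing frequency order.
#' @return Logical matrix with `tf_id` rownames.
#' @export
annotation_property_flags <- function(records, domains = NULL) {
  if (is.null(domains)) {
    freq <- sort(table(unlist(lapply(records$pfam_counts, names))),
                 decreasing = TRUE)
    domains <- names(freq)
  }
  dom <- vapply(domains, function(d) {
    vapply(records$pfam_counts, function(p) isTRUE(p[d] > 0), NA)
  }, logical(nrow(records)))
  if (is.null(dim(dom))) dom <- matrix(dom, nrow = nrow(records))
  ptm <- as.matrix(records[, ptm_columns()])
  colnames(ptm) <- PTM_TYPES
  flags <- cbind(dom, ptm, PPI = records$has_ppi, DBD = records$has_dbd)
  rownames(flags) <- records$tf_id
  flags
}
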