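#' Build an encoding configuration from an annotation corpus
#'
#' Fixes everything [encode_tf()] needs: the TFClass registry, the ordered
#' list of frequent Pfam domains (those present in more than `min_pfam_freq`
#' TFs, ordered by decreasing frequency with ties broken alphabetically),
#' and the count averages used by the thermometer encodings of the numbers
#' of DNA-binding domains, protein-protein interactions and phosphorylation
#' sites.
#'
#' With `averages = "fixed"` the shipped reference averages 4 (DBDs),
#' 9 (PPIs) and 14 (phosphorylation sites) are used; with `"empirical"` the
#' arithmetic means over `records` are used instead.
#'
#' @param records A `tf_records` table (the corpus the encoding is fit on).
#' @param min_pfam_freq A domain is "frequent" when more than this many TFs
#'   carry it (default 20).
#' @param averages `"fixed"` (default) or `"empirical"`.
#' @param registry TFClass registry; default [tfclass_registry()].
#' @param zf_high_threshold Zinc-finger thermometer upper threshold
#'   (default 3: more than three frequent zinc fingers sets both bits).
#' @return An `encoding_config` list.
#' @export
build_encoding_config <- function(records, min_pfam_freq = 20,
                                  averages = c("fixed", "empirical"),
                                  registry = tfclass_registry(),
                                  zf_high_threshold = 3L) {
  averages <- match.arg(averages)
  validate_tf_records(records)
  freq <- table(unlist(lapply(records$pfam_counts, names)))
  keep <- freq[freq > min_pfam_freq]
  if (!length(keep)) {
    stop("no Pfam domain occurs in more than ", min_pfam_freq,
         " TFs; lower min_pfam_freq")
  }
  ord <- order(-as.integer(keep), names(keep))
  frequent_pfam <- names(keep)[ord]
  avg <- switch(averages,
    fixed = c(n_dbd = 4, n_ppi = 9, n_phospho = 14),
    empirical = c(n_dbd = mean(records$n_dbd),
                  n_ppi = mean(records$n_ppi),
                  n_phospho = mean(records$n_phospho_sites))
  )
  if (any(avg <= 0)) stop("count averages must be positive; got ",
                          paste(round(avg, 3), collapse = ", "))
  encoding_config(registry = registry, frequent_pfam = frequent_pfam,
                  avg_n_dbd = avg[["n_dbd"]], avg_n_ppi = avg[["n_ppi"]],
                  avg_n_phospho = avg[["n_phospho"]],
                  zf_high_threshold = zf_high_threshold)
}

#' Assemble an encoding configuration directly
#'
#' @param registry A `class_registry`.
#' @param frequent_pfam Ordered, duplicate-free character vector of frequent
#'   Pfam domain names.
#' @param avg_n_dbd,avg_n_ppi,avg_n_phospho Positive thermometer averages.
#' @param zf_high_threshold Integer zinc-finger upper threshold.
#' @return An `encoding_config` list.
#' @export
encoding_config <- function(registry, frequent_pfam,
                            avg_n_dbd = 4, avg_n_ppi = 9,
                            avg_n_phospho = 14, zf_high_threshold = 3L) {
  stopifnot(inherits(registry, "class_registry"),
            length(frequent_pfam) >= 1L,
            !anyDuplicated(frequent_pfam),
            avg_n_dbd > 0, avg_n_ppi > 0, avg_n_phospho > 0)
  structure(
    list(registry = registry,
         frequent_pfam = as.character(frequent_pfam),
         avg_n_dbd = avg_n_dbd, avg_n_ppi = avg_n_ppi,
         avg_n_phospho = avg_n_phospho,
         zf_high_threshold = as.integer(zf_high_threshold)),
    class = "encoding_config")
}

#' @export
print.encoding_config <- function(x, ...) {
  cat("encoding_config:", tfclass_block_length(x$registry),
      "TFClass bits,", length(x$frequent_pfam), "frequent Pfam domains,",
      "averages", x$avg_n_dbd, "/", x$avg_n_ppi, "/", x$avg_n_phospho,
      "(DBD/PPI/PhS)\n")
  invisible(x)
}

# Names and lengths of the ten feature blocks, in canonical order.
PROPERTY_NAMES <- c("TF_Class", "PD", "DBD", "N_DBD", "PPI", "N_PPI",
                    "N_PhS", "PTM", "Ind_PTM", "N_ZFD")

block_lengths <- function(config) {
  c(TF_Class = tfclass_block_length(config$registry),
    PD = length(config$frequent_pfam),
    DBD = 1L, N_DBD = 2L, PPI = 1L, N_PPI = 2L, N_PhS = 2L, PTM = 1L,
    Ind_PTM = 6L, N_ZFD = 2L)
}

#' Thermometer encoding of a count relative to an average
#'
#' Reduced-resolution ordinal encoding of annotation counts: `[1 1]` when
#' the count exceeds the average, `[1 0]` when it is between one and the
#' average (inclusive), `[0 0]` when it is zero.
#'
#' @param n Non-negative count.
#' @param avg Positive average acting as the upper threshold.
#' @return Integer vector of two bits.
#' @export
#' @examples
#' encode_thermometer(20, 14)  # c(1, 1)
#' encode_thermometer(14, 14)  # c(1, 0)
#' encode_thermometer(0, 14)   # c(0, 0)
encode_thermometer <- function(n, avg) {
  stopifnot(length(n) == 1L, length(avg) == 1L, avg > 0)
  if (is.na(n) || n < 0) stop("count must be non-negative, got ", n)
  as.integer(c(n >= 1, n > avg))
}

#' Thermometer encoding of the frequent zinc-finger domain count
#'
#' `[1 1]` for more than `threshold` (default three) zf-C2H2 + zf-H2C2_2
#' domains, `[1 0]` for one to `threshold`, `[0 0]` for none.
#'
#' @param n_zf Non-negative zinc-finger domain count.
#' @param threshold Upper threshold (default 3).
#' @return Integer vector of two bits.
#' @export
encode_zf <- function(n_zf, threshold = 3L) {
  encode_thermometer(n_zf, threshold)
}

#' Encode one TF record as a binary feature vector
#'
#' Concatenates the ten property blocks in the fixed order TF_Class, PD,
#' DBD, N_DBD, PPI, N_PPI, N_PhS, PTM, Ind_PTM, N_ZFD. The result is a pure
#' function of `(record, config)`.
#'
#' @param record One-row `tf_records` table (or a row index into a larger
#'   table via `records[i, ]`).
#' @param config An `encoding_config`.
#' @return Named integer bit vector with a `blocks` attribute mapping block
#'   name to bit indices.
#' @seealso [encode_tf_matrix()] for whole-corpus encoding.
#' @export
encode_tf <- function(record, config) {
  stopifnot(inherits(config, "encoding_config"), nrow(record) == 1L)
  p <- record$pfam_counts[[1L]]
  pd <- as.integer(vapply(config$frequent_pfam,
                          function(d) isTRUE(p[d] > 0), NA))
  ptm_bits <- as.integer(unlist(record[1L, ptm_columns()]))
  bits <- c(
    encode_tfclass(record$tfclass_code, config$registry),
    pd,
    as.integer(record$has_dbd),
    encode_thermometer(record$n_dbd, config$avg_n_dbd),
    as.integer(record$has_ppi),
    encode_thermometer(record$n_ppi, config$avg_n_ppi),
    encode_thermometer(record$n_phospho_sites, config$avg_n_phospho),
    as.integer(any(ptm_bits == 1L)),
    ptm_bits,
    encode_zf(record$n_zf_frequent, config$zf_high_threshold)
  )
  names(bits) <- feature_bit_names(config)
  lens <- block_lengths(config)
  ends <- cumsum(lens)
  attr(bits, "blocks") <- stats::setNames(
    lapply(seq_along(lens), function(i) (ends[i] - lens[i] + 1L):ends[i]),
    names(lens))
  bits
}

feature_bit_names <- function(config) {
  reg <- config$registry
  c(paste0("TF_Class.", c(reg$superclasses, reg$classes)),
    paste0("PD.", config$frequent_pfam),
    "DBD", c("N_DBD.lo", "N_DBD.hi"),
    "PPI", c("N_PPI.lo", "N_PPI.hi"),
    c("N_PhS.lo", "N_PhS.hi"),
    "PTM", paste0("Ind_PTM.", PTM_TYPES),
    c("N_ZFD.lo", "N_ZFD.hi"))
}

#' Encode an annotation corpus as a binary feature matrix
#'
#' @param records A `tf_records` table.
#' @param config An `encoding_config`.
#' @return A `tf_features` object: integer matrix (TFs x bits, `tf_id`
#'   rownames) with a `blocks` attribute mapping each property name to its
#'   column indices.
#' @export
encode_tf_matrix <- function(records, config) {
  validate_tf_records(records)
  rows <- lapply(seq_len(nrow(records)),
                 function(i) encode_tf(records[i, ], config))
  x <- do.call(rbind, rows)
  rownames(x) <- records$tf_id
  structure(x, blocks = attr(rows[[1L]], "blocks"),
            class = c("tf_features", class(x)))
}

#' @export
print.tf_features <- function(x, ...) {
  blocks <- attr(x, "blocks")
  cat("tf_features:", nrow(x), "TFs x", ncol(x), "bits (",
      paste(names(blocks), lengths(blocks), sep = "=", collapse = ", "),
      ")\n")
  invisible(x)
}

#' Restrict a feature matrix to named property blocks
#'
#' @param features A `tf_features` matrix.
#' @param property_names Non-empty subset of the ten property names
#'   (`TF_Class`, `PD`, `DBD`, `N_DBD`, `PPI`, `N_PPI`, `N_PhS`, `PTM`,
#'   `Ind_PTM`, `N_ZFD`). Block order in the output follows the canonical
#'   order, not the order given.
#' @return A `tf_features` matrix containing only the named blocks.
#' @export
select_blocks <- function(features, property_names) {
  blocks <- attr(features, "blocks")
  if (is.null(blocks)) stop("features has no blocks attribute")
  if (!length(property_names)) stop("empty property selection")
  unknown <- setdiff(property_names, names(blocks))
  if (length(unknown)) {
    stop("unknown property name(s): ", paste(unknown, collapse = ", "))
  }
  keep <- names(blocks)[names(blocks) %in% property_names]
  idx <- unlist(blocks[keep], use.names = FALSE)
  out <- features[, idx, drop = FALSE]
  lens <- lengths(blocks[keep])
  ends <- cumsum(lens)
  structure(out,
            blocks = stats::setNames(
              lapply(seq_along(lens),
                     function(i) (ends[i] - lens[i] + 1L):ends[i]),
              keep),
            class = c("tf_features", class(out)[class(out) != "tf_features"]))
}
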