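#' GC content of a binding-site motif
#'
#' Default (`"pooled"`): the C + G counts summed over all positions divided
#' by the total count, which is invariant to per-column depth differences.
#' `"per_column"` averages the per-position C + G frequencies instead.
#'
#' @param motif A `pfm_motif`.
#' @param method `"pooled"` (default) or `"per_column"`.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(motif, method = c("pooled", "per_column")) {
  method <- match.arg(method)
  stopifnot(inherits(motif, "pfm_motif"))
  counts <- motif$counts
  if (sum(counts) == 0) stop("zero total count in PFM")
  cg <- colSums(counts[c("C", "G"), , drop = FALSE])
  tot <- colSums(counts)
  switch(method,
    pooled = sum(cg) / sum(tot),
    per_column = mean(cg / tot))
}

#' Total information content of a motif in bits
#'
#' Per-column Schneider information against a uniform background:
#' `2 + sum_b p_b log2 p_b` with column probabilities `p_b` and
#' `0 log2 0 = 0`, summed over columns. No pseudocounts or small-sample
#' correction are applied. Bounded by `[0, 2L]` for an `L`-column motif and
#' invariant under column permutation and count scaling.
#'
#' @param motif A `pfm_motif`.
#' @return Information content in bits.
#' @export
#' @examples
#' information_content(pfm_motif("x", matrix(c(1, 0, 0, 0), 4)))  # 2 bits
information_content <- function(motif) {
  stopifnot(inherits(motif, "pfm_motif"))
  totals <- colSums(motif$counts)
  if (any(totals == 0)) stop("zero-total column in PFM")
  p <- sweep(motif$counts, 2L, totals, "/")
  plogp <- ifelse(p > 0, p * log2(p), 0)
  sum(2 + colSums(plogp))
}

#' Per-motif GC/IC statistics with binary cutoffs
#'
#' Computes GC fraction and information content for each motif and flags
#' motifs with GC strictly above `gc_cut` (default 40%) and IC strictly
#' above `ic_cut` (default 9.0 bits). The flag columns feed
#' [property_enrichment()] directly.
#'
#' @param motifs A list of `pfm_motif` objects.
#' @param gc_cut,ic_cut Strict cutoffs for the high-GC and high-IC flags.
#' @param gc_method Passed to [gc_content()].
#' @return A `motif_stats` data.frame: `tf_id`, `gc_fraction`, `ic_bits`,
#'   `gc_high`, `ic_high`. Duplicate `tf_id`s keep the first motif, with a
#'   warning.
#' @export
motif_flags <- function(motifs, gc_cut = 0.40, ic_cut = 9.0,
                        gc_method = "pooled") {
  if (inherits(motifs, "pfm_motif")) motifs <- list(motifs)
  stopifnot(length(motifs) >= 1L)
  ids <- vapply(motifs, `[[`, "", "tf_id")
  dup <- duplicated(ids)
  if (any(dup)) {
    warning("duplicate motif tf_id(s) ",
            paste(unique(ids[dup]), collapse = ", "),
            "; keeping the first of each")
    motifs <- motifs[!dup]
    ids <- ids[!dup]
  }
  gc <- vapply(motifs, gc_content, 0, method = gc_method)
  ic <- vapply(motifs, information_content, 0)
  out <- data.frame(tf_id = ids, gc_fraction = gc, ic_bits = ic,
                    gc_high = gc > gc_cut, ic_high = ic > ic_cut,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("motif_stats", "data.frame")
  out
}
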