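#' Read a TF annotation table
#'
#' Parses a tab-separated annotation file into a [tf_records()] table. The
#' file has one header-named column per record field; Pfam domain counts are
#' encoded as `"name:count"` lists separated by `";"` (empty for none), and an
#' empty `label` cell means unlabeled. Row order is preserved.
#'
#' @param path Path to a TSV file written by [write_annotation_table()] or of
#'   the same layout.
#' @return A `tf_records` data.frame.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("tf_id", "tfclass_code", "pfam", "has_dbd", "n_dbd",
                "has_ppi", "n_ppi", ptm_columns(), "n_phospho_sites",
                "n_zf_frequent")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("annotation table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  label <- if ("label" %in% names(df)) df$label else rep("", nrow(df))
  label[is.na(label) | label == ""] <- UNLABELED
  ptm <- vapply(ptm_columns(), function(cl) df[[cl]] == "TRUE",
                logical(nrow(df)))
  if (is.null(dim(ptm))) ptm <- matrix(ptm, nrow = nrow(df))
  tf_records(
    tf_id = df$tf_id,
    tfclass_code = df$tfclass_code,
    pfam_counts = lapply(df$pfam, parse_pfam_field),
    has_dbd = df$has_dbd == "TRUE",
    n_dbd = as.integer(df$n_dbd),
    has_ppi = df$has_ppi == "TRUE",
    n_ppi = as.integer(df$n_ppi),
    ptm_flags = ptm,
    n_phospho_sites = as.integer(df$n_phospho_sites),
    n_zf_frequent = as.integer(df$n_zf_frequent),
    label = label
  )
}

parse_pfam_field <- function(field) {
  if (is.na(field) || field == "") return(integer())
  items <- strsplit(field, ";", fixed = TRUE)[[1L]]
  parts <- regmatches(items, regexec("^(.*):([0-9]+)$", items))
  bad <- lengths(parts) != 3L
  if (any(bad)) stop("malformed pfam entry: ", items[bad][1L])
  stats::setNames(as.integer(vapply(parts, `[`, "", 3L)),
                  vapply(parts, `[`, "", 2L))
}

format_pfam_field <- function(p) {
  if (!length(p)) return("")
  paste(names(p), p, sep = ":", collapse = ";")
}

#' Write a TF annotation table
#'
#' Inverse of [read_annotation_table()]; round-trips a `tf_records` table
#' exactly.
#'
#' @param records A `tf_records` table.
#' @param path Output TSV path.
#' @param include_labels Write the `label` column (set `FALSE` to produce the
#'   blinded table handed to the pipeline while ground truth is kept in a
#'   sidecar, see [write_labels()]).
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(records, path, include_labels = TRUE) {
  validate_tf_records(records)
  out <- as.data.frame(records)[, c("tf_id", "tfclass_code")]
  out$pfam <- vapply(records$pfam_counts, format_pfam_field, "")
  for (col in c("has_dbd", "n_dbd", "has_ppi", "n_ppi")) {
    out[[col]] <- records[[col]]
  }
  for (col in ptm_columns()) out[[col]] <- records[[col]]
  out$n_phospho_sites <- records$n_phospho_sites
  out$n_zf_frequent <- records$n_zf_frequent
  if (include_labels) {
    out$label <- ifelse(records$label == UNLABELED, "", records$label)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write a label sidecar
#'
#' Two-column TSV (`tf_id`, `label`) holding regulatory-function labels,
#' used for training labels and for the generator's ground truth.
#'
#' @param path TSV path.
#' @return `read_labels()`: named character vector (tf_id -> label).
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("tf_id", "label") %in% names(df)))
  stats::setNames(df$label, df$tf_id)
}

#' @param labels Named character vector (tf_id -> label).
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(tf_id = names(labels), label = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read JASPAR-format position frequency matrices
#'
#' Accepts both the bracketed dialect (`A [ 4 19 0 ]`) and the plain
#' whitespace dialect (four unlabelled rows in A, C, G, T order). Rows are
#' mapped to the fixed A, C, G, T order regardless of label order in the
#' file. Each motif must have four equal-length rows and at least one
#' positive count per column.
#'
#' @param path Path to a JASPAR PFM text file (one or more motifs).
#' @return Named list of `pfm_motif` objects (`tf_id` + 4 x L `counts`
#'   matrix with rownames A, C, G, T).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' motif headers found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  motifs <- lapply(seq_along(starts), function(i) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    toks <- strsplit(header, "\\s+")[[1L]]
    tf_id <- if (length(toks) >= 2L) toks[2L] else toks[1L]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4L) {
      stop("motif ", tf_id, ": expected 4 base rows, found ", length(body))
    }
    parsed <- lapply(body, parse_pfm_row)
    bases <- vapply(parsed, `[[`, "", "base")
    if (all(bases == "")) {
      bases <- c("A", "C", "G", "T")   # plain dialect: fixed row order
    } else if (!setequal(bases, c("A", "C", "G", "T"))) {
      stop("motif ", tf_id, ": missing base row(s): ",
           paste(setdiff(c("A", "C", "G", "T"), bases), collapse = ", "))
    }
    lens <- lengths(lapply(parsed, `[[`, "counts"))
    if (length(unique(lens)) != 1L) {
      stop("motif ", tf_id, ": row-length mismatch (",
           paste(lens, collapse = ", "), ")")
    }
    counts <- do.call(rbind, lapply(parsed, `[[`, "counts"))
    rownames(counts) <- bases
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    pfm_motif(tf_id, counts)
  })
  stats::setNames(motifs, vapply(motifs, `[[`, "", "tf_id"))
}

parse_pfm_row <- function(line) {
  base <- ""
  m <- regexec("^([ACGTacgt])\\s*[\\[|]?\\s*(.*)$", line)
  hit <- regmatches(line, m)[[1L]]
  body <- line
  if (length(hit) == 3L) {
    base <- toupper(hit[2L])
    body <- hit[3L]
  }
  body <- gsub("[][]", " ", body)
  toks <- strsplit(trimws(body), "\\s+")[[1L]]
  counts <- suppressWarnings(as.numeric(toks))
  if (!length(counts) || anyNA(counts)) {
    stop("unparseable PFM row: ", line)
  }
  list(base = base, counts = counts)
}

#' Construct a position frequency matrix motif
#'
#' @param tf_id TF identifier the motif belongs to.
#' @param counts Numeric 4 x L matrix of non-negative counts, rows A, C, G,
#'   T. Every column must have a positive total.
#' @return A `pfm_motif` object.
#' @export
pfm_motif <- function(tf_id, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PFM must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1L) stop("PFM must have at least one column")
  if (any(counts < 0)) stop("negative PFM counts")
  if (any(colSums(counts) == 0)) {
    stop("motif ", tf_id, ": all-zero column in PFM")
  }
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(tf_id = as.character(tf_id), counts = counts),
            class = "pfm_motif")
}

#' @export
print.pfm_motif <- function(x, ...) {
  cat("pfm_motif", x$tf_id, "- length", ncol(x$counts), "\n")
  print(x$counts)
  invisible(x)
}

#' Write motifs in JASPAR PFM format
#'
#' @param motifs A `pfm_motif` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(motifs, path) {
  if (inherits(motifs, "pfm_motif")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m$tf_id, " ", m$tf_id), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, " [ ",
                        paste(format(m$counts[b, ], trim = TRUE),
                              collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Construct a TF-TF interaction pair set
#'
#' Pairs are stored unordered (lexicographically sorted within each pair) and
#' de-duplicated; self-pairs are dropped with a warning.
#'
#' @param a,b Character vectors of interacting TF identifiers.
#' @param source_name Name of the evidence source.
#' @return An `interaction_pairs` object with a `pairs` data.frame
#'   (columns `a`, `b`).
#' @export
interaction_pairs <- function(a, b, source_name = "pairs") {
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == length(b))
  self <- a == b
  if (any(self)) {
    warning("dropping ", sum(self), " self-pair(s): ",
            paste(utils::head(unique(a[self]), 3L), collapse = ", "))
    a <- a[!self]; b <- b[!self]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  structure(
    list(source_name = source_name,
         pairs = data.frame(a = lo[!dup], b = hi[!dup],
                            stringsAsFactors = FALSE)),
    class = "interaction_pairs")
}

#' @export
print.interaction_pairs <- function(x, ...) {
  cat("interaction_pairs [", x$source_name, "]: ", nrow(x$pairs),
      " unordered pairs\n", sep = "")
  invisible(x)
}

#' Read or write a TF-TF interaction pair list
#'
#' Two-column tab-separated identifiers, one interacting pair per row.
#' Reading de-duplicates under unordered comparison and drops self-pairs
#' with a warning.
#'
#' @param path TSV path.
#' @param source_name Evidence-source name attached to the set; defaults to
#'   the file name.
#' @param header Whether the file has a header row.
#' @return `read_pairs()`: an `interaction_pairs` object.
#' @export
read_pairs <- function(path, source_name = basename(path), header = TRUE) {
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("pair list must have two columns: ", path)
  interaction_pairs(df[[1L]], df[[2L]], source_name = source_name)
}

#' @param pairs An `interaction_pairs` object.
#' @rdname read_pairs
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct time-course up/down regulated TF sets
#'
#' @param time_points Ordered character vector of time-point labels.
#' @param up,down Named lists (one element per time point) of TF identifier
#'   vectors. A TF may not be both up- and down-regulated at the same time
#'   point.
#' @return A `timecourse_sets` object.
#' @export
timecourse_sets <- function(time_points, up, down) {
  time_points <- as.character(time_points)
  up <- lapply(up, as.character)
  down <- lapply(down, as.character)
  stopifnot(length(up) == length(time_points),
            length(down) == length(time_points))
  names(up) <- names(down) <- time_points
  for (tp in time_points) {
    both <- intersect(up[[tp]], down[[tp]])
    if (length(both)) {
      stop("TF(s) in both up and down at time point ", tp, ": ",
           paste(utils::head(both, 3L), collapse = ", "))
    }
  }
  structure(list(time_points = time_points, up = up, down = down),
            class = "timecourse_sets")
}

#' @export
print.timecourse_sets <- function(x, ...) {
  cat("timecourse_sets:", length(x$time_points), "time points;",
      length(unique(unlist(x$up))), "TFs up,",
      length(unique(unlist(x$down))), "TFs down (pooled)\n")
  invisible(x)
}

#' Read or write time-course regulated TF sets
#'
#' TSV with columns `time_point`, `direction` (`up`/`down`), `tf_id`.
#'
#' @param path TSV path.
#' @return `read_timecourse_sets()`: a `timecourse_sets` object.
#' @export
read_timecourse_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("time_point", "direction", "tf_id") %in% names(df)))
  tps <- unique(df$time_point)
  pick <- function(dirn) {
    lapply(tps, function(tp) {
      df$tf_id[df$time_point == tp & df$direction == dirn]
    })
  }
  timecourse_sets(tps, up = pick("up"), down = pick("down"))
}

#' @param sets A `timecourse_sets` object.
#' @rdname read_timecourse_sets
#' @export
write_timecourse_sets <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets$time_points, function(tp) {
    rbind(
      if (length(sets$up[[tp]]))
        data.frame(time_point = tp, direction = "up",
                   tf_id = sets$up[[tp]]),
      if (length(sets$down[[tp]]))
        data.frame(time_point = tp, direction = "down",
                   tf_id = sets$down[[tp]])
    )
  }))
  if (is.null(rows)) {
    rows <- data.frame(time_point = character(), direction = character(),
                       tf_id = character())
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Columns are written in their existing (stable) order, without quoting or
#' row names, so downstream tools and diffs see a deterministic layout.
#'
#' @param results A data.frame of results (e.g. enrichment tables or
#'   ensemble predictions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
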