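#' TFClass registry of superclass and class codes
#'
#' The TFClass hierarchy assigns every transcription factor a dotted numeric
#' code (superclass.class.family...). The registry fixes which superclass and
#' class codes are encodable and in which bit order. Two variants are bundled:
#'
#' * `"base47"`: 10 superclasses plus 37 class-level codes, giving a 47-bit
#'   encoding in which one superclass bit and (when resolvable) one class bit
#'   are set.
#' * `"split50"` (default): identical except that the very large C2H2
#'   zinc-finger class 2.3 is replaced by its four families 2.3.1-2.3.4,
#'   giving 10 + 36 + 4 = 50 bits with more balanced subset sizes.
#'
#' @param variant `"split50"` or `"base47"`.
#' @return A `class_registry` object.
#' @seealso [class_registry()] for building a custom registry,
#'   [encode_tfclass()] for the encoding itself.
#' @export
#' @examples
#' reg <- tfclass_registry("base47")
#' tfclass_block_length(reg)
tfclass_registry <- function(variant = c("split50", "base47")) {
  variant <- match.arg(variant)
  superclasses <- as.character(0:9)
  base_classes <- c(
    "0.2", "0.3", "0.4",
    "1.1", "1.2", "1.3",
    "2.1", "2.2", "2.3", "2.5", "2.6", "2.7", "2.8", "2.9",
    "3.1", "3.2", "3.3", "3.4", "3.5", "3.6", "3.7",
    "4.1", "4.2",
    "5.1", "5.2", "5.3",
    "6.1", "6.2", "6.3", "6.4", "6.5", "6.7",
    "7.1", "7.2",
    "8.1", "8.2",
    "9.1"
  )
  classes <- switch(variant,
    base47 = base_classes,
    split50 = {
      i <- match("2.3", base_classes)
      append(base_classes[-i], c("2.3.1", "2.3.2", "2.3.3", "2.3.4"),
             after = i - 1L)
    }
  )
  class_registry(superclasses, classes)
}

#' Build a custom TFClass registry
#'
#' @param superclasses Character vector of superclass codes (single dotted-code
#'   components, e.g. `"2"`), in bit order.
#' @param classes Character vector of dotted class (or family) codes, in bit
#'   order. Each code's leading component must appear in `superclasses`.
#' @return A `class_registry`: a list with elements `superclasses` and
#'   `classes`.
#' @export
class_registry <- function(superclasses, classes) {
  superclasses <- as.character(superclasses)
  classes <- as.character(classes)
  ok_sup <- grepl("^[0-9]+$", superclasses)
  if (!all(ok_sup)) {
    stop("invalid superclass code(s): ",
         paste(superclasses[!ok_sup], collapse = ", "))
  }
  ok_cls <- grepl("^[0-9]+(\\.[0-9]+)+$", classes)
  if (!all(ok_cls)) {
    stop("invalid class code(s): ", paste(classes[!ok_cls], collapse = ", "))
  }
  if (anyDuplicated(superclasses)) stop("duplicated superclass codes")
  if (anyDuplicated(classes)) stop("duplicated class codes")
  sup_of <- vapply(strsplit(classes, ".", fixed = TRUE), `[`, "", 1L)
  orphan <- !(sup_of %in% superclasses)
  if (any(orphan)) {
    stop("class code(s) without a registered superclass: ",
         paste(classes[orphan], collapse = ", "))
  }
  structure(list(superclasses = superclasses, classes = classes),
            class = "class_registry")
}

#' @export
print.class_registry <- function(x, ...) {
  cat("TFClass registry:", length(x$superclasses), "superclasses,",
      length(x$classes), "classes;",
      tfclass_block_length(x), "bits\n")
  invisible(x)
}

#' Length of the TF_Class bit block under a registry
#'
#' @param registry A `class_registry`.
#' @return Integer: one bit per superclass plus one per class code.
#' @export
tfclass_block_length <- function(registry) {
  stopifnot(inherits(registry, "class_registry"))
  length(registry$superclasses) + length(registry$classes)
}

# Dotted-code component split, with grammar check.
parse_tfclass_code <- function(code) {
  if (length(code) != 1L || is.na(code) ||
      !grepl("^[0-9]+(\\.[0-9]+)*$", code)) {
    stop("malformed TFClass code: ", deparse(code))
  }
  strsplit(code, ".", fixed = TRUE)[[1L]]
}

#' Encode a TFClass code as a binary vector
#'
#' Sets the bit of the code's superclass and, when the code resolves to a
#' registered class (or family, for registries that split a class into
#' families), the bit of the longest registered prefix. The encoding gives
#' Hamming distance 0 for identical codes, 2 between different classes of the
#' same superclass and 4 across superclasses.
#'
#' Codes that carry no class information (`"2"`, or the `"X.0"` convention for
#' an uncharacterised class) yield a superclass-only vector. A code whose
#' class component is simply unknown to the registry also falls back to the
#' superclass bit, with a warning.
#'
#' @param code Dotted TFClass code, e.g. `"2.3.1"`.
#' @param registry A `class_registry`; default [tfclass_registry()].
#' @return Named integer vector of 0/1 bits, superclass bits first.
#' @export
#' @examples
#' reg <- tfclass_registry()
#' sum(encode_tfclass("2.3.1", reg) != encode_tfclass("2.3.4", reg))  # 2
#' sum(encode_tfclass("2.3.1", reg) != encode_tfclass("3.1", reg))    # 4
encode_tfclass <- function(code, registry = tfclass_registry()) {
  stopifnot(inherits(registry, "class_registry"))
  parts <- parse_tfclass_code(code)
  sup <- parts[1L]
  if (!(sup %in% registry$superclasses)) {
    stop("unknown superclass in TFClass code: ", code)
  }
  bits <- integer(tfclass_block_length(registry))
  names(bits) <- c(registry$superclasses, registry$classes)
  bits[sup] <- 1L
  if (length(parts) >= 2L && parts[2L] != "0") {
    # longest registered dotted prefix of the code
    prefixes <- vapply(seq_along(parts)[-1L], function(k) {
      paste(parts[seq_len(k)], collapse = ".")
    }, "")
    hit <- prefixes[prefixes %in% registry$classes]
    if (length(hit)) {
      bits[hit[length(hit)]] <- 1L
    } else {
      warning("TFClass code ", code,
              " has no registered class; encoding superclass only")
    }
  }
  bits
}
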