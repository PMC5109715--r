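# Class-conditional TFClass composition of the default simulation: the
# experimental training cohort of the human TF corpus (counts per
# class-level code for P / S / M+ / M-; columns sum to 45 / 47 / 77 / 288).
tfclass_training_counts <- function() {
  codes <- c("1.1", "1.2", "1.3", "2.1", "2.2", "2.3.1", "2.3.3", "2.3.4",
             "3.1", "3.2", "3.3", "3.5", "3.6", "3.7", "4.1", "4.2",
             "5.1", "5.3", "6.1", "6.5", "7.1", "7.2", "8.1", "8.2")
  m <- matrix(c(
    # P   S  M+   M-
      2,  9,  3,  11,   # 1.1
      1, 23,  3,   2,   # 1.2
      1,  0,  0,   0,   # 1.3
      1,  1, 45,   0,   # 2.1
      0,  0,  1,   3,   # 2.2
      4,  1,  0,   0,   # 2.3.1
      6,  1,  4,   1,   # 2.3.3
      1,  2,  1,   1,   # 2.3.4
      0,  0,  3, 195,   # 3.1
      0,  1,  1,   3,   # 3.2
      2,  3,  1,  50,   # 3.3
     23,  3,  7,   1,   # 3.5
      0,  0,  1,   0,   # 3.6
      0,  0,  0,   1,   # 3.7
      0,  0,  2,  17,   # 4.1
      2,  0,  0,   0,   # 4.2
      0,  0,  0,   2,   # 5.1
      1,  0,  2,   0,   # 5.3
      0,  1,  2,   0,   # 6.1
      0,  1,  0,   0,   # 6.5
      1,  0,  0,   0,   # 7.1
      0,  1,  0,   0,   # 7.2
      0,  0,  1,   0,   # 8.1
      0,  0,  0,   1    # 8.2
  ), ncol = 4L, byrow = TRUE,
  dimnames = list(codes, TF_CLASSES))
  m
}

# Default marker-domain Bernoulli rates per class. Rows are the 20
# frequent Pfam domains of the default corpus; rates reflect the coupling
# between structural class and domain content (zinc-finger/KRAB-heavy
# Pioneers, bHLH/bZIP Settlers, nuclear-receptor positive Migrants,
# homeodomain/forkhead negative Migrants).
default_pfam_rates <- function() {
  domains <- c("zf-C2H2", "zf-H2C2_2", "zf-C2H2_4", "KRAB", "SCAN", "BTB",
               "Homeobox", "Pou", "Fork_head", "HLH", "PAS", "bZIP_1",
               "bZIP_2", "Hormone_recep", "zf-C4", "Ets", "HMG_box",
               "T-box", "STAT_bind", "P53")
  m <- matrix(c(
    # P     S     M+    M-
    0.55, 0.10, 0.12, 0.06,   # zf-C2H2
    0.45, 0.08, 0.10, 0.03,   # zf-H2C2_2
    0.25, 0.04, 0.05, 0.02,   # zf-C2H2_4
    0.50, 0.04, 0.04, 0.02,   # KRAB
    0.18, 0.03, 0.03, 0.08,   # SCAN
    0.10, 0.04, 0.05, 0.08,   # BTB
    0.02, 0.04, 0.08, 0.75,   # Homeobox
    0.01, 0.02, 0.03, 0.12,   # Pou
    0.04, 0.06, 0.04, 0.20,   # Fork_head
    0.04, 0.65, 0.06, 0.03,   # HLH
    0.02, 0.18, 0.04, 0.07,   # PAS
    0.06, 0.25, 0.06, 0.05,   # bZIP_1
    0.03, 0.15, 0.03, 0.07,   # bZIP_2
    0.02, 0.03, 0.70, 0.02,   # Hormone_recep
    0.03, 0.03, 0.65, 0.02,   # zf-C4
    0.55, 0.06, 0.10, 0.02,   # Ets
    0.03, 0.04, 0.05, 0.12,   # HMG_box
    0.02, 0.12, 0.04, 0.07,   # T-box
    0.02, 0.04, 0.06, 0.08,   # STAT_bind
    0.02, 0.06, 0.03, 0.08    # P53
  ), ncol = 4L, byrow = TRUE,
  dimnames = list(domains, TF_CLASSES))
  m
}

#' Configuration of the synthetic TF-corpus generator
#'
#' The `"paper-like"` preset mirrors the published marginals of the human
#' TF training corpus: class sizes 45 (P) / 47 (S) / 77 (M+) / 288 (M-),
#' the training cohort's class-conditional TFClass composition, DBD-count
#' means per class near 7.05 / 2.87 / 4.80 / 1.23 with overall PPI and
#' phosphorylation-site means near 9 and 14, motif GC targets near
#' 0.60 / 0.58 / 0.52 / 0.24, an interaction-rate matrix with planted
#' enrichment of P:P, P:S and S:S DNA co-binding and depletion of M+:M+,
#' and time-course effect multipliers planting Ets/HLH/Hormone_recep
#' enrichment in the up set and Fork_head/Ubiquitination enrichment in
#' the down set.
#'
#' Any field can be overridden through `...`; `count_family = "poisson"`
#' replaces the default negative binomial count model.
#'
#' @param preset Currently `"paper-like"`.
#' @param seed Default seed the generators fall back to.
#' @param ... Named overrides of config fields (e.g. `n_per_class`,
#'   `pair_rate_matrix`, `unlabeled_fraction`).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(preset = "paper-like", seed = 1L, ...) {
  stopifnot(identical(preset, "paper-like"))
  config <- list(
    n_per_class = c(P = 45L, S = 47L, `M+` = 77L, `M-` = 288L),
    class_tfclass_counts = tfclass_training_counts(),
    class_pfam_rates = default_pfam_rates(),
    count_means = list(
      n_dbd = c(P = 7.05, S = 2.87, `M+` = 4.80, `M-` = 1.23),
      n_ppi = c(P = 6, S = 8, `M+` = 14, `M-` = 8),
      n_phospho = c(P = 12, S = 16, `M+` = 18, `M-` = 13),
      n_zf = c(P = 6, S = 0.6, `M+` = 1.2, `M-` = 0.3)
    ),
    count_size = 2,            # negative binomial dispersion
    count_family = "nbinom",
    ptm_rates = matrix(c(
      # P     S     M+    M-
      0.85, 0.90, 0.90, 0.80,   # phosphorylation-bearing (via n_phospho)
      0.35, 0.40, 0.45, 0.30,   # acetylation
      0.25, 0.30, 0.35, 0.25,   # methylation
      0.30, 0.55, 0.40, 0.30,   # ubiquitination
      0.20, 0.40, 0.25, 0.20,   # sumoylation
      0.05, 0.08, 0.10, 0.05    # O-GlcNAc
    ), ncol = 4L, byrow = TRUE,
    dimnames = list(PTM_TYPES, TF_CLASSES)),
    pair_rate_matrix = {
      m <- matrix(0.02, 4L, 4L, dimnames = list(TF_CLASSES, TF_CLASSES))
      m["P", "P"] <- 0.10
      m["P", "S"] <- m["S", "P"] <- 0.06
      m["S", "S"] <- 0.06
      m["M+", "M+"] <- 0.005
      m
    },
    motif_gc = c(P = 0.60, S = 0.58, `M+` = 0.52, `M-` = 0.24),
    motif_sharpness = c(P = 0.55, S = 0.52, `M+` = 0.35, `M-` = 0.45),
    motif_length = c(min = 8L, max = 14L),
    timecourse_base_rate = c(up = 0.20, down = 0.25),
    timecourse_effects = list(
      up = c(Ets = 3, HLH = 2.5, Hormone_recep = 2),
      down = c(Fork_head = 2.5, Ubiquitination = 2)
    ),
    n_time_points = 3L,
    unlabeled_fraction = 0,
    seed = as.integer(seed)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  config[names(overrides)] <- overrides
  validate_sim_config(structure(config, class = "sim_config"))
}

validate_sim_config <- function(config) {
  problems <- character()
  if (any(config$n_per_class < 1L)) {
    problems <- c(problems, "n_per_class must be >= 1")
  }
  probs <- c(config$class_pfam_rates, config$ptm_rates,
             config$pair_rate_matrix, config$unlabeled_fraction,
             config$timecourse_base_rate)
  if (any(probs < 0 | probs > 1)) {
    problems <- c(problems, "probabilities must lie in [0, 1]")
  }
  if (!isTRUE(all.equal(config$pair_rate_matrix,
                        t(config$pair_rate_matrix)))) {
    problems <- c(problems, "pair_rate_matrix must be symmetric")
  }
  if (any(colSums(config$class_tfclass_counts) <= 0)) {
    problems <- c(problems, "each class needs TFClass weight mass")
  }
  if (!config$count_family %in% c("nbinom", "poisson")) {
    problems <- c(problems, "count_family must be nbinom or poisson")
  }
  if (length(problems)) {
    stop("invalid simulation config:\n  ",
         paste(problems, collapse = "\n  "))
  }
  config
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      paste(names(x$n_per_class), x$n_per_class, sep = "=",
            collapse = " "),
      "| counts:", x$count_family,
      "| unlabeled:", x$unlabeled_fraction, "\n")
  invisible(x)
}

draw_count <- function(n, mean, config) {
  if (config$count_family == "poisson") {
    stats::rpois(n, mean)
  } else {
    stats::rnbinom(n, size = config$count_size, mu = mean)
  }
}

#' Generate a synthetic TF annotation table with planted class structure
#'
#' Draws, for each TF of each regulatory-function class: a TFClass code
#' from the class's categorical distribution (at family resolution for the
#' split C2H2 classes), marker Pfam domains from class-conditional
#' Bernoulli rates, annotation counts from class-conditional negative
#' binomial (or Poisson) models, and PTM flags from class-conditional
#' rates. Derived fields stay consistent: `has_dbd = n_dbd > 0`,
#' `has_ppi = n_ppi > 0`, the phosphorylation flag tracks a positive site
#' count, and `n_zf_frequent` includes the drawn zf-C2H2/zf-H2C2_2 domain
#' copies. A `unlabeled_fraction` of the records is blinded to
#' `"unlabeled"` while the ground truth is returned separately.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; default `config$seed`. The output is a pure
#'   function of `(config, seed)`.
#' @return List with `records` (a `tf_records` table) and `truth` (named
#'   character vector tf_id -> generating class).
#' @export
generate_tf_table <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  classes <- rep(TF_CLASSES, config$n_per_class[TF_CLASSES])
  n <- length(classes)
  tf_id <- sprintf("TF%04d", seq_len(n))
  tfclass_code <- character(n)
  pfam_counts <- vector("list", n)
  n_dbd <- n_ppi <- n_phospho <- n_zf <- integer(n)
  ptm <- matrix(FALSE, n, 6L, dimnames = list(NULL, PTM_TYPES))
  zf_domains <- c("zf-C2H2", "zf-H2C2_2")
  for (i in seq_len(n)) {
    cls <- classes[i]
    w <- config$class_tfclass_counts[, cls]
    tfclass_code[i] <- sample(rownames(config$class_tfclass_counts), 1L,
                              prob = w)
    rates <- config$class_pfam_rates[, cls]
    present <- names(rates)[stats::runif(length(rates)) < rates]
    copies <- stats::setNames(
      1L + stats::rpois(length(present), 0.5), present)
    # zinc-finger domains come in tandem arrays
    for (zd in intersect(present, zf_domains)) {
      copies[zd] <- copies[zd] + stats::rpois(1L, 2)
    }
    pfam_counts[[i]] <- copies
    n_dbd[i] <- draw_count(1L, config$count_means$n_dbd[cls], config)
    n_ppi[i] <- draw_count(1L, config$count_means$n_ppi[cls], config)
    has_phos <- stats::runif(1L) < config$ptm_rates["Phosphorylation", cls]
    n_phospho[i] <- if (has_phos) {
      1L + draw_count(1L, config$count_means$n_phospho[cls] - 1, config)
    } else 0L
    ptm[i, ] <- c(n_phospho[i] > 0L,
                  stats::runif(5L) < config$ptm_rates[-1L, cls])
    n_zf[i] <- draw_count(1L, config$count_means$n_zf[cls], config) +
      sum(copies[intersect(present, zf_domains)])
  }
  truth <- stats::setNames(classes, tf_id)
  label <- classes
  if (config$unlabeled_fraction > 0) {
    blind <- sample(n, round(config$unlabeled_fraction * n))
    label[blind] <- UNLABELED
  }
  records <- tf_records(
    tf_id = tf_id, tfclass_code = tfclass_code,
    pfam_counts = pfam_counts,
    has_dbd = n_dbd > 0L, n_dbd = n_dbd,
    has_ppi = n_ppi > 0L, n_ppi = n_ppi,
    ptm_flags = ptm, n_phospho_sites = n_phospho,
    n_zf_frequent = n_zf, label = label)
  list(records = records, truth = truth)
}

#' Generate synthetic TF-TF interaction pairs
#'
#' Includes each unordered pair of classified TFs independently, with the
#' probability given by the class-pair rate matrix.
#'
#' @param config A [simulation_config()].
#' @param class_assignments Named character vector (tf_id -> class).
#' @param seed Integer seed; default `config$seed`.
#' @return An `interaction_pairs` object.
#' @export
generate_pairs <- function(config, class_assignments,
                           seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  ids <- names(class_assignments)
  n <- length(ids)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  rates <- config$pair_rate_matrix[
    cbind(class_assignments[idx[, 1L]], class_assignments[idx[, 2L]])]
  keep <- stats::runif(nrow(idx)) < rates
  interaction_pairs(ids[idx[keep, 1L]], ids[idx[keep, 2L]],
                    source_name = "synthetic")
}

#' Generate synthetic binding-site motifs with class-conditional GC and IC
#'
#' Each classified TF gets one position frequency matrix. Per column, the
#' base distribution mixes the class's GC-balanced background composition
#' with a dominant base (drawn in proportion to that composition, so the
#' expected GC matches the class target); the mixing weight (`sharpness`)
#' tunes the information content.
#'
#' @param config A [simulation_config()].
#' @param class_assignments Named character vector (tf_id -> class).
#' @param seed Integer seed; default `config$seed`.
#' @param depth Total count per column (default 100).
#' @return Named list of `pfm_motif` objects.
#' @export
generate_motifs <- function(config, class_assignments,
                            seed = config$seed, depth = 100L) {
  validate_sim_config(config)
  set.seed(seed)
  lens <- config$motif_length
  motifs <- lapply(names(class_assignments), function(id) {
    cls <- class_assignments[[id]]
    g <- config$motif_gc[[cls]]
    sharp <- config$motif_sharpness[[cls]]
    comp <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    L <- sample(lens[["min"]]:lens[["max"]], 1L)
    counts <- vapply(seq_len(L), function(j) {
      dominant <- sample(names(comp), 1L, prob = comp)
      p <- (1 - sharp) * comp
      p[dominant] <- p[dominant] + sharp
      cnt <- round(depth * p)
      cnt[cnt < 0] <- 0
      if (sum(cnt) == 0) cnt[dominant] <- depth
      cnt
    }, numeric(4L))
    pfm_motif(id, counts)
  })
  stats::setNames(motifs, names(class_assignments))
}

#' Generate synthetic time-course up/down regulated TF sets
#'
#' Pooled inclusion probabilities start from the base up/down rates and are
#' multiplied by the configured effect multipliers for every planted
#' property the TF carries (capped at 0.95); up and down membership is
#' mutually exclusive. Pooled members are then spread over the configured
#' number of time points (each member present at one or more points).
#'
#' @param config A [simulation_config()].
#' @param records The `tf_records` the properties are read from.
#' @param seed Integer seed; default `config$seed`.
#' @return A `timecourse_sets` object.
#' @export
generate_timecourse <- function(config, records, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  flags <- annotation_property_flags(records)
  rate_for <- function(dirn) {
    base <- config$timecourse_base_rate[[dirn]]
    eff <- config$timecourse_effects[[dirn]]
    r <- rep(base, nrow(records))
    for (term in names(eff)) {
      if (!term %in% colnames(flags)) next
      r <- ifelse(flags[, term], r * eff[[term]], r)
    }
    pmin(r, 0.95)
  }
  p_up <- rate_for("up")
  p_down <- rate_for("down")
  u <- stats::runif(nrow(records))
  in_up <- u < p_up
  in_down <- !in_up & u < pmin(p_up + p_down, 1)
  tps <- paste0("t", seq_len(config$n_time_points))
  spread <- function(members) {
    sets <- stats::setNames(rep(list(character()), length(tps)), tps)
    for (id in members) {
      at <- sample(tps, 1L + stats::rbinom(1L, length(tps) - 1L, 0.4))
      for (tp in at) sets[[tp]] <- c(sets[[tp]], id)
    }
    sets
  }
  timecourse_sets(tps,
                  up = spread(records$tf_id[in_up]),
                  down = spread(records$tf_id[in_down]))
}
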