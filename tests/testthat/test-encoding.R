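test_that("thermometer encoding follows the zero / up-to-average / above-average rule", {
  expect_equal(encode_thermometer(20, 14), c(1L, 1L))
  expect_equal(encode_thermometer(14, 14), c(1L, 0L))  # average inclusive
  expect_equal(encode_thermometer(1, 14), c(1L, 0L))
  expect_equal(encode_thermometer(0, 14), c(0L, 0L))
  expect_error(encode_thermometer(-1, 14), "non-negative")
  # monotone: increasing n never drops a bit
  prev <- c(0L, 0L)
  for (n in 0:30) {
    cur <- encode_thermometer(n, 9)
    expect_true(all(cur - prev >= 0L))
    prev <- cur
  }
})

test_that("zinc-finger count encoding uses the more-than-three rule", {
  expect_equal(encode_zf(5), c(1L, 1L))
  expect_equal(encode_zf(4), c(1L, 1L))
  expect_equal(encode_zf(3), c(1L, 0L))
  expect_equal(encode_zf(1), c(1L, 0L))
  expect_equal(encode_zf(0), c(0L, 0L))
})

test_that("TFClass Hamming distances are 0 / 2 / 4 for identical, within- and across-superclass codes", {
  reg <- tiny_registry()
  codes <- reg$classes
  for (i in seq_along(codes)) {
    for (j in seq_along(codes)) {
      d <- sum(encode_tfclass(codes[i], reg) != encode_tfclass(codes[j], reg))
      sup_i <- sub("\\..*", "", codes[i])
      sup_j <- sub("\\..*", "", codes[j])
      expected <- if (codes[i] == codes[j]) 0L else
        if (sup_i == sup_j) 2L else 4L
      expect_identical(d, expected)
    }
  }
})

test_that("TFClass encoding sets at most two bits and resolves family-level codes", {
  reg <- tfclass_registry("split50")
  # family codes resolve to the family bit
  bits <- encode_tfclass("2.3.1", reg)
  expect_identical(sum(bits), 2L)
  expect_identical(unname(bits[c("2", "2.3.1")]), c(1L, 1L))
  # deeper codes fall back to the longest registered prefix
  deep <- encode_tfclass("3.1.1.5", reg)
  expect_identical(unname(deep[c("3", "3.1")]), c(1L, 1L))
  # superclass-only conventions
  expect_identical(sum(encode_tfclass("0.0", reg)), 1L)
  expect_identical(sum(encode_tfclass("7", reg)), 1L)
  # every registered code encodes with at most 2 ones
  for (code in reg$classes) {
    expect_lte(sum(encode_tfclass(code, reg)), 2L)
  }
  expect_error(encode_tfclass("12.1", reg), "unknown superclass")
  expect_warning(out <- encode_tfclass("2.99", reg), "no registered class")
  expect_identical(sum(out), 1L)
  expect_error(encode_tfclass("2..3", reg), "malformed")
})

test_that("encoding config extracts frequent domains by threshold, order and empirical means", {
  # 6 TFs: domA in 5, domB in 3, domC in 3, domD in 1
  pfam <- list(c(domA = 1L, domB = 2L), c(domA = 1L, domC = 1L),
               c(domA = 2L, domB = 1L, domC = 1L), c(domA = 1L),
               c(domA = 1L, domB = 1L, domC = 1L), c(domD = 4L))
  rec <- make_records(6, codes = rep("1.1", 6), pfam = pfam,
                      n_dbd = c(0L, 1L, 2L, 3L, 4L, 5L),
                      has_dbd = c(FALSE, rep(TRUE, 5)),
                      n_ppi = 0:5, has_ppi = c(FALSE, rep(TRUE, 5)),
                      n_phospho_sites = c(2L, 2L, 2L, 2L, 2L, 14L))
  cfg <- build_encoding_config(rec, min_pfam_freq = 2,
                               averages = "empirical",
                               registry = tiny_registry())
  expect_identical(cfg$frequent_pfam, c("domA", "domB", "domC"))
  expect_equal(cfg$avg_n_dbd, mean(0:5))
  expect_equal(cfg$avg_n_ppi, mean(0:5))
  expect_equal(cfg$avg_n_phospho, mean(c(2, 2, 2, 2, 2, 14)))
  fixed <- build_encoding_config(rec, min_pfam_freq = 2,
                                 averages = "fixed",
                                 registry = tiny_registry())
  expect_equal(c(fixed$avg_n_dbd, fixed$avg_n_ppi, fixed$avg_n_phospho),
               c(4, 9, 14))
  expect_error(build_encoding_config(rec, min_pfam_freq = 10),
               "lower min_pfam_freq")
})

test_that("encode_tf populates blocks per the property table and is deterministic", {
  reg <- tiny_registry()
  cfg <- encoding_config(reg, frequent_pfam = c("domA", "domB"))
  bare <- make_records(1, codes = "2.1")
  v <- encode_tf(bare, cfg)
  blocks <- attr(v, "blocks")
  expect_identical(sum(v[blocks$TF_Class]), 2L)
  for (b in setdiff(names(blocks), "TF_Class")) {
    expect_identical(sum(v[blocks[[b]]]), 0L)
  }
  expect_identical(length(v), sum(lengths(blocks)))
  expect_identical(length(v),
                   tfclass_block_length(reg) + 2L + 1L + 2L + 1L + 2L +
                     2L + 1L + 6L + 2L)
  # phosphorylation only: PTM flag set, first Ind_PTM bit set
  phos <- make_records(1, codes = "2.1",
                       ptm_flags = matrix(c(TRUE, rep(FALSE, 5)), 1),
                       n_phospho_sites = 3L)
  vp <- encode_tf(phos, cfg)
  expect_identical(unname(vp["PTM"]), 1L)
  expect_identical(unname(vp[blocks$Ind_PTM]),
                   c(1L, 0L, 0L, 0L, 0L, 0L))
  # PD bits track frequent-domain presence in order
  dom <- make_records(1, codes = "1.2", pfam = list(c(domB = 2L)))
  expect_identical(unname(encode_tf(dom, cfg)[blocks$PD]), c(0L, 1L))
  # pure function
  expect_identical(encode_tf(phos, cfg), encode_tf(phos, cfg))
})

test_that("select_blocks subsets named property blocks and validates names", {
  cfg <- encoding_config(tiny_registry(), frequent_pfam = c("dA", "dB"))
  feats <- encode_tf_matrix(make_records(5, codes = rep("1.1", 5)), cfg)
  all10 <- select_blocks(feats, c("TF_Class", "PD", "DBD", "N_DBD", "PPI",
                                  "N_PPI", "N_PhS", "PTM", "Ind_PTM",
                                  "N_ZFD"))
  expect_equal(unclass(all10)[, ], unclass(feats)[, ])
  best <- select_blocks(feats, c("TF_Class", "PD", "N_PPI"))
  expect_identical(ncol(best), tfclass_block_length(tiny_registry()) + 2L + 2L)
  expect_identical(names(attr(best, "blocks")), c("TF_Class", "PD", "N_PPI"))
  expect_error(select_blocks(feats, character()), "empty")
  expect_error(select_blocks(feats, "NOT_A_BLOCK"), "unknown property")
})
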