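test_that("Fisher 2x2 matches exhaustive fixed-margin enumeration for small tables", {
  # no association: identical row proportions
  expect_equal(fisher_2x2(4, 6, 2, 3)$p_value, 1)
  expect_error(fisher_2x2(-1, 2, 3, 4), "negative")
  set.seed(7)
  for (i in 1:40) {
    cells <- as.integer(rmultinom(1, sample(4:30, 1), rep(1 / 4, 4)))
    res <- fisher_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(res$p_value,
                 oracle_fisher_two_sided(cells[1], cells[2], cells[3],
                                         cells[4]),
                 tolerance = 1e-10)
    # direction always consistent with observed vs expected
    exp_a <- (cells[1] + cells[2]) * (cells[1] + cells[3]) / sum(cells)
    expect_identical(res$direction,
                     if (cells[1] > exp_a) "enriched" else "depleted")
  }
})

test_that("per-class property enrichment conserves expected counts", {
  set.seed(15)
  classes <- stats::setNames(sample(c("P", "S", "M+", "M-"), 200, TRUE),
                             sprintf("t%03d", 1:200))
  flags <- stats::setNames(runif(200) < 0.3, names(classes))
  res <- property_enrichment(classes, flags)
  expect_equal(sum(res$expected), sum(flags))       # conservation
  expect_equal(sum(res$observed), sum(flags))
  expect_true(all((res$observed > res$expected) ==
                    (res$direction == "enriched")))
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
  # a feature carried by everyone is trivially unenriched
  all_on <- stats::setNames(rep(TRUE, 200), names(classes))
  res1 <- property_enrichment(classes, all_on)
  expect_true(all(res1$p_value == 1))
  expect_equal(res1$observed, res1$n_class)
  expect_equal(res1$expected, as.numeric(res1$n_class))
})

test_that("pair-class enrichment uses the all-pairs universe and detects planted rates", {
  classes <- stats::setNames(rep(c("P", "S"), c(10, 20)),
                             sprintf("p%02d", 1:30))
  # no interactions at all: p = 1
  empty <- interaction_pairs(character(), character())
  res0 <- pair_class_enrichment(empty, classes, "P", "P")
  expect_equal(res0$p_value, 1)
  # combinatorial identities of the universe
  expect_identical(res0$n_class, 10 * 9 / 2)
  expect_equal(pair_class_enrichment(empty, classes, "P", "S")$n_class,
               10 * 20)
  expect_error(pair_class_enrichment(empty, classes, "P", "M+"),
               "no members")
  # planted 10x rate on P:P pairs
  cfg <- simulation_config(seed = 2)
  big <- stats::setNames(rep(c("P", "S", "M+", "M-"), c(45, 47, 77, 288)),
                         sprintf("q%03d", 1:457))
  pairs <- generate_pairs(cfg, big, seed = 12)
  pp <- pair_class_enrichment(pairs, big, "P", "P")
  expect_identical(pp$direction, "enriched")
  expect_lt(pp$p_value, 0.01)
})

test_that("partner log-ratios recover planted partner biases", {
  classes <- stats::setNames(rep(c("P", "S"), each = 100),
                             sprintf("n%03d", 1:200))
  p_ids <- names(classes)[classes == "P"]
  s_ids <- names(classes)[classes == "S"]
  # TF x interacts with 40 P and 20 S partners; P share of others is
  # 99/199, so expected P partners = 60 * 99/199
  x <- "n200"  # an S member, so 100 P and 99 S others
  partners <- c(p_ids[1:40], s_ids[1:20])
  pairs <- interaction_pairs(rep(x, 60), partners)
  obs_lr <- partner_log_ratio(x, pairs, classes, "P")
  expect_equal(obs_lr, log2(40 / (60 * 100 / 199)))
  # observed = expected gives 0; doubling gives 1
  even <- interaction_pairs(rep(x, 4), c(p_ids[1:2], s_ids[1:2]))
  classes_even <- stats::setNames(rep(c("P", "S"), each = 2),
                                  c(p_ids[1:2], s_ids[1:2]))
  classes_even[x] <- "S"
  expect_equal(partner_log_ratio(x, even, classes_even, "P"),
               log2(2 / (4 * 2 / 4)))   # = 0
  expect_error(partner_log_ratio("n050", even, classes, "P"),
               "no classified partners")
  expect_warning(lr0 <- partner_log_ratio(
    x, interaction_pairs(rep(x, 2), s_ids[1:2]), classes, "P"),
    "-Inf")
  expect_identical(lr0, -Inf)
})

test_that("Benjamini-Hochberg adjustment matches the hand formula and is well-behaved", {
  expect_equal(benjamini_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(benjamini_adjust(0.2), 0.2)
  expect_equal(benjamini_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(benjamini_adjust(numeric()), numeric())
  set.seed(19)
  for (i in 1:10) {
    p <- runif(sample(2:12, 1))
    adj <- benjamini_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-12))          # never below the raw p
    expect_true(all(diff(adj[order(p)]) >= -1e-12))   # order-preserving
  }
  expect_error(benjamini_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("time-course enrichment applies the occurrence filter and validates membership", {
  set.seed(33)
  n <- 300
  ids <- sprintf("b%03d", 1:n)
  classes <- stats::setNames(sample(c("P", "S"), n, TRUE), ids)
  flags <- cbind(rare = c(rep(TRUE, 8), rep(FALSE, n - 8)),
                 common = runif(n) < 0.5)
  rownames(flags) <- ids
  # all 8 'rare' carriers in the up set: observed 8 < 9 is filtered even
  # though maximally enriched
  up <- ids[1:20]
  res <- timecourse_enrichment(list(up = up, down = character()),
                               classes, flags)
  expect_false(any(res$term == "rare" & res$enrichment == "enriched"))
  expect_false(any(res$direction == "down"))
  # empty sets give an empty table
  res0 <- timecourse_enrichment(list(up = character(), down = character()),
                                classes, flags)
  expect_identical(nrow(res0), 0L)
  expect_error(
    timecourse_enrichment(list(up = "nope", down = character()),
                          classes, flags),
    "absent from background")
})

test_that("planted time-course effects are detected and the null is calibrated", {
  cfg <- simulation_config(seed = 27)
  sim <- generate_tf_table(cfg)
  tc <- generate_timecourse(cfg, sim$records)
  flags <- annotation_property_flags(sim$records)
  res <- timecourse_enrichment(tc, sim$truth, flags)
  all_up <- res[res$class == "All" & res$direction == "up", ]
  ets <- all_up[all_up$term == "Ets", ]
  expect_identical(ets$enrichment, "enriched")
  expect_lt(ets$p_adjusted, 0.05)
  # per-block correction scope is available and at least as significant
  res_pb <- timecourse_enrichment(tc, sim$truth, flags,
                                  adjust_scope = "per_block")
  ets_pb <- res_pb[res_pb$class == "All" & res_pb$direction == "up" &
                     res_pb$term == "Ets", ]
  expect_lte(ets_pb$p_adjusted, ets$p_adjusted + 1e-12)
})
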