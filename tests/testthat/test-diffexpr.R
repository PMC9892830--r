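test_that("normality branching selects the right test", {
  set.seed(1)
  a <- 2^rnorm(10, 10)
  res <- test_two_groups(a, a)
  expect_equal(res$p_value, 1)

  # constant data in both groups: handled, p = 1
  res0 <- test_two_groups(rep(4, 5), rep(4, 5))
  expect_equal(res0$p_value, 1)

  # an extreme outlier forces a normality failure and the rank test
  b <- c(2^rnorm(11, 10, 0.2), 2^25)
  res1 <- test_two_groups(b, 2^rnorm(12, 10, 0.2))
  expect_equal(res1$test_used, "wilcoxon")

  # clean normal data takes the t branch
  res2 <- test_two_groups(2^rnorm(12, 10, 0.3), 2^rnorm(11, 10.5, 0.3))
  expect_equal(res2$test_used, "t")
})

test_that("type-I error of the branched test is calibrated at the 5% level", {
  set.seed(2024)
  p <- replicate(2000, {
    test_two_groups(2^rnorm(12, 10, 0.5), 2^rnorm(11, 10, 0.5))$p_value
  })
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("rank-sum branch matches a brute-force enumeration oracle at small n", {
  set.seed(3)
  for (i in 1:20) {
    a <- 2^rnorm(sample(4:6, 1), 10, 0.5)
    b <- 2^rnorm(sample(4:6, 1), 10.4, 0.5)
    p_exact <- oracle_wilcoxon(log2(a), log2(b))
    p_approx <- suppressWarnings(
      stats::wilcox.test(log2(a), log2(b), exact = FALSE, correct = FALSE)$p.value)
    # same U statistic, approximate p close to the exact enumeration
    w_pkg <- suppressWarnings(stats::wilcox.test(log2(a), log2(b))$statistic)
    r <- rank(c(log2(a), log2(b)))
    expect_equal(unname(w_pkg), sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2)
    expect_lt(abs(p_approx - p_exact), 0.15)
  }
})

test_that("differential expression calls respect gates, labels and symmetry", {
  st <- simulate_study(simulation_config(seed = 8, n_proteins = 250))
  pp <- preprocess(st$protein, st$annotations)
  de <- differential_expression(pp, st$annotations)
  expect_s3_class(de, "de_result")

  # significance invariant
  gates <- attr(de, "gates")
  ok <- !is.na(de$p_value)
  expect_identical(de$significant[ok],
                   de$p_value[ok] < gates[["alpha"]] &
                     (de$fold_change[ok] >= gates[["fc_up"]] |
                        de$fold_change[ok] <= gates[["fc_down"]]))
  expect_true(all(de$direction[de$significant & de$fold_change >= 1.5] == "up"))

  # swapping group labels inverts FC and leaves p unchanged
  ann_sw <- st$annotations
  ann_sw$group <- c(LNM = "noLNM", noLNM = "LNM")[ann_sw$group]
  de_sw <- differential_expression(pp, ann_sw)
  expect_equal(de_sw$fold_change, 1 / de$fold_change, tolerance = 1e-12)
  expect_equal(de_sw$p_value, de$p_value, tolerance = 1e-9)

  # tightening fc_up can only shrink the up set
  de_tight <- differential_expression(pp, st$annotations, fc_up = 2)
  up_loose <- de$feature_id[de$direction == "up"]
  up_tight <- de_tight$feature_id[de_tight$direction == "up"]
  expect_true(all(up_tight %in% up_loose))

  # removing the gates makes every tested feature significant
  de_all <- differential_expression(pp, st$annotations, fc_up = 1, fc_down = 1,
                                    alpha = 1.0000001)
  expect_true(all(de_all$significant[!is.na(de_all$p_value)]))

  # BH column is monotone in raw p after sorting
  srt <- de[order(de$p_value), ]
  expect_true(all(diff(srt$p_adj[!is.na(srt$p_adj)]) >= -1e-12))

  # unpreprocessed input and empty contrast are refused
  expect_error(differential_expression(st$protein, st$annotations),
               class = "gaclnm_design_error")
  expect_error(differential_expression(pp, st$annotations, tissue = "nonesuch"),
               class = "gaclnm_design_error")
})

test_that("DE detects planted fold changes and stays quiet under the null", {
  # null: discovery fraction at most a few percent (FC gate on top of alpha)
  st0 <- simulate_study(simulation_config(seed = 21, n_proteins = 400,
                                          de_fraction = 0,
                                          kinase_activity_logfc = 0))
  de0 <- differential_expression(preprocess(st0$protein, st0$annotations),
                                 st0$annotations)
  g0 <- glance(de0)
  expect_lte((g0$n_up + g0$n_down) / g0$n_tested, 0.05)

  # planted features: test-level sensitivity and FC recovery, averaged over
  # seeds (per-seed FC medians are compressed toward 1 by MNAR censoring)
  rec <- vapply(1:5, function(s) {
    st1 <- simulate_study(simulation_config(seed = 22 + s, n_proteins = 300,
                                            de_fraction = 0.25))
    de1 <- differential_expression(preprocess(st1$protein, st1$annotations),
                                   st1$annotations)
    planted <- c(st1$truth$de_up, st1$truth$de_down)
    c(mean(de1$p_value[de1$feature_id %in% planted] < 0.05, na.rm = TRUE),
      median(de1$fold_change[de1$feature_id %in% st1$truth$de_up], na.rm = TRUE))
  }, numeric(2))
  expect_gte(mean(rec[1, ]), 0.6)
  expect_gte(mean(rec[2, ]), 1.4)
  expect_lte(mean(rec[2, ]), 1.6)
})

test_that("phosphosite-to-protein adjustment isolates phosphorylation change", {
  # constant parent protein of 1: adjusted equals raw
  sv <- matrix(2^rnorm(8, 5), 2, 4,
               dimnames = list(c("P1_S10", "P2_T3"), paste0("S", 1:4)))
  pv <- matrix(1, 2, 4, dimnames = list(c("P1", "P2"), paste0("S", 1:4)))
  site_qm <- quant_matrix(sv, "phosphosite")
  prot_qm <- quant_matrix(pv, "protein")
  adj <- phospho_adjust(site_qm, prot_qm)
  expect_equal(adj$values, sv)
  expect_true(all(attr(adj, "adjusted")))

  # site identical to its parent: ratio is exactly 1 everywhere
  pv2 <- sv; rownames(pv2) <- c("P1", "P2")
  adj2 <- phospho_adjust(site_qm, quant_matrix(pv2, "protein"))
  expect_true(all(adj2$values == 1))

  # orphan site passes through unadjusted with flag FALSE
  pv3 <- pv[1, , drop = FALSE]
  adj3 <- phospho_adjust(site_qm, quant_matrix(pv3, "protein"))
  expect_false(attr(adj3, "adjusted")[["P2_T3"]])
  expect_equal(adj3$values["P2_T3", ], sv["P2_T3", ])

  # missing parent sample blanks the site there
  pv4 <- pv; pv4[1, 2] <- NA
  adj4 <- phospho_adjust(site_qm, quant_matrix(pv4, "protein"))
  expect_true(is.na(adj4$values["P1_S10", 2]))
})

test_that("kinase shift on sites decomposes additively against protein shift", {
  # site planted at +1 log2 while its parent carries +0.58: the adjusted
  # site fold change is the difference of the two shifts
  set.seed(9)
  n <- 40
  groups <- rep(c("LNM", "noLNM"), c(n, n))
  ids <- paste0("S", seq_len(2 * n))
  prot <- matrix(2^(10 + 0.58 * (groups == "LNM") + rnorm(2 * n, 0, 0.2)),
                 1, 2 * n, dimnames = list("P1", ids))
  site <- prot * 2^matrix((1 - 0.58) * (groups == "LNM") + rnorm(2 * n, 0, 0.2),
                          1, 2 * n)
  rownames(site) <- "P1_S10"
  adj <- phospho_adjust(quant_matrix(site, "phosphosite"),
                        quant_matrix(prot, "protein"))
  adj_fc <- log2(mean(adj$values[1, groups == "LNM"]) /
                 mean(adj$values[1, groups == "noLNM"]))
  expect_equal(adj_fc, 0.42, tolerance = 0.15)
})

test_that("hypergeometric over-representation matches the combinatorial count", {
  sets <- list(ALL = letters[1:20], TOP = letters[1:5], NONE = letters[19:20])
  attr(sets$ALL, "description") <- attr(sets$TOP, "description") <-
    attr(sets$NONE, "description") <- ""
  res <- ora_enrich(hits = letters[1:5], universe = letters[1:20], sets = sets)

  # saturated set: p = 1
  expect_equal(res$p_value[res$set == "ALL"], 1)
  # all five hits inside a five-member set: p = 1 / C(20,5)
  expect_equal(res$p_value[res$set == "TOP"], 1 / choose(20, 5), tolerance = 1e-12)
  # zero overlap: p = 1 under the upper-tail convention, excluded from FDR
  expect_equal(res$p_value[res$set == "NONE"], 1)
  expect_false(res$tested[res$set == "NONE"])
  expect_true(is.na(res$fdr[res$set == "NONE"]))

  expect_error(ora_enrich(c("a", "zz"), letters[1:20], sets),
               class = "gaclnm_value_error")
})
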