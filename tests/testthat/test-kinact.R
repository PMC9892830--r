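# site table with global mean exactly 0 and sd exactly 1: nine +1 values
# (the kinase's substrates), nine -1, one 0 -> n = 19, sd = sqrt(18/18) = 1
hand_ksea_table <- function() {
  ids <- sprintf("P%02d_S%d", 1:19, 1:19)
  tibble::tibble(site_id = ids, log2fc = c(rep(1, 9), rep(-1, 9), 0))
}

hand_ksea_links <- function() {
  ids <- sprintf("P%02d_S%d", 1:9, 1:9)
  tibble::tibble(kinase_id = "KINA", site_id = ids, source = "curated",
                 networkin_score = NA_real_)
}

test_that("KSEA z equals the closed form on a hand-built table", {
  res <- ksea(hand_ksea_table(), hand_ksea_links())
  expect_equal(nrow(res), 1)
  expect_equal(res$m, 9L)
  expect_equal(res$mean_all_log2fc, 0)
  expect_equal(res$sd_all_log2fc, 1)
  expect_equal(res$z, 3.0, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pnorm(-3), tolerance = 1e-12)
  expect_equal(res$p_value, 0.0027, tolerance = 1e-4)
  expect_equal(res$direction, "up")

  # kinase whose substrate mean equals the global mean scores exactly zero
  links0 <- tibble::tibble(kinase_id = "KINB",
                           site_id = sprintf("P%02d_S%d", c(1:3, 11:13, 19), c(1:3, 11:13, 19)),
                           source = "curated", networkin_score = NA_real_)
  res0 <- ksea(hand_ksea_table(), links0)
  expect_equal(res0$z, 0)
  expect_equal(res0$p_value, 1)
})

test_that("KSEA matches an independent single-pass oracle on random tables", {
  set.seed(31)
  for (i in 1:10) {
    n <- 150
    tab <- tibble::tibble(site_id = make_site_id(sprintf("P%03d", 1:n), "S", 1:n),
                          log2fc = rnorm(n))
    links <- tibble::tibble(
      kinase_id = sample(sprintf("K%d", 1:8), 60, replace = TRUE),
      site_id = sample(tab$site_id, 60),
      source = sample(c("curated", "predicted"), 60, replace = TRUE),
      networkin_score = NA_real_)
    links$networkin_score[links$source == "predicted"] <- runif(sum(links$source == "predicted"), 0, 5)
    links <- dplyr::distinct(links, kinase_id, site_id, .keep_all = TRUE)
    res <- ksea(tab, links, min_substrates = 3)
    # oracle: recompute z per kinase from scratch
    fc <- setNames(tab$log2fc, tab$site_id)
    kept <- links[links$source == "curated" | links$networkin_score >= 2.5, ]
    for (k in res$kinase_id) {
      subs <- unique(kept$site_id[kept$kinase_id == k])
      z_oracle <- (mean(fc[subs]) - mean(fc)) * sqrt(length(subs)) / sd(fc)
      expect_equal(res$z[res$kinase_id == k], z_oracle, tolerance = 1e-10)
    }
  }
})

test_that("KSEA symmetry, cutoff monotonicity and degenerate input", {
  tab <- hand_ksea_table()
  links <- hand_ksea_links()
  res <- ksea(tab, links)
  neg <- tab; neg$log2fc <- -neg$log2fc
  res_neg <- ksea(neg, links)
  expect_equal(res_neg$z, -res$z, tolerance = 1e-12)
  expect_equal(res_neg$p_value, res$p_value, tolerance = 1e-12)

  # raising the NetworKIN cutoff never increases any kinase's substrate count
  set.seed(12)
  tab2 <- tibble::tibble(site_id = make_site_id(sprintf("Q%02d", 1:40), "S", 1:40),
                         log2fc = rnorm(40))
  links2 <- tibble::tibble(kinase_id = "KC", site_id = tab2$site_id,
                           source = "predicted", networkin_score = runif(40, 0, 5))
  m_low <- ksea(tab2, links2, networkin_cutoff = 1)$m
  m_high <- ksea(tab2, links2, networkin_cutoff = 3)$m
  expect_lte(m_high, m_low)

  const <- tab; const$log2fc <- 0.5
  expect_error(ksea(const, links), class = "gaclnm_value_error")
})

test_that("ABPP replicate aggregation follows the stated averaging rules", {
  # equal upper quartiles across columns so normalization is the identity:
  # the replicate pair (2, 4) averages to 3
  v <- rbind(SITE_A = c(2, 4, 3, 3),
             HIGH1 = c(50, 50, 50, 50),
             HIGH2 = c(100, 100, 100, 100))
  colnames(v) <- c("X_r1", "X_r2", "Y_r1", "Y_r2")
  qm <- quant_matrix(v, "abpp_site")
  rep_of <- c(X_r1 = "X", X_r2 = "X", Y_r1 = "Y", Y_r2 = "Y")
  agg <- abpp_aggregate(qm, rep_of)
  expect_equal(agg$values["SITE_A", "X"], 3)
  expect_equal(agg$values["SITE_A", "Y"], 3)

  # identical replicates: the mean equals either one (normalize off)
  agg2 <- abpp_aggregate(qm, rep_of, normalize = FALSE)
  expect_equal(agg2$values["HIGH1", "X"], 50)

  # one missing replicate: the present value stands; both missing: missing
  v3 <- v; v3["SITE_A", "X_r1"] <- NA; v3["SITE_A", c("Y_r1", "Y_r2")] <- NA
  agg3 <- abpp_aggregate(quant_matrix(v3, "abpp_site"), rep_of, normalize = FALSE)
  expect_equal(agg3$values["SITE_A", "X"], 4)
  expect_true(is.na(agg3$values["SITE_A", "Y"]))

  # unpaired replicate column is a design error
  expect_error(abpp_aggregate(qm, rep_of[-1]), class = "gaclnm_design_error")
  rep_bad <- rep_of; rep_bad["Y_r2"] <- "Z"
  expect_error(abpp_aggregate(qm, rep_bad), class = "gaclnm_design_error")
})

test_that("group-exclusive ABPP detection fires on two-of-four patterns", {
  set.seed(41)
  v <- 2^matrix(rnorm(4 * 8, 20, 0.3), 4, 8)
  rownames(v) <- paste0("K", 1:4, "_K85")
  colnames(v) <- c(paste0("L", 1:4), paste0("C", 1:4))
  # site 1: present in exactly two LNM samples, absent everywhere else
  v[1, ] <- NA
  v[1, c("L1", "L2")] <- 2^20
  groups <- setNames(rep(c("LNM", "noLNM"), each = 4), colnames(v))
  res <- abpp_differential(quant_matrix(v, "abpp_site"), groups)
  expect_equal(res$exclusive_group[res$site_id == "K1_K85"], "LNM")
  expect_true(is.na(res$p_value[res$site_id == "K1_K85"]))

  # identical group distributions are not significant
  v2 <- v
  v2[2, 1:4] <- v2[2, 5:8]
  res2 <- abpp_differential(quant_matrix(v2, "abpp_site"), groups)
  expect_false(res2$significant[res2$site_id == "K2_K85"])
})

test_that("a planted kinase activity shift is recovered from ABPP in most seeds", {
  hits <- vapply(1:50, function(s) {
    cfg <- simulation_config(seed = 100 + s, n_kinases = 12,
                             n_active_kinases = 1, kinase_activity_logfc = 1)
    ab <- simulate_abpp(cfg)
    agg <- abpp_aggregate(ab$qm, ab$replicate_of)
    res <- abpp_differential(agg, ab$groups)
    active <- names(ab$truth$kinase_shift)[ab$truth$kinase_shift != 0]
    rows <- res[grepl(paste0("^", active, "_"), res$site_id), ]
    any(rows$significant & rows$fold_change >= 1.5, na.rm = TRUE)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("motif matrices read flanks off the sequence correctly", {
  sites <- tibble::tibble(protein_id = "P1", position = 3,
                          site_class = "Lys1_ATP_binding")
  pfm <- motif_matrix(sites, c(P1 = "AAKAA"), flank = 2)
  f <- pfm$Lys1_ATP_binding
  expect_equal(f$freq["A", "-2"], 1)
  expect_equal(f$freq["A", "2"], 1)
  expect_equal(f$counts["K", "0"], 1L)
  expect_equal(unname(colSums(f$counts)), rep(1L, 5))

  # site at the sequence start: left flank columns have no contributors
  sites2 <- tibble::tibble(protein_id = "P2", position = 1,
                           site_class = "Lys1_ATP_binding")
  pfm2 <- motif_matrix(sites2, c(P2 = "KAAAA"), flank = 2)
  expect_equal(unname(colSums(pfm2$Lys1_ATP_binding$counts)), c(0L, 0L, 1L, 1L, 1L))

  # non-lysine position and absent sequence are skipped with warnings
  sites3 <- tibble::tibble(protein_id = c("P1", "ZZ"), position = c(2, 5),
                           site_class = "Lys1_ATP_binding")
  expect_warning(expect_warning(pfm3 <- motif_matrix(sites3, c(P1 = "AAKAA"), flank = 1)))
  expect_equal(pfm3$Lys1_ATP_binding$n_sites, 0L)
  expect_equal(nrow(pfm3$Lys1_ATP_binding$skipped), 2)
})

test_that("the class-specific -2 consensus is recovered from constructed sequences", {
  ab <- simulate_abpp(simulation_config(seed = 55))
  pfm <- motif_matrix(ab$site_class, ab$sequences, flank = 7)
  expect_equal(pfm$Lys1_ATP_binding$consensus[["-2"]], "A")
  expect_equal(pfm$Lys2_active_site$consensus[["-2"]], "D")
  expect_true(all(pfm$Lys1_ATP_binding$freq >= 0 & pfm$Lys1_ATP_binding$freq <= 1))
})
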