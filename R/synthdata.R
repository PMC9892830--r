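#' Simulation configuration
#'
#' Defaults reproduce the study design the pipeline targets: 11 no-LNM and
#' 12 LNM subjects, 5 TMT 10-plex batches each with one pooled
#' internal-standard channel, tumor/para-tumor pairs (one LNM subject
#' tumor-only so that 45 biological samples + 5 IS channels exactly fill
#' the 5 plexes), multiplicative batch effects, intensity-dependent (MNAR)
#' missingness, planted 1.5-fold differentially expressed proteins,
#' phosphosites tethered to their parent proteins, activated kinases
#' shifting their substrate sites, ABPP site tables with technical
#' duplicates, and proportional-hazards survival driven by two marker
#' genes.
#'
#' All "log" parameters are on the log2 scale.
#'
#' @param seed integer RNG seed; the full bundle is deterministic given it.
#' @param n_subjects_nolnm,n_subjects_lnm subjects per group.
#' @param n_batches,plex_size TMT design; one channel per batch is the IS.
#' @param n_proteins number of simulated proteins.
#' @param sites_per_protein_mean Poisson mean of phosphosites per protein.
#' @param baseline_logmean,baseline_logsd protein baseline log2 abundance.
#' @param batch_effect_logsd spread of the per-batch multiplicative effect.
#' @param sample_loading_logsd spread of the per-sample loading factor.
#' @param subject_effect_logsd subject-level random effect shared by a
#'   subject's tumor and para-tumor samples (paired structure).
#' @param residual_logsd measurement noise.
#' @param de_fraction fraction of proteins with a group effect in LNM
#'   tumors (half up at `de_fold_change`, half down at its reciprocal).
#' @param de_fold_change linear fold change of planted up features.
#' @param phospho_extra_logsd site-level noise on top of the parent
#'   protein.
#' @param n_kinases,substrates_per_kinase,n_active_kinases,kinase_activity_logfc
#'   kinase model: active kinases shift their substrate sites by
#'   `kinase_activity_logfc` in LNM tumors.
#' @param missing_mnar_midpoint,missing_mnar_slope logistic missingness on
#'   log2 intensity: P(missing) = plogis(slope * (midpoint - log2 x)).
#' @param mcar_fraction additional intensity-independent missing fraction.
#' @param n_survival,surv_beta1,surv_beta2,marker_cor,censor_rate survival
#'   cohort: exponential times with log hazard `beta1*z1 + beta2*z2` on
#'   standardized marker expression (correlation `marker_cor`), an expected
#'   fraction `censor_rate` censored uniformly on `[0, T]`.
#' @param abpp_n_per_group,abpp_tech_rep_logsd,abpp_bio_logsd,abpp_exclusive_sites
#'   ABPP experiment: biological samples per group (two technical
#'   replicates each), replicate and biological noise, and the number of
#'   group-exclusive sites to plant.
#' @return A `sim_config` list, validated.
#' @export
simulation_config <- function(seed = 1,
                              n_subjects_nolnm = 11, n_subjects_lnm = 12,
                              n_batches = 5, plex_size = 10,
                              n_proteins = 2000, sites_per_protein_mean = 1,
                              baseline_logmean = 20, baseline_logsd = 2,
                              batch_effect_logsd = 0.5,
                              sample_loading_logsd = 0.25,
                              subject_effect_logsd = 0.3,
                              residual_logsd = 0.4,
                              de_fraction = 0.1, de_fold_change = 1.5,
                              phospho_extra_logsd = 0.3,
                              n_kinases = 20, substrates_per_kinase = 10,
                              n_active_kinases = 3, kinase_activity_logfc = 1,
                              missing_mnar_midpoint = 16,
                              missing_mnar_slope = 0.8,
                              mcar_fraction = 0,
                              n_survival = 200, surv_beta1 = 0.7,
                              surv_beta2 = 0.4, marker_cor = 0.5,
                              censor_rate = 0.3,
                              abpp_n_per_group = 4,
                              abpp_tech_rep_logsd = 0.15,
                              abpp_bio_logsd = 0.3,
                              abpp_exclusive_sites = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(plex_size >= 2, n_batches >= 1,
              de_fraction >= 0, de_fraction <= 1,
              mcar_fraction >= 0, mcar_fraction < 1,
              censor_rate >= 0, censor_rate < 1,
              de_fold_change > 0, marker_cor > -1, marker_cor < 1)
  })
  capacity <- cfg$n_batches * (cfg$plex_size - 1)
  if (cfg$n_subjects_nolnm + cfg$n_subjects_lnm > capacity) {
    stop_design("design infeasible: ", cfg$n_subjects_nolnm + cfg$n_subjects_lnm,
                " tumor samples plus IS channels exceed ", cfg$n_batches, " x ",
                cfg$plex_size, "-plex capacity")
  }
  structure(cfg, class = "sim_config")
}

# Sample layout: every subject contributes a tumor sample; para-tumor
# samples are dropped from the last LNM subjects when the plexes cannot
# hold all pairs (mirrors a design with one unpaired subject).
sim_design <- function(cfg) {
  n_no <- cfg$n_subjects_nolnm; n_ln <- cfg$n_subjects_lnm
  capacity <- cfg$n_batches * (cfg$plex_size - 1)
  subjects <- tibble::tibble(
    subject_id = sprintf("SUBJ%02d", seq_len(n_no + n_ln)),
    group = rep(c("noLNM", "LNM"), c(n_no, n_ln)))
  # stages: noLNM split I/II, LNM mostly III with one II
  st_no <- rep(c("I", "II"), c(round(n_no * 5 / 11), n_no - round(n_no * 5 / 11)))
  st_ln <- if (n_ln >= 2) c("II", rep("III", n_ln - 1)) else rep("III", n_ln)
  subjects$stage <- c(st_no, st_ln)
  subjects$n_stage <- ifelse(subjects$group == "noLNM", 0L,
                             1L + (seq_len(nrow(subjects)) %% 3L))
  n_para <- min(n_no + n_ln, capacity - (n_no + n_ln))
  para_subjects <- subjects$subject_id[seq_len(n_para)]
  samples <- dplyr::bind_rows(
    dplyr::mutate(subjects, tissue = "tumor"),
    dplyr::mutate(subjects[subjects$subject_id %in% para_subjects, ],
                  tissue = "para_tumor"))
  samples$sample_id <- paste0(samples$subject_id, "_",
                              ifelse(samples$tissue == "tumor", "T", "P"))
  # randomized assignment of samples to batch x channel slots
  slots <- expand.grid(batch_id = sprintf("B%d", seq_len(cfg$n_batches)),
                       channel = seq_len(cfg$plex_size - 1L),
                       stringsAsFactors = FALSE)
  slots <- slots[sample.int(nrow(slots), nrow(samples)), ]
  samples$batch_id <- slots$batch_id
  samples$channel_id <- sprintf("ch%02d", slots$channel)
  samples$is_internal_standard <- FALSE
  is_rows <- tibble::tibble(
    subject_id = NA_character_, group = NA_character_, stage = NA_character_,
    n_stage = NA_integer_, tissue = NA_character_,
    sample_id = sprintf("IS_B%d", seq_len(cfg$n_batches)),
    batch_id = sprintf("B%d", seq_len(cfg$n_batches)),
    channel_id = sprintf("ch%02d", cfg$plex_size),
    is_internal_standard = TRUE)
  dplyr::bind_rows(samples, is_rows)[, c("sample_id", "subject_id", "tissue",
                                         "group", "stage", "n_stage", "batch_id",
                                         "channel_id", "is_internal_standard")]
}

apply_mnar <- function(log2v, cfg) {
  p_miss <- stats::plogis(cfg$missing_mnar_slope * (cfg$missing_mnar_midpoint - log2v))
  if (cfg$mcar_fraction > 0) p_miss <- p_miss + (1 - p_miss) * cfg$mcar_fraction
  miss <- matrix(stats::runif(length(log2v)) < p_miss, nrow = nrow(log2v))
  out <- 2^log2v
  out[miss] <- NA
  out
}

#' Simulate a complete multi-batch TMT study
#'
#' Generates the full bundle the pipeline consumes, plus the ground truth
#' needed for parameter-recovery tests. Protein log2 intensity follows
#' `mu_f + subject_s + loading_s + batch_b + delta_f * 1[LNM tumor] + eps`;
#' the internal-standard channel of each batch is the linear-scale mean of
#' that batch's member samples (the pooling model), which makes the batch
#' factor exactly removable by ratio-to-IS. Phosphosite log2 intensity is
#' the parent protein's (per sample) plus a site offset, the kinase
#' activity shift for substrate sites of active kinases in LNM tumors, and
#' extra noise. Missingness is intensity-dependent (logistic on log2).
#'
#' @param cfg a [simulation_config()].
#' @return List of class `sim_study`: `protein`, `phospho`
#'   ([quant_matrix()]s with missing values), `annotations`, `ks_links`,
#'   `ppi` (igraph), `gene_sets`, `survival` (tibble), `abpp` (see
#'   [simulate_abpp()]), and `truth` (list of planted parameters).
#' @export
simulate_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ann <- sim_design(cfg)
  bio <- ann[!ann$is_internal_standard, ]
  n_s <- nrow(bio)
  prot_ids <- sprintf("PROT%04d", seq_len(cfg$n_proteins))

  mu <- stats::rnorm(cfg$n_proteins, cfg$baseline_logmean, cfg$baseline_logsd)
  subj_ids <- unique(bio$subject_id)
  subj_eff <- stats::setNames(stats::rnorm(length(subj_ids), 0, cfg$subject_effect_logsd), subj_ids)
  loading <- stats::setNames(stats::rnorm(n_s, 0, cfg$sample_loading_logsd), bio$sample_id)
  batches <- sprintf("B%d", seq_len(cfg$n_batches))
  batch_eff <- stats::setNames(stats::rnorm(length(batches), 0, cfg$batch_effect_logsd), batches)

  n_de <- round(cfg$de_fraction * cfg$n_proteins)
  delta <- stats::setNames(numeric(cfg$n_proteins), prot_ids)
  de_up <- de_down <- character(0)
  if (n_de > 0) {
    de_idx <- sample.int(cfg$n_proteins, n_de)
    n_up <- ceiling(n_de / 2)
    delta[de_idx[seq_len(n_up)]] <- log2(cfg$de_fold_change)
    if (n_de > n_up) delta[de_idx[(n_up + 1):n_de]] <- -log2(cfg$de_fold_change)
    de_up <- prot_ids[de_idx[seq_len(n_up)]]
    de_down <- prot_ids[setdiff(de_idx, de_idx[seq_len(n_up)])]
  }

  is_lnm_tumor <- bio$group %in% "LNM" & bio$tissue == "tumor"
  prot_log2 <- matrix(mu, cfg$n_proteins, n_s) +
    matrix(subj_eff[bio$subject_id] + loading[bio$sample_id] + batch_eff[bio$batch_id],
           cfg$n_proteins, n_s, byrow = TRUE) +
    outer(delta, as.numeric(is_lnm_tumor)) +
    matrix(stats::rnorm(cfg$n_proteins * n_s, 0, cfg$residual_logsd), cfg$n_proteins)
  dimnames(prot_log2) <- list(prot_ids, bio$sample_id)

  # phosphosites tethered to parents
  n_sites_per <- stats::rpois(cfg$n_proteins, cfg$sites_per_protein_mean)
  parent <- rep(prot_ids, n_sites_per)
  n_sites <- length(parent)
  residue <- sample(c("S", "T", "Y"), n_sites, replace = TRUE,
                    prob = c(0.8545, 0.1378, 0.0077))
  position <- sample.int(600, n_sites, replace = TRUE)
  site_ids <- make_site_id(parent, residue, position)
  dup <- duplicated(site_ids)
  parent <- parent[!dup]; site_ids <- site_ids[!dup]; n_sites <- length(site_ids)

  # kinase -> substrate assignment and activity shifts
  kin_ids <- sprintf("KIN%02d", seq_len(cfg$n_kinases))
  kin_shift <- stats::setNames(numeric(cfg$n_kinases), kin_ids)
  if (cfg$n_active_kinases > 0) {
    kin_shift[seq_len(min(cfg$n_active_kinases, cfg$n_kinases))] <- cfg$kinase_activity_logfc
  }
  n_assign <- min(n_sites, cfg$n_kinases * cfg$substrates_per_kinase)
  assigned <- sample.int(n_sites, n_assign)
  kin_of_site <- rep(NA_character_, n_sites)
  kin_of_site[assigned] <- rep(kin_ids, length.out = n_assign)
  site_shift <- ifelse(is.na(kin_of_site), 0, kin_shift[kin_of_site])

  site_offset <- stats::rnorm(n_sites, -1, 0.5)  # sites below parent abundance
  site_log2 <- prot_log2[parent, , drop = FALSE] +
    matrix(site_offset, n_sites, n_s) +
    outer(site_shift, as.numeric(is_lnm_tumor)) +
    matrix(stats::rnorm(n_sites * n_s, 0, cfg$phospho_extra_logsd), n_sites)
  rownames(site_log2) <- site_ids

  # IS channels: linear-scale mean of the batch members
  add_is <- function(log2m) {
    lin <- 2^log2m
    is_cols <- vapply(batches, function(b) {
      rowMeans(lin[, bio$sample_id[bio$batch_id == b], drop = FALSE])
    }, numeric(nrow(lin)))
    colnames(is_cols) <- sprintf("IS_%s", batches)
    log2(cbind(lin, is_cols))
  }
  prot_full <- add_is(prot_log2)
  site_full <- add_is(site_log2)
  colnames(prot_full) <- colnames(site_full) <- c(bio$sample_id, sprintf("IS_%s", batches))
  # annotation IS ids are IS_B<i>
  stopifnot(identical(sprintf("IS_%s", batches), ann$sample_id[ann$is_internal_standard]))

  protein_qm <- quant_matrix(apply_mnar(prot_full, cfg), "protein")
  phospho_qm <- quant_matrix(apply_mnar(site_full, cfg), "phosphosite")

  # kinase-substrate links: curated or NetworKIN-predicted (score U(0,5))
  linked <- which(!is.na(kin_of_site))
  src <- sample(c("curated", "predicted"), length(linked), replace = TRUE, prob = c(0.7, 0.3))
  ks_links <- tibble::tibble(
    kinase_id = kin_of_site[linked],
    site_id = site_ids[linked],
    source = src,
    networkin_score = ifelse(src == "predicted", round(stats::runif(length(linked), 0, 5), 3), NA))

  # PPI graph: background random edges plus a planted clique among up-DE
  n_bg <- min(4000, cfg$n_proteins * 4)
  a <- prot_ids[sample.int(cfg$n_proteins, n_bg, replace = TRUE)]
  b <- prot_ids[sample.int(cfg$n_proteins, n_bg, replace = TRUE)]
  conf <- stats::runif(n_bg, 0.15, 1)
  clique_nodes <- utils::head(de_up, 8)
  if (length(clique_nodes) >= 2) {
    cmb <- utils::combn(clique_nodes, 2)
    a <- c(a, cmb[1, ]); b <- c(b, cmb[2, ])
    conf <- c(conf, rep(0.9, ncol(cmb)))
  }
  keep <- a != b
  ppi <- edges_to_graph(a[keep], b[keep], conf[keep], "unit")

  # gene sets: random background sets plus one enriched in planted up features
  gene_sets <- lapply(seq_len(10), function(i) {
    s <- sample(prot_ids, sample(20:50, 1))
    attr(s, "description") <- "background set"
    s
  })
  names(gene_sets) <- sprintf("SET%02d", seq_len(10))
  if (length(de_up) >= 5) {
    s <- unique(c(utils::head(de_up, 15), sample(prot_ids, 10)))
    attr(s, "description") <- "planted up-regulated module"
    gene_sets$UP_MODULE <- s
  }

  survival <- sim_survival(cfg, marker_ids = utils::head(c(de_up, prot_ids), 2))
  abpp <- simulate_abpp(cfg, kinase_shift = kin_shift)

  structure(list(
    protein = protein_qm, phospho = phospho_qm,
    annotations = validate_annotations(ann),
    ks_links = ks_links, ppi = ppi, gene_sets = gene_sets,
    survival = survival$records, abpp = abpp,
    truth = list(
      protein_log2fc = delta, de_up = de_up, de_down = de_down,
      site_kinase_log2fc = stats::setNames(site_shift, site_ids),
      kinase_of_site = stats::setNames(kin_of_site, site_ids),
      kinase_shift = kin_shift,
      batch_log2 = batch_eff, loading_log2 = loading,
      subject_log2 = subj_eff,
      surv_beta = c(cfg$surv_beta1, cfg$surv_beta2),
      marker_genes = survival$marker_genes,
      abpp = abpp$truth)
  ), class = "sim_study")
}

sim_survival <- function(cfg, marker_ids) {
  n <- cfg$n_survival
  z1 <- stats::rnorm(n)
  z2 <- cfg$marker_cor * z1 + sqrt(1 - cfg$marker_cor^2) * stats::rnorm(n)
  lp <- cfg$surv_beta1 * z1 + cfg$surv_beta2 * z2
  t_event <- stats::rexp(n, rate = exp(lp))
  censored <- stats::runif(n) < cfg$censor_rate
  time <- ifelse(censored, t_event * stats::runif(n), t_event)
  records <- tibble::tibble(
    sample_id = sprintf("SURV%03d", seq_len(n)),
    time = time, event = !censored)
  records[[marker_ids[1]]] <- z1
  records[[marker_ids[2]]] <- z2
  list(records = records, marker_genes = marker_ids)
}

#' Simulate an ABPP desthiobiotin-site experiment
#'
#' Four biological samples per group by default, each measured in two
#' technical replicate runs. Each kinase contributes an ATP-binding-site
#' lysine (Lys1) and/or an active-site lysine (Lys2); sites of activated
#' kinases are shifted up in the LNM group. A configurable number of sites
#' is generated group-exclusively — present in (at least two) LNM samples
#' and absent from all controls — emulating an activity detectable only in
#' the metastatic group. Protein sequences carry the class-specific motif
#' (alanine at -2 of Lys1, aspartate at -2 of Lys2) so motif recovery is
#' testable against construction.
#'
#' @param cfg a [simulation_config()].
#' @param kinase_shift optional named per-kinase log2 activity shift
#'   (defaults to the config's active-kinase pattern).
#' @return List of class `sim_abpp`: `qm` (replicate-level
#'   [quant_matrix()]), `replicate_of` (column to biological sample map),
#'   `groups` (sample to group map), `site_class` (tibble: `site_id`,
#'   `protein_id`, `position`, `site_class`), `sequences`, and `truth`.
#' @export
simulate_abpp <- function(cfg = simulation_config(), kinase_shift = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  kin_ids <- sprintf("KIN%02d", seq_len(cfg$n_kinases))
  if (is.null(kinase_shift)) {
    kinase_shift <- stats::setNames(numeric(cfg$n_kinases), kin_ids)
    if (cfg$n_active_kinases > 0) {
      kinase_shift[seq_len(min(cfg$n_active_kinases, cfg$n_kinases))] <- cfg$kinase_activity_logfc
    }
  }
  n_g <- cfg$abpp_n_per_group
  samples <- c(sprintf("LNM%d", seq_len(n_g)), sprintf("CTRL%d", seq_len(n_g)))
  groups <- stats::setNames(rep(c("LNM", "noLNM"), each = n_g), samples)
  rep_cols <- as.vector(t(outer(samples, c("_r1", "_r2"), paste0)))
  replicate_of <- stats::setNames(rep(samples, each = 2), rep_cols)

  # each kinase contributes Lys1 and/or Lys2 (at least one)
  has1 <- stats::runif(cfg$n_kinases) < 0.8
  has2 <- stats::runif(cfg$n_kinases) < 0.8
  has1[!has1 & !has2] <- TRUE
  mk_sites <- function(kin, cls, pos) {
    tibble::tibble(protein_id = kin, position = pos,
                   site_class = cls,
                   site_id = paste0(kin, "_K", pos))
  }
  pos1 <- sample(30:120, cfg$n_kinases, replace = TRUE)
  pos2 <- pos1 + sample(60:140, cfg$n_kinases, replace = TRUE)
  sites <- dplyr::bind_rows(
    mk_sites(kin_ids[has1], "Lys1_ATP_binding", pos1[has1]),
    mk_sites(kin_ids[has2], "Lys2_active_site", pos2[has2]))
  n_sites <- nrow(sites)

  base <- stats::rnorm(n_sites, cfg$baseline_logmean, 1)
  shift <- kinase_shift[sites$protein_id]
  bio_log2 <- matrix(base, n_sites, length(samples)) +
    outer(unname(shift), as.numeric(groups == "LNM")) +
    matrix(stats::rnorm(n_sites * length(samples), 0, cfg$abpp_bio_logsd), n_sites)
  v <- bio_log2[, rep(seq_along(samples), each = 2), drop = FALSE] +
    matrix(stats::rnorm(n_sites * length(rep_cols), 0, cfg$abpp_tech_rep_logsd), n_sites)
  dimnames(v) <- list(sites$site_id, rep_cols)
  v <- 2^v

  exclusive <- character(0)
  if (cfg$abpp_exclusive_sites > 0) {
    for (i in seq_len(cfg$abpp_exclusive_sites)) {
      ex_id <- paste0("KINX", i, "_K85")
      exclusive <- c(exclusive, ex_id)
      sites <- dplyr::bind_rows(sites, tibble::tibble(
        protein_id = paste0("KINX", i), position = 85L,
        site_class = "Lys2_active_site", site_id = ex_id))
      row <- rep(NA_real_, length(rep_cols))
      present <- samples[groups == "LNM"][1:2]
      keep_cols <- rep_cols[replicate_of[rep_cols] %in% present]
      row[match(keep_cols, rep_cols)] <- 2^stats::rnorm(length(keep_cols), cfg$baseline_logmean, 0.3)
      v <- rbind(v, stats::setNames(row, rep_cols))
      rownames(v)[nrow(v)] <- ex_id
    }
  }

  # sequences with the class motif at -2 (A for Lys1, D for Lys2)
  aa_pool <- strsplit("ACDEFGHILMNPQRSTVWY", "")[[1]]  # no K: keep site lysines unique
  seq_len_max <- max(sites$position) + 20
  seqs <- vapply(unique(sites$protein_id), function(p) {
    s <- sample(aa_pool, seq_len_max, replace = TRUE)
    for (j in which(sites$protein_id == p)) {
      s[sites$position[j]] <- "K"
      s[sites$position[j] - 2] <- if (sites$site_class[j] == "Lys1_ATP_binding") "A" else "D"
    }
    paste(s, collapse = "")
  }, "")

  structure(list(
    qm = quant_matrix(v, "abpp_site"),
    replicate_of = replicate_of, groups = groups,
    site_class = sites[, c("site_id", "protein_id", "position", "site_class")],
    sequences = seqs,
    truth = list(kinase_shift = kinase_shift, exclusive_sites = exclusive)
  ), class = "sim_abpp")
}

#' Write a simulated study bundle to disk
#'
#' Serializes every component in the package's interchange formats
#' (TSV matrices, CSV annotations, TSV edge list and kinase-substrate map,
#' GMT gene sets, FASTA sequences, TSV survival and ground-truth tables).
#'
#' @param study a `sim_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @param force overwrite existing files.
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir, force = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chk <- function(p) {
    if (file.exists(p) && !force) stop_value("output exists (use force = TRUE): ", p)
    p
  }
  write_quant_matrix(study$protein, chk(file.path(dir, "protein.tsv")))
  write_quant_matrix(study$phospho, chk(file.path(dir, "phosphosite.tsv")))
  write_quant_matrix(study$abpp$qm, chk(file.path(dir, "abpp.tsv")))
  utils::write.csv(study$annotations, chk(file.path(dir, "annotations.csv")),
                   row.names = FALSE, na = "")
  utils::write.table(study$ks_links, chk(file.path(dir, "ks_links.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  ed <- igraph::as_data_frame(study$ppi, what = "edges")
  utils::write.table(
    data.frame(protein_a = ed$from, protein_b = ed$to, score = ed$confidence),
    chk(file.path(dir, "ppi_edges.tsv")), sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(study$gene_sets, chk(file.path(dir, "gene_sets.gmt")))
  utils::write.table(study$survival, chk(file.path(dir, "survival.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  seqs <- study$abpp$sequences
  writeLines(paste0(">", names(seqs), "\n", seqs), chk(file.path(dir, "abpp_proteins.fasta")))
  truth <- tibble::tibble(feature_id = names(study$truth$protein_log2fc),
                          true_log2fc = unname(study$truth$protein_log2fc))
  utils::write.table(truth, chk(file.path(dir, "ground_truth.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
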