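#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study design the pipeline targets: a good-prognosis
#' group (GPG, 7 samples), a nongerminomatous malignant group (IPG_PPG, 6
#' samples) and an embryonic-stem-cell reference group (ESC, 5 samples); 723
#' miRNA probes with 2 GPG-up and 19 IPG_PPG-up planted at a 4-fold (2 log2)
#' effect; 2000 mRNA features with 400 / 290 planted signature genes at 1.5
#' log2, of which the targets of planted miRNAs are repressed by 1 log2 in the
#' miRNA-high group and 6 genes sit inside a hemizygous deletion planted on
#' the 4q-analog interval in round(0.6 x 5) = 3 of the 5 IPG_PPG SNP-array
#' samples (LRR shift -0.45, noise sd 0.15, 500 probes per chromosome);
#' survival follows exponential hazards 0.03/yr (GPG, n = 95) versus 0.08/yr
#' (IPG_PPG, n = 59) with independent Uniform(0, 20 yr) censoring.
#'
#' The miRNA matrix covers 6 GPG + 6 IPG_PPG samples, the mRNA matrix all
#' GPG/IPG_PPG/ESC samples, and the SNP arrays the GPG samples plus the first
#' 5 IPG_PPG samples, reproducing the study's per-assay subsets.
#'
#' @param n_mrna_features,n_mirna_features Feature universe sizes.
#' @param n_gpg,n_ipg_ppg,n_esc Group sizes.
#' @param n_mirna_gpg miRNA-assay subset of the GPG group.
#' @param n_snp_ipg_ppg SNP-assay subset of the IPG_PPG group.
#' @param baseline_log2,noise_sd Baseline mean and within-group sd of log2
#'   expression.
#' @param n_up_mirna_gpg,n_up_mirna_ngm,mirna_effect_log2 Planted miRNA
#'   counts per group and their log2 effect.
#' @param n_sig_mrna_gpg,n_sig_mrna_ngm,mrna_effect_log2 Planted signature
#'   mRNA counts per group and their log2 effect.
#' @param targets_per_planted_mirna,target_repression_log2 Predicted targets
#'   recorded per planted miRNA and their repression (log2) in the miRNA-high
#'   group.
#' @param n_deletion_genes Signature genes placed inside the deletion and
#'   forced up in the non-deleted group.
#' @param n_region_mirnas Annotated (non-differential) miRNAs placed inside
#'   the deletion interval.
#' @param n_esc_shared_ngm,n_esc_shared_gpg Planted signature genes whose
#'   elevation the ESC group shares with IPG_PPG / GPG (the stem-like
#'   program that places NGMGCTs nearest the ESCs).
#' @param deletions `data.frame` with columns `chromosome`, `start`, `end`,
#'   `group`, `carrier_fraction`, `copy_number`.
#' @param deletion_lrr_shift LRR shift applied to carriers inside a deletion
#'   (empirical single-copy-loss level on bead arrays, default -0.45).
#' @param lrr_noise_sd,probes_per_chrom,baf_noise_sd SNP-array signal model.
#' @param hazard_gpg,hazard_ngm,n_surv_gpg,n_surv_ngm,max_follow_up Survival
#'   simulation (exponential rates per year; uniform censoring horizon).
#' @param seed Integer RNG seed; identical config + seed gives identical
#'   output.
#' @return Validated list of class `CohortConfig`.
#' @export
cohort_config <- function(n_mrna_features = 2000,
                          n_mirna_features = 723,
                          n_gpg = 7, n_ipg_ppg = 6, n_esc = 5,
                          n_mirna_gpg = 6,
                          n_snp_ipg_ppg = 5,
                          baseline_log2 = 7.0, noise_sd = 0.25,
                          n_up_mirna_gpg = 2, n_up_mirna_ngm = 19,
                          mirna_effect_log2 = 2.0,
                          n_sig_mrna_gpg = 400, n_sig_mrna_ngm = 290,
                          mrna_effect_log2 = 1.5,
                          targets_per_planted_mirna = 10,
                          target_repression_log2 = 1.0,
                          n_deletion_genes = 6,
                          n_region_mirnas = 7,
                          n_esc_shared_ngm = 100, n_esc_shared_gpg = 10,
                          deletions = data.frame(
                            chromosome = "chr4", start = 75084501,
                            end = 131387610, group = "IPG_PPG",
                            carrier_fraction = 0.6, copy_number = 1,
                            stringsAsFactors = FALSE),
                          deletion_lrr_shift = -0.45,
                          lrr_noise_sd = 0.15, probes_per_chrom = 500,
                          baf_noise_sd = 0.02,
                          hazard_gpg = 0.03, hazard_ngm = 0.08,
                          n_surv_gpg = 95, n_surv_ngm = 59,
                          max_follow_up = 20,
                          seed = 42) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_mrna_features > 0, n_mirna_features > 0, n_gpg >= 2,
              n_ipg_ppg >= 2, n_esc >= 1, noise_sd > 0,
              mirna_effect_log2 > 0, mrna_effect_log2 > 0,
              target_repression_log2 > 0, probes_per_chrom > 1,
              lrr_noise_sd > 0, max_follow_up > 0)
    if (any(deletions$carrier_fraction <= 0 | deletions$carrier_fraction > 1))
      stop("carrier_fraction must lie in (0, 1]")
  })
  if (cfg$n_mirna_gpg > cfg$n_gpg || cfg$n_snp_ipg_ppg > cfg$n_ipg_ppg)
    stop("per-assay subsets cannot exceed the group sizes")
  if (cfg$n_up_mirna_gpg + cfg$n_up_mirna_ngm > cfg$n_mirna_features)
    stop("planted miRNA count exceeds the miRNA universe")
  if (cfg$n_sig_mrna_gpg + cfg$n_sig_mrna_ngm > cfg$n_mrna_features)
    stop("planted signature count exceeds the mRNA universe")
  if (cfg$n_up_mirna_ngm * cfg$targets_per_planted_mirna +
      cfg$n_deletion_genes > cfg$n_sig_mrna_gpg)
    stop("GPG-up signature too small for the planted targets and deletion genes")
  if (cfg$n_up_mirna_gpg * cfg$targets_per_planted_mirna > cfg$n_sig_mrna_ngm)
    stop("IPG_PPG-up signature too small for the planted targets")
  class(cfg) <- "CohortConfig"
  cfg
}

# Toy genome used by the generator: 5 chromosomes with real-scale lengths;
# chr4 carries a band map in which the default deletion spans q13.3-q28.3.
toy_chromosomes <- function() {
  c(chr1 = 247e6, chr2 = 243e6, chr3 = 199e6, chr4 = 191154276, chr5 = 181e6)
}

toy_cytobands <- function() {
  chroms <- toy_chromosomes()
  chr4 <- data.frame(
    chromosome = "chr4",
    start = c(1, 25e6, 50e6, 65e6, 76e6, 95e6, 115e6, 125e6, 140e6, 165e6) + c(0, rep(1, 9)),
    end = c(25e6, 50e6, 65e6, 76e6, 95e6, 115e6, 125e6, 140e6, 165e6, chroms[["chr4"]]),
    band = c("p15", "p11", "q13.1", "q13.3", "q21", "q25", "q28.1", "q28.3", "q31", "q35"),
    stringsAsFactors = FALSE)
  other <- do.call(rbind, lapply(setdiff(names(chroms), "chr4"), function(chr) {
    len <- chroms[[chr]]
    cut <- round(len * c(0.25, 0.5, 0.75))
    data.frame(chromosome = chr,
               start = c(1, cut + 1),
               end = c(cut, len),
               band = c("p11", "q11", "q21", "q31"),
               stringsAsFactors = FALSE)
  }))
  rbind(chr4, other)
}

place_features <- function(ids, class, width, chroms, forbidden = NULL) {
  if (length(ids) == 0L)
    return(data.frame(feature_id = character(), symbol = character(),
                      chromosome = character(), start = integer(),
                      end = integer(), strand = character(),
                      feature_class = character(), stringsAsFactors = FALSE))
  chr_pick <- sample(names(chroms), length(ids), replace = TRUE,
                     prob = chroms / sum(chroms))
  start <- integer(length(ids))
  for (i in seq_along(ids)) {
    repeat {
      s <- sample.int(chroms[[chr_pick[i]]] - width, 1L)
      if (is.null(forbidden)) break
      f <- forbidden[forbidden$chromosome == chr_pick[i], , drop = FALSE]
      if (nrow(f) == 0L || all(s > f$end | (s + width - 1) < f$start)) break
      chr_pick[i] <- sample(names(chroms), 1L, prob = chroms / sum(chroms))
    }
    start[i] <- s
  }
  data.frame(feature_id = ids, symbol = ids, chromosome = chr_pick,
             start = start, end = start + width - 1L,
             strand = sample(c("+", "-"), length(ids), replace = TRUE),
             feature_class = class, stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with recorded ground truth
#'
#' Emits every input the pipeline consumes — mRNA and miRNA expression
#' matrices, per-sample SNP-array probe tracks, a survival table, a toy genome
#' annotation with cytobands, a target-prediction map — plus the planted
#' truth (which features, regions and pairs are real), so downstream recovery
#' is testable without any external data. See [cohort_config()] for the
#' statistical structure. Identical config and seed give identical output.
#'
#' @param config A [cohort_config()].
#' @return List with elements `mrna`, `mirna` ([expression_matrix()]s), `snp`
#'   (named list of [snp_array_sample()]), `surv` ([survival_table()]),
#'   `annot` ([genome_annotation()]), `preds` ([target_prediction_map()]),
#'   `groups` ([sample_groups()] over the expression cohort), `truth`, and
#'   the `config` used.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  chroms <- toy_chromosomes()

  gpg <- sprintf("GPG_%d", seq_len(config$n_gpg))
  ngm <- sprintf("NGM_%d", seq_len(config$n_ipg_ppg))
  esc <- sprintf("ESC_%d", seq_len(config$n_esc))
  groups <- sample_groups(c(stats::setNames(rep("GPG", length(gpg)), gpg),
                            stats::setNames(rep("IPG_PPG", length(ngm)), ngm),
                            stats::setNames(rep("ESC", length(esc)), esc)))

  gene_ids <- sprintf("GENE%04d", seq_len(config$n_mrna_features))
  mir_ids <- sprintf("MIR%04d", seq_len(config$n_mirna_features))

  ## ---- planted feature sets ------------------------------------------------
  mir_gpg <- if (config$n_up_mirna_gpg > 0)
    sample(mir_ids, config$n_up_mirna_gpg) else character()
  mir_ngm <- if (config$n_up_mirna_ngm > 0)
    sample(setdiff(mir_ids, mir_gpg), config$n_up_mirna_ngm) else character()

  sig_gpg <- if (config$n_sig_mrna_gpg > 0)
    sample(gene_ids, config$n_sig_mrna_gpg) else character()
  sig_ngm <- if (config$n_sig_mrna_ngm > 0)
    sample(setdiff(gene_ids, sig_gpg), config$n_sig_mrna_ngm) else character()

  tpm <- config$targets_per_planted_mirna
  n_tgt_gpgup <- length(mir_ngm) * tpm   # targets of NGM-up miRNAs, up in GPG
  n_tgt_ngmup <- length(mir_gpg) * tpm   # targets of GPG-up miRNAs, up in NGM
  tgt_gpgup <- sig_gpg[seq_len(n_tgt_gpgup)]
  del_genes <- if (nrow(config$deletions) > 0)
    sig_gpg[n_tgt_gpgup + seq_len(config$n_deletion_genes)] else character()
  plain_gpg <- setdiff(sig_gpg, c(tgt_gpgup, del_genes))
  tgt_ngmup <- sig_ngm[seq_len(n_tgt_ngmup)]
  plain_ngm <- setdiff(sig_ngm, tgt_ngmup)
  esc_shared_ngm <- plain_ngm[seq_len(min(config$n_esc_shared_ngm, length(plain_ngm)))]
  esc_shared_gpg <- plain_gpg[seq_len(min(config$n_esc_shared_gpg, length(plain_gpg)))]

  pairs <- data.frame(mirna = character(), target = character(),
                      mirna_up_group = character(), stringsAsFactors = FALSE)
  if (length(mir_ngm))
    pairs <- rbind(pairs, data.frame(
      mirna = rep(mir_ngm, each = tpm), target = tgt_gpgup,
      mirna_up_group = "IPG_PPG", stringsAsFactors = FALSE))
  if (length(mir_gpg))
    pairs <- rbind(pairs, data.frame(
      mirna = rep(mir_gpg, each = tpm), target = tgt_ngmup,
      mirna_up_group = "GPG", stringsAsFactors = FALSE))

  ## ---- expression matrices -------------------------------------------------
  mrna_samples <- c(gpg, ngm, esc)
  m <- matrix(stats::rnorm(config$n_mrna_features * length(mrna_samples),
                           config$baseline_log2, config$noise_sd),
              nrow = config$n_mrna_features,
              dimnames = list(gene_ids, mrna_samples))
  eff <- config$mrna_effect_log2
  rep_eff <- config$target_repression_log2
  m[tgt_gpgup, ngm] <- m[tgt_gpgup, ngm] - rep_eff          # repressed where miRNA is high
  m[del_genes, ngm] <- m[del_genes, ngm] - eff              # dosage loss in the deleted group
  m[plain_gpg, gpg] <- m[plain_gpg, gpg] + eff
  m[esc_shared_gpg, esc] <- m[esc_shared_gpg, esc] + eff    # stemness genes shared GPG/ESC
  m[tgt_ngmup, gpg] <- m[tgt_ngmup, gpg] - rep_eff
  m[plain_ngm, ngm] <- m[plain_ngm, ngm] + eff
  m[esc_shared_ngm, esc] <- m[esc_shared_ngm, esc] + eff    # ESC-like program shared with NGM
  mrna <- expression_matrix(m, "mrna_probe")

  mirna_samples <- c(gpg[seq_len(config$n_mirna_gpg)], ngm)
  mm <- matrix(stats::rnorm(config$n_mirna_features * length(mirna_samples),
                            config$baseline_log2, config$noise_sd),
               nrow = config$n_mirna_features,
               dimnames = list(mir_ids, mirna_samples))
  gpg_mi <- gpg[seq_len(config$n_mirna_gpg)]
  mm[mir_gpg, gpg_mi] <- mm[mir_gpg, gpg_mi] + config$mirna_effect_log2
  mm[mir_ngm, ngm] <- mm[mir_ngm, ngm] + config$mirna_effect_log2
  mirna <- expression_matrix(mm, "mirna")

  ## ---- annotation ----------------------------------------------------------
  dels <- config$deletions
  gene_w <- 20000L; mir_w <- 200L
  del1 <- if (nrow(dels)) dels[1L, ] else NULL
  del_gene_rec <- if (length(del_genes) && !is.null(del1)) {
    s <- sort(sample(seq(del1$start, del1$end - gene_w), length(del_genes)))
    data.frame(feature_id = del_genes, symbol = del_genes,
               chromosome = del1$chromosome, start = s, end = s + gene_w - 1L,
               strand = "+", feature_class = "gene", stringsAsFactors = FALSE)
  } else NULL
  other_genes <- setdiff(gene_ids, del_genes)
  sig_other <- intersect(other_genes, c(sig_gpg, sig_ngm))
  null_genes <- setdiff(other_genes, sig_other)
  # planted signature genes outside deletion genes never land inside a deletion
  sig_rec <- place_features(sig_other, "gene", gene_w, chroms, forbidden = dels)
  null_rec <- place_features(null_genes, "gene", gene_w, chroms)

  region_mirs <- if (is.null(del1)) character() else
    utils::head(setdiff(mir_ids, c(mir_gpg, mir_ngm)), config$n_region_mirnas)
  region_mir_rec <- if (length(region_mirs)) {
    s <- sort(sample(seq(del1$start, del1$end - mir_w), length(region_mirs)))
    data.frame(feature_id = region_mirs, symbol = region_mirs,
               chromosome = del1$chromosome, start = s, end = s + mir_w - 1L,
               strand = "+", feature_class = "mirna", stringsAsFactors = FALSE)
  } else NULL
  # one planted IPG_PPG miRNA nested inside an IPG_PPG-up host gene
  intragenic <- NULL
  host_rec <- NULL
  if (length(mir_ngm) && length(plain_ngm)) {
    host <- plain_ngm[1L]
    hrow <- sig_rec[sig_rec$feature_id == host, ]
    host_rec <- data.frame(feature_id = mir_ngm[1L], symbol = mir_ngm[1L],
                           chromosome = hrow$chromosome,
                           start = hrow$start + 50L,
                           end = hrow$start + 50L + mir_w - 1L,
                           strand = "+", feature_class = "mirna",
                           stringsAsFactors = FALSE)
    intragenic <- data.frame(mirna = mir_ngm[1L], host_gene = host,
                             stringsAsFactors = FALSE)
  }
  placed_mirs <- c(region_mirs, if (!is.null(host_rec)) host_rec$feature_id)
  other_mir_rec <- place_features(setdiff(mir_ids, placed_mirs), "mirna",
                                  mir_w, chroms)
  records <- rbind(del_gene_rec, sig_rec, null_rec, region_mir_rec, host_rec,
                   other_mir_rec)
  annot <- genome_annotation(records, toy_cytobands())

  ## ---- target predictions (planted targets + random decoys) ---------------
  planted <- c(mir_ngm, mir_gpg)
  pred_mir <- c(rep(mir_ngm, each = tpm), rep(mir_gpg, each = tpm))
  pred_gene <- c(tgt_gpgup, tgt_ngmup)
  decoys <- setdiff(mir_ids, planted)
  if (length(decoys)) {
    pred_mir <- c(pred_mir, rep(decoys, each = tpm))
    pred_gene <- c(pred_gene,
                   sample(gene_ids, length(decoys) * tpm, replace = TRUE))
  }
  preds <- target_prediction_map(pred_mir, pred_gene)

  ## ---- SNP arrays ----------------------------------------------------------
  snp_samples <- c(gpg, ngm[seq_len(config$n_snp_ipg_ppg)])
  positions <- lapply(chroms, function(len)
    round(seq(1, len, length.out = config$probes_per_chrom)))
  carriers <- list()
  for (i in seq_len(nrow(dels))) {
    members <- snp_samples[unclass(groups)[snp_samples] == dels$group[i]]
    n_carry <- round(dels$carrier_fraction[i] * length(members))
    carriers[[i]] <- sample(members, n_carry)
  }
  snp <- lapply(snp_samples, function(sid) {
    pr <- do.call(rbind, lapply(names(chroms), function(chr) {
      pos <- positions[[chr]]
      n <- length(pos)
      lrr <- stats::rnorm(n, 0, config$lrr_noise_sd)
      geno <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
      for (i in seq_len(nrow(dels))) {
        if (dels$chromosome[i] != chr || !(sid %in% carriers[[i]])) next
        inside <- pos >= dels$start[i] & pos <= dels$end[i]
        lrr[inside] <- lrr[inside] + config$deletion_lrr_shift
        het <- inside & geno == 1L
        geno[het] <- sample(c(0L, 2L), sum(het), replace = TRUE)
      }
      baf <- pmin(1, pmax(0, geno / 2 + stats::rnorm(n, 0, config$baf_noise_sd)))
      data.frame(probe_id = sprintf("%s_p%04d", chr, seq_len(n)),
                 chromosome = chr, position = pos, lrr = lrr, baf = baf,
                 stringsAsFactors = FALSE)
    }))
    snp_array_sample(sid, pr)
  })
  names(snp) <- snp_samples

  ## ---- survival ------------------------------------------------------------
  surv_groups <- rep(c("GPG", "IPG_PPG"), c(config$n_surv_gpg, config$n_surv_ngm))
  rates <- ifelse(surv_groups == "GPG", config$hazard_gpg, config$hazard_ngm)
  death <- stats::rexp(length(rates), rates)
  cens <- stats::runif(length(rates), 0, config$max_follow_up)
  surv <- survival_table(data.frame(
    sample_id = sprintf("SURV_%03d", seq_along(rates)),
    time = pmin(death, cens), event = as.integer(death <= cens),
    group = surv_groups, stringsAsFactors = FALSE))

  horizons <- c(5, 10, 15)
  surv_true <- data.frame(
    group = rep(c("GPG", "IPG_PPG"), each = length(horizons)),
    horizon = rep(horizons, 2),
    surv = c(exp(-config$hazard_gpg * horizons),
             exp(-config$hazard_ngm * horizons)))

  truth <- list(mirna_up_gpg = sort(mir_gpg), mirna_up_ngm = sort(mir_ngm),
                mrna_up_gpg = sort(sig_gpg), mrna_up_ngm = sort(sig_ngm),
                pairs = pairs, deletions = dels,
                carriers = lapply(carriers, sort),
                deletion_genes = sort(del_genes),
                region_mirnas = sort(region_mirs),
                intragenic = intragenic,
                esc_shared_ngm = sort(esc_shared_ngm),
                esc_shared_gpg = sort(esc_shared_gpg),
                surv_true = surv_true)

  list(mrna = mrna, mirna = mirna, snp = snp, surv = surv, annot = annot,
       preds = preds, groups = groups, truth = truth, config = config)
}

#' Write all cohort artifacts to a directory
#'
#' Serializes a generated cohort in the package's file formats (TSV matrices,
#' TSV annotation and cytobands, two-column prediction TSV, per-sample SNP
#' TSVs, survival CSV) plus `truth.json`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$mrna, file.path(dir, "mrna.tsv"))
  write_expression_matrix(cohort$mirna, file.path(dir, "mirna.tsv"))
  write_table(data.frame(sample_id = names(cohort$groups),
                         group = unclass(cohort$groups)),
              file.path(dir, "groups.tsv"))
  write_table(cohort$annot$records, file.path(dir, "annotation.tsv"))
  write_table(cohort$annot$cytobands, file.path(dir, "cytobands.tsv"))
  pred_rows <- data.frame(
    mirna = rep(names(cohort$preds), lengths(cohort$preds)),
    gene = unlist(cohort$preds, use.names = FALSE))
  utils::write.table(pred_rows, file.path(dir, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  snp_dir <- file.path(dir, "snp")
  dir.create(snp_dir, showWarnings = FALSE)
  for (s in cohort$snp)
    write_table(s$probes, file.path(snp_dir, paste0(s$sample_id, ".tsv")))
  utils::write.csv(as.data.frame(cohort$surv), file.path(dir, "survival.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
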