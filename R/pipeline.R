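#' Run configuration for the full pipeline
#'
#' @param synthetic Generate the inputs with [generate_cohort()].
#' @param seed Seed for the synthetic cohort (ignored when `paths` given).
#' @param cohort_args Extra arguments to [cohort_config()].
#' @param paths Named list of input files for a user-data run: `mrna`,
#'   `mirna`, `groups`, `annotation`, `cytobands`, `predictions`, `snp_dir`,
#'   `survival` (all in the package's formats).
#' @param out_dir Output directory for result tables and the JSON run report.
#' @param mirna_alpha,mirna_min_fc miRNA-branch thresholds.
#' @param mrna_qmax mRNA-branch q-value threshold.
#' @param cnv_params List passed to [call_copy_number()].
#' @param min_support Recurrent-region support threshold.
#' @param comparison Two group labels compared throughout.
#' @param esc_group Reference group for the proximity distances (skipped if
#'   absent).
#' @param horizons Survival-rate horizons (years).
#' @return Validated list of class `RunConfig`.
#' @export
run_config <- function(synthetic = TRUE, seed = 42, cohort_args = list(),
                       paths = NULL, out_dir = tempfile("gctomics_run_"),
                       mirna_alpha = 0.05, mirna_min_fc = 2,
                       mrna_qmax = 0.001,
                       cnv_params = list(), min_support = 3,
                       comparison = c("GPG", "IPG_PPG"), esc_group = "ESC",
                       horizons = c(5, 10, 15)) {
  stopifnot(length(comparison) == 2, mirna_alpha > 0, mirna_alpha <= 1,
            mirna_min_fc >= 1, mrna_qmax > 0, mrna_qmax <= 1, min_support >= 1)
  if (!synthetic) {
    if (is.null(paths)) stop("non-synthetic runs need `paths`")
    missing <- !vapply(paths[!names(paths) %in% "snp_dir"], file.exists, logical(1))
    if (any(missing))
      stop("missing input files: ", paste(names(paths)[missing], collapse = ", "))
  }
  structure(as.list(environment()), class = "RunConfig")
}

load_run_inputs <- function(config) {
  if (config$synthetic) {
    args <- config$cohort_args
    args$seed <- config$seed
    return(generate_cohort(do.call(cohort_config, args)))
  }
  p <- config$paths
  g <- read_table(p$groups)
  snp_files <- list.files(p$snp_dir, pattern = "\\.tsv$", full.names = TRUE)
  snp <- lapply(snp_files, read_snp_array)
  names(snp) <- vapply(snp, function(s) s$sample_id, character(1))
  list(mrna = read_expression_matrix(p$mrna, "mrna_probe"),
       mirna = read_expression_matrix(p$mirna, "mirna"),
       groups = sample_groups(stats::setNames(g$group, g$sample_id)),
       annot = read_genome_annotation(p$annotation, "one", p$cytobands),
       preds = read_target_predictions(p$predictions),
       snp = snp,
       surv = read_survival(p$survival),
       truth = NULL)
}

#' Run the full integrative pipeline
#'
#' Stage order: differential signatures (miRNA then mRNA), sample-structure
#' distances against the reference group, miRNA-target integration,
#' copy-number calling and recurrent-region intersection with expression
#' integration, cytoband over-representation of the signature genes, and
#' survival comparison. All result tables are written under
#' `config$out_dir` together with `report.json`; any stage failure aborts
#' with a stage-tagged error. Fully deterministic given the seed.
#'
#' @param config A [run_config()].
#' @return The run report (named list), invisibly written as JSON.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    report$stages[[name]] <<- c(res, list(seconds = round(proc.time()[["elapsed"]] - t0, 3)))
    invisible(res)
  }
  a <- config$comparison[1L]; b <- config$comparison[2L]

  inputs <- stage("inputs", {
    inp <- load_run_inputs(config)
    list(n_mrna = nrow(inp$mrna$values), n_mirna = nrow(inp$mirna$values),
         n_samples = length(inp$groups), inp = inp)
  })
  inp <- inputs$inp
  report$stages$inputs$inp <- NULL

  sig <- stage("diffexpr", {
    mi <- mirna_signatures(inp$mirna, inp$groups, a, b,
                           alpha = config$mirna_alpha, min_fc = config$mirna_min_fc)
    mr <- mrna_signatures(inp$mrna, inp$groups, a, b, q_max = config$mrna_qmax)
    write_signature_table(mi[[a]], file.path(config$out_dir, "mirna_sig_up_a.tsv"))
    write_signature_table(mi[[b]], file.path(config$out_dir, "mirna_sig_up_b.tsv"))
    write_signature_table(mr[[a]], file.path(config$out_dir, "mrna_sig_up_a.tsv"))
    write_signature_table(mr[[b]], file.path(config$out_dir, "mrna_sig_up_b.tsv"))
    list(mirna_up_a = nrow(mi[[a]]$table), mirna_up_b = nrow(mi[[b]]$table),
         mrna_up_a = nrow(mr[[a]]$table), mrna_up_b = nrow(mr[[b]]$table),
         mi = mi, mr = mr)
  })
  mi <- sig$mi; mr <- sig$mr
  report$stages$diffexpr$mi <- report$stages$diffexpr$mr <- NULL
  sig_union <- union(signature_features(mr[[a]]), signature_features(mr[[b]]))

  stage("structure", {
    res <- list(n_signature_features = length(sig_union))
    if (config$esc_group %in% unclass(inp$groups)) {
      d_a <- group_distance(inp$mrna, inp$groups, a, config$esc_group, sig_union)
      d_b <- group_distance(inp$mrna, inp$groups, b, config$esc_group, sig_union)
      dist_tab <- data.frame(
        group_a = c(a, b), group_b = config$esc_group,
        mean_distance = c(d_a$mean_distance, d_b$mean_distance),
        se = c(d_a$se, d_b$se), n_pairs = c(d_a$n_pairs, d_b$n_pairs))
      write_table(dist_tab, file.path(config$out_dir, "esc_distances.tsv"))
      res$distance_a_esc <- d_a$mean_distance
      res$distance_b_esc <- d_b$mean_distance
      res$closer_to_esc <- if (d_a$mean_distance < d_b$mean_distance) a else b
    }
    emb <- pca_embedding(inp$mrna, k = 2)
    write_table(data.frame(sample = rownames(emb$coords), emb$coords),
                file.path(config$out_dir, "pca_mrna.tsv"))
    res
  })

  integ <- stage("integration", {
    universe <- toupper(feature_ids(inp$mrna))
    pairs <- anti_correlated_pairs(mi, mr, inp$preds, universe = universe)
    write_table(pairs, file.path(config$out_dir, "mirna_target_pairs.tsv"))
    mts <- multi_target_summary(pairs)
    write_table(mts$targets, file.path(config$out_dir, "multi_target_genes.tsv"))
    intra <- annotate_intragenic(inp$annot)
    write_table(intra, file.path(config$out_dir, "intragenic_mirnas.tsv"))
    list(n_pairs = nrow(pairs),
         n_multi_target_genes = sum(mts$targets$n_mirnas >= 2),
         n_intragenic = sum(!is.na(intra$host_gene)), pairs = pairs)
  })
  report$stages$integration$pairs <- NULL

  cnvres <- stage("cnv", {
    segs <- lapply(inp$snp, function(s)
      do.call(call_copy_number, c(list(sample = s), config$cnv_params)))
    ab <- aberration_table(segs, inp$annot$cytobands)
    write_table(ab, file.path(config$out_dir, "aberrations.tsv"))
    reg <- recurrent_regions(segs, inp$groups, b, "loss",
                             min_support = config$min_support,
                             cytobands = inp$annot$cytobands)
    write_table(as.data.frame(reg), file.path(config$out_dir, "recurrent_regions.tsv"))
    integ_cnv <- integrate_cnv_expression(reg, mr, inp$annot)
    write_table(integ_cnv, file.path(config$out_dir, "cnv_expression.tsv"))
    list(n_aberrant_segments = nrow(ab), n_recurrent_regions = nrow(reg),
         region_support = if (nrow(reg)) max(reg$support) else 0L,
         n_dosage_consistent = if (nrow(integ_cnv)) sum(integ_cnv$n_consistent) else 0L)
  })

  stage("enrichment", {
    bands <- cytoband_sets(inp$annot)
    universe <- toupper(feature_ids(inp$mrna))
    query <- toupper(signature_features(mr[[a]]))
    res <- if (length(query)) {
      enr <- enrich_collection(query, bands, universe)
      write_table(enr, file.path(config$out_dir, "cytoband_enrichment.tsv"))
      list(n_band_sets = length(bands), n_significant = sum(enr$significant),
           top_band = enr$set_id[1L])
    } else list(n_band_sets = length(bands), n_significant = 0L)
    res
  })

  stage("survival", {
    km_a <- kaplan_meier(inp$surv, a)
    km_b <- kaplan_meier(inp$surv, b)
    lr <- logrank(inp$surv, a, b)
    rates <- data.frame(
      group = rep(c(a, b), each = length(config$horizons)),
      horizon = rep(config$horizons, 2),
      surv = c(km_rate_at(km_a, config$horizons),
               km_rate_at(km_b, config$horizons)))
    write_table(rates, file.path(config$out_dir, "survival_rates.tsv"))
    list(logrank_chisq = lr$chi_square, logrank_p = lr$p,
         rates_a = unname(km_rate_at(km_a, config$horizons)),
         rates_b = unname(km_rate_at(km_b, config$horizons)))
  })

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}
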