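# Shared, memoized synthetic cohorts so the heavier multi-seed checks reuse
# the same generated data instead of regenerating per test file.

default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(cohort_config(seed = 42))
    cache
  }
})

# 20 default-condition cohorts (seeds 1..20) for seed-robust recovery checks
cohorts20 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(1:20, function(s) generate_cohort(cohort_config(seed = s)))
    cache
  }
})

# 20 all-null cohorts: nothing planted, no deletions
null_config <- function(seed) {
  cohort_config(n_up_mirna_gpg = 0, n_up_mirna_ngm = 0,
                n_sig_mrna_gpg = 0, n_sig_mrna_ngm = 0,
                n_deletion_genes = 0, n_region_mirnas = 0,
                n_esc_shared_ngm = 0, n_esc_shared_gpg = 0,
                deletions = data.frame(chromosome = character(),
                                       start = numeric(), end = numeric(),
                                       group = character(),
                                       carrier_fraction = numeric(),
                                       copy_number = numeric(),
                                       stringsAsFactors = FALSE),
                seed = seed)
}

null_cohorts <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(1:20, function(s) generate_cohort(null_config(s)))
    cache
  }
})

# Table 3 fixture: signature miRNAs of both prognostic groups with the printed
# prediction rows; targets sit in the opposite group's mRNA signature.
table3_fixture <- function() {
  preds <- read_target_predictions(
    system.file("extdata", "table3_predictions.tsv", package = "gctomics"))
  gpg_mirs <- c("miR-142-5p", "miR-146a")
  ngm_mirs <- c("let-7e", "miR-26a", "miR-133b", "miR-154", "miR-181c",
                "miR-218", "miR-335", "miR-376a", "miR-410", "miR-433",
                "miR-503", "miR-539", "miR-543")
  mirna_sigs <- list(
    GPG = signature_set("GPG", data.frame(feature = gpg_mirs)),
    IPG_PPG = signature_set("IPG_PPG", data.frame(feature = ngm_mirs)))
  gpg_up_genes <- sort(unique(unlist(preds[intersect(ngm_mirs, names(preds))])))
  ngm_up_genes <- sort(unique(unlist(preds[gpg_mirs])))
  mrna_sigs <- list(
    GPG = signature_set("GPG", data.frame(feature = gpg_up_genes)),
    IPG_PPG = signature_set("IPG_PPG", data.frame(feature = ngm_up_genes)))
  list(preds = preds, mirna_sigs = mirna_sigs, mrna_sigs = mrna_sigs)
}
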