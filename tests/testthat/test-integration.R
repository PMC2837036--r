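test_that("Fisher exact 2x2 matches enumeration and reference implementation", {
  # (3,1,1,3): 5 admissible tables, two-sided p = 34/70 by hand enumeration
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), oracle_fisher_two_sided(3, 1, 1, 3),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(3, 1, 1, 3),
               stats::fisher.test(matrix(c(3, 1, 1, 3), 2))$p.value,
               tolerance = 1e-9)
  # transpose symmetry
  expect_equal(fisher_exact_2x2(10, 2, 2, 10), fisher_exact_2x2(2, 10, 10, 2),
               tolerance = 1e-12)
  # degenerate margins
  expect_warning(p <- fisher_exact_2x2(0, 0, 0, 10), "degenerate")
  expect_equal(p, 1)
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "nonnegative")
})

test_that("Fisher exact agrees with full enumeration and the reference test", {
  expect_lt(fisher_sweep_maxdiff(30), 1e-10)
  # spot-check a random subset against the reference implementation
  set.seed(61)
  for (i in 1:100) {
    tb <- rmultinom(1, sample(4:60, 1), prob = runif(4, 0.05, 1))[, 1L]
    if (any(c(tb[1] + tb[2], tb[3] + tb[4], tb[1] + tb[3], tb[2] + tb[4]) == 0)) next
    expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4]),
                 stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-8)
  }
})

test_that("per-miRNA enrichment builds the documented 2x2 and is monotone in overlap", {
  # universe 1000, signature 50, targets 40, overlap 15 -> table (15,35,25,925)
  universe <- sprintf("G%04d", 1:1000)
  sig <- universe[1:50]
  targets <- c(universe[1:15], universe[501:525])  # overlap 15 of 40
  preds <- target_prediction_map(rep("mirX", 40), targets)
  p <- mirna_enrichment("mirX", sig, preds, universe)
  expect_equal(p, fisher_exact_2x2(15, 35, 25, 925), tolerance = 1e-12)
  expect_equal(p, stats::fisher.test(matrix(c(15, 35, 25, 925), 2,
                                            byrow = TRUE))$p.value,
               tolerance = 1e-9)
  # zero overlap, small sets, large universe: no association
  preds0 <- target_prediction_map(rep("mirY", 5), universe[900:904])
  expect_gt(mirna_enrichment("mirY", universe[1:5], preds0, universe), 0.9)
  # missing prediction entry -> NA; too-small universe -> error
  expect_true(is.na(mirna_enrichment("nope", sig, preds, universe)))
  expect_error(mirna_enrichment("mirX", sig, preds, universe[1:200]),
               "universe smaller")
  # monotone nonincreasing p in the overlap count at fixed margins
  ps <- vapply(0:20, function(a)
    fisher_exact_2x2(a, 20 - a, 30 - a, 950 + a, alternative = "greater"),
    numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("anti-correlated pairing applies the direction and membership rules", {
  preds <- target_prediction_map(
    c("miR-142-5p", "miR-142-5p", "miR-146a", "miR-9"),
    c("RUNX1T1", "GENEUP_GPG", "RUNX1T1", "SOMEGENE"))
  mirna_sigs <- list(
    GPG = signature_set("GPG", data.frame(feature = c("miR-142-5p", "miR-146a",
                                                      "miR-nopred"))),
    IPG_PPG = signature_set("IPG_PPG", data.frame(feature = character())))
  mrna_sigs <- list(
    GPG = signature_set("GPG", data.frame(feature = "GENEUP_GPG")),
    IPG_PPG = signature_set("IPG_PPG", data.frame(feature = "RUNX1T1")))
  pairs <- suppressMessages(
    anti_correlated_pairs(mirna_sigs, mrna_sigs, preds))
  # RUNX1T1 pairs with both GPG miRNAs; the same-group gene never pairs
  expect_equal(pairs$target, c("RUNX1T1", "RUNX1T1"))
  expect_setequal(pairs$mirna, c("miR-142-5p", "miR-146a"))
  expect_true(all(pairs$mirna_up_group != pairs$target_up_group))
  expect_false("GENEUP_GPG" %in% pairs$target)
  # miRNA with no prediction entry is skipped with a message, not an error
  expect_message(anti_correlated_pairs(mirna_sigs, mrna_sigs, preds),
                 "no prediction entry")
})

test_that("the printed multi-target structure is recovered from the fixture", {
  fx <- table3_fixture()
  pairs <- suppressMessages(
    anti_correlated_pairs(fx$mirna_sigs, fx$mrna_sigs, fx$preds))
  # every pair satisfies the membership invariants
  expect_true(all(pairs$mirna_up_group != pairs$target_up_group))
  expect_true(all(mapply(function(m, t) t %in% fx$preds[[m]],
                         pairs$mirna, pairs$target)))
  smry <- multi_target_summary(pairs)
  expect_equal(smry$targets$n_mirnas[smry$targets$gene == "WAPAL"], 4L)
  expect_equal(smry$targets$mirnas[smry$targets$gene == "WAPAL"],
               "miR-26a,miR-335,miR-433,miR-539")
  expect_equal(smry$targets$n_mirnas[smry$targets$gene == "NUP50"], 3L)
  expect_equal(smry$targets$mirnas[smry$targets$gene == "NUP50"],
               "miR-218,miR-26a,miR-503")
  # shared-target miRNA pairs include the printed relations
  mp <- smry$mirna_pairs
  row <- mp[mp$mirna_a == "miR-26a" & mp$mirna_b == "miR-503", ]
  expect_true(grepl("CREBL2", row$shared_targets) &&
                grepl("DNAJA2", row$shared_targets))
  # empty input gives empty tables
  empty <- multi_target_summary(pairs[0, ])
  expect_equal(nrow(empty$targets), 0L)
})

test_that("planted coupling is recovered with significant per-miRNA enrichment", {
  meds <- vapply(cohorts20()[1:10], function(ch) {
    mi <- mirna_signatures(ch$mirna, ch$groups)
    mr <- mrna_signatures(ch$mrna, ch$groups)
    universe <- rownames(ch$mrna$values)
    opp <- c(GPG = "IPG_PPG", IPG_PPG = "GPG")
    ps <- unlist(lapply(mi, function(s) {
      sig_genes <- signature_features(mr[[opp[[s$group]]]])
      vapply(signature_features(s), function(m)
        mirna_enrichment(m, sig_genes, ch$preds, universe), numeric(1))
    }))
    planted <- c(ch$truth$mirna_up_gpg, ch$truth$mirna_up_ngm)
    recovered <- unlist(lapply(mi, signature_features))
    is_planted <- sub("^.*\\.", "", names(ps)) %in% planted
    all(ps[is_planted] < 0.05) &&
      (sum(!is_planted) == 0 || all(ps[!is_planted] >= 1e-4))
  }, logical(1))
  expect_true(stats::median(meds) == 1)
})

test_that("intragenic assignment requires containment and prefers the smaller host", {
  rec <- data.frame(
    feature_id = c("SLIT2", "BIGGENE", "NESTED", "miR-218", "miR-edge", "miR-out"),
    symbol = c("SLIT2", "BIGGENE", "NESTED", "miR-218", "miR-edge", "miR-out"),
    chromosome = c("chr4", "chr7", "chr7", "chr4", "chr4", "chr7"),
    start = c(1000, 100, 400, 2000, 900, 5000),
    end = c(9000, 2000, 1200, 2100, 1100, 5100),
    strand = "+",
    feature_class = c("gene", "gene", "gene", "mirna", "mirna", "mirna"),
    stringsAsFactors = FALSE)
  ann <- genome_annotation(rec)
  intra <- annotate_intragenic(ann)
  expect_equal(intra$host_gene[intra$mirna == "miR-218"], "SLIT2")
  # partial boundary overlap is not intragenic
  expect_true(is.na(intra$host_gene[intra$mirna == "miR-edge"]))
  expect_true(is.na(intra$host_gene[intra$mirna == "miR-out"]))
  # nested genes: the smaller containing gene wins
  rec2 <- rec
  rec2[rec2$feature_id == "miR-out", c("start", "end")] <- c(500, 600)
  intra2 <- annotate_intragenic(genome_annotation(rec2))
  expect_equal(intra2$host_gene[intra2$mirna == "miR-out"], "NESTED")
  # the generator's planted intragenic miRNA is found
  ch <- default_cohort()
  gintra <- annotate_intragenic(ch$annot)
  expect_equal(
    gintra$host_gene[gintra$mirna == ch$truth$intragenic$mirna],
    ch$truth$intragenic$host_gene)
})
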