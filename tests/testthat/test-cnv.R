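flat_sample <- function(n = 120, chroms = "chr1", lrr = 0, sd = 0,
                        spacing = 1000, id = "S1") {
  probes <- do.call(rbind, lapply(chroms, function(chr) {
    pos <- seq(spacing, by = spacing, length.out = n)
    data.frame(probe_id = sprintf("%s_%03d", chr, seq_len(n)), chromosome = chr,
               position = pos,
               lrr = lrr + if (sd > 0) rnorm(n, 0, sd) else 0,
               baf = rep(c(0, 0.5, 1), length.out = n),
               stringsAsFactors = FALSE)
  }))
  snp_array_sample(id, probes)
}

test_that("flat tracks call one neutral segment per chromosome", {
  s <- flat_sample(n = 50, chroms = c("chr1", "chr2"))
  segs <- call_copy_number(s)
  expect_equal(nrow(segs), 2L)
  expect_true(all(segs$state == "neutral"))
  expect_equal(segs$n_probes, c(50L, 50L))
  # segments partition the probe span
  expect_equal(segs$start, c(1000, 1000))
  expect_equal(segs$end, c(50000, 50000))
})

test_that("planted deletions are recovered to within two probe positions", {
  ch <- default_cohort()
  del <- ch$truth$deletions[1L, ]
  carrier <- ch$truth$carriers[[1L]][1L]
  non_carrier <- setdiff(paste0("NGM_", 1:5), ch$truth$carriers[[1L]])[1L]
  spacing <- diff(ch$snp[[carrier]]$probes$position[1:2])

  segs <- call_copy_number(ch$snp[[carrier]])
  loss <- segs[segs$state == "loss", ]
  expect_equal(nrow(loss), 1L)
  expect_equal(loss$chromosome, del$chromosome)
  expect_lt(abs(loss$start - del$start), 2.5 * spacing)
  expect_lt(abs(loss$end - del$end), 2.5 * spacing)
  expect_lt(loss$mean_lrr, -0.3)
  # hemizygous loss: heterozygous BAF collapsed, so high confidence
  expect_lt(loss$het_fraction, 0.1)
  expect_false(loss$low_confidence)
  # segments partition each chromosome without overlap
  for (chr in unique(segs$chromosome)) {
    sc <- segs[segs$chromosome == chr, ]
    expect_true(all(sc$start[-1L] > sc$end[-nrow(sc)]))
    expect_equal(sum(sc$n_probes), 500L)
  }
  # non-carriers stay neutral
  segs0 <- call_copy_number(ch$snp[[non_carrier]])
  expect_equal(nrow(segs0[segs0$state != "neutral", ]), 0L)
})

test_that("isolated extreme probes do not trigger a call", {
  s <- flat_sample(n = 100)
  pr <- s$probes
  pr$lrr[c(10, 30, 50, 70, 90)] <- -1
  s2 <- snp_array_sample("S1", pr)
  segs <- call_copy_number(s2)
  expect_true(all(segs$state == "neutral"))
  # a chromosome with fewer probes than the window is neutral with a warning
  short <- flat_sample(n = 3)
  expect_warning(segs <- call_copy_number(short), "fewer than")
  expect_equal(segs$state, "neutral")
})

test_that("caller sensitivity and specificity hold over 100 seeded trials", {
  hits <- logical(100)
  false_calls <- integer(100)
  for (i in 1:100) {
    set.seed(i)
    s <- flat_sample(n = 400, sd = 0.15, id = "T")
    pr <- s$probes
    pr$lrr[100:160] <- pr$lrr[100:160] - 0.45   # 61-probe deletion
    pr$baf[100:160] <- round(pr$baf[100:160])
    segs <- call_copy_number(snp_array_sample("T", pr))
    loss <- segs[segs$state == "loss", ]
    hits[i] <- nrow(loss) >= 1L &&
      any(loss$start <= pr$position[157] & loss$end >= pr$position[103])
    null_segs <- call_copy_number(s)
    false_calls[i] <- sum(null_segs$state == "loss")
  }
  expect_gte(mean(hits), 0.95)
  expect_lte(mean(false_calls), 0.05)
})

chr4_bands <- function() {
  data.frame(
    chromosome = "chr4",
    start = c(1, 25e6 + 1, 50e6 + 1, 65e6 + 1, 76e6 + 1, 95e6 + 1, 115e6 + 1,
              125e6 + 1, 140e6 + 1, 165e6 + 1),
    end = c(25e6, 50e6, 65e6, 76e6, 95e6, 115e6, 125e6, 140e6, 165e6, 191154276),
    band = c("p15", "p11", "q13.1", "q13.3", "q21", "q25", "q28.1", "q28.3",
             "q31", "q35"),
    stringsAsFactors = FALSE)
}

test_that("aberration tables carry cytoband span labels", {
  bands <- chr4_bands()
  seg <- data.frame(sample_id = "S1", chromosome = "chr4",
                    start = 75084501, end = 131387610, state = "loss",
                    mean_lrr = -0.45, n_probes = 100, het_fraction = 0,
                    low_confidence = FALSE, stringsAsFactors = FALSE)
  tab <- aberration_table(list(seg), bands)
  expect_equal(tab$cytoband, "4q13.3-4q28.3")
  expect_equal(tab$size, 131387610 - 75084501 + 1)
  # a segment inside one band gets a single label
  seg2 <- seg
  seg2$start <- 70e6; seg2$end <- 71e6
  expect_equal(aberration_table(list(seg2), bands)$cytoband, "4q13.3")
  # neutral-only input gives an empty table
  seg3 <- seg; seg3$state <- "neutral"
  expect_equal(nrow(aberration_table(list(seg3), bands)), 0L)
})

mk_seg <- function(sample, start, end, state = "loss", chr = "chr1") {
  data.frame(sample_id = sample, chromosome = chr, start = start, end = end,
             state = state, mean_lrr = -0.4, n_probes = 10, het_fraction = 0,
             low_confidence = FALSE, stringsAsFactors = FALSE)
}

test_that("recurrent regions intersect same-state segments within a group", {
  g <- sample_groups(stats::setNames(rep("IPG_PPG", 5), paste0("N", 1:5)))
  segs <- list(mk_seg("N1", 100, 500), mk_seg("N2", 200, 600),
               mk_seg("N3", 300, 700), mk_seg("N4", 2000, 2100),
               mk_seg("N5", 5000, 5100, state = "gain"))
  reg <- recurrent_regions(segs, g, "IPG_PPG", "loss", min_support = 3)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$support, 3L)
  expect_equal(c(reg$start, reg$end), c(300, 500))
  expect_equal(reg$samples, "N1,N2,N3")
  # maximality: one breakpoint beyond either boundary drops the support
  oracle <- oracle_recurrent_per_base(do.call(rbind, segs), paste0("N", 1:5),
                                      "loss", 3, 10000)
  expect_equal(reg$start, oracle$start)
  expect_equal(reg$end, oracle$end)
  # disjoint losses never form a region
  segs2 <- list(mk_seg("N1", 100, 200), mk_seg("N2", 300, 400))
  expect_equal(nrow(recurrent_regions(segs2, g, "IPG_PPG", "loss", 2)), 0L)
  expect_error(recurrent_regions(segs, g, "IPG_PPG", "loss", 6), "min_support")
})

test_that("sweep-line regions equal the per-base brute-force counter", {
  for (seed in 1:5) {
    set.seed(seed)
    samples <- paste0("S", 1:10)
    g <- sample_groups(stats::setNames(rep("IPG_PPG", 10), samples))
    segs <- lapply(samples, function(s) {
      n <- sample(1:3, 1)
      start <- sort(sample(1:18000, n))
      end <- pmin(start + sample(500:5000, n, replace = TRUE), 20000)
      do.call(rbind, lapply(seq_len(n), function(i)
        mk_seg(s, start[i], end[i])))
    })
    reg <- recurrent_regions(segs, g, "IPG_PPG", "loss", min_support = 3)
    oracle <- oracle_recurrent_per_base(do.call(rbind, segs), samples,
                                        "loss", 3, 20000)
    if (is.null(oracle)) {
      expect_equal(nrow(reg), 0L)
    } else {
      expect_equal(nrow(reg), nrow(oracle))
      expect_equal(reg$start, oracle$start)
      expect_equal(reg$end, oracle$end)
      expect_equal(reg$support, oracle$support)
      expect_equal(reg$samples, oracle$samples)
    }
  }
})

test_that("features in a region are selected by >= 1 bp overlap", {
  rec <- data.frame(
    feature_id = c("gIn1", "gIn2", "gSpan", "gOut", "m1", "m2"),
    symbol = c("GIN1", "GIN2", "GSPAN", "GOUT", "M1", "M2"),
    chromosome = "chr1",
    start = c(1100, 1500, 900, 5000, 1200, 4000),
    end = c(1200, 1600, 1050, 5100, 1210, 4010),
    strand = "+",
    feature_class = c("gene", "gene", "gene", "gene", "mirna", "mirna"),
    stringsAsFactors = FALSE)
  ann <- genome_annotation(rec)
  region <- list(chromosome = "chr1", start = 1000, end = 2000)
  fr <- features_in_region(region, ann)
  expect_setequal(fr$genes$feature_id, c("gIn1", "gIn2", "gSpan"))
  expect_equal(fr$mirnas$feature_id, "m1")
  # region between features is empty
  fr2 <- features_in_region(list(chromosome = "chr1", start = 2500, end = 3000), ann)
  expect_equal(nrow(fr2$genes) + nrow(fr2$mirnas), 0L)
  # the cohort's planted region miRNAs are all recovered
  ch <- default_cohort()
  del <- ch$truth$deletions[1L, ]
  fr3 <- features_in_region(del, ch$annot)
  expect_true(all(ch$truth$region_mirnas %in% fr3$mirnas$feature_id))
  expect_true(all(ch$truth$deletion_genes %in% fr3$genes$feature_id))
})

test_that("dosage-consistent signature genes are counted per lost region", {
  ch <- default_cohort()
  segs <- lapply(ch$snp, call_copy_number)
  reg <- recurrent_regions(segs, ch$groups, "IPG_PPG", "loss", 3,
                           ch$annot$cytobands)
  mr <- mrna_signatures(ch$mrna, ch$groups)
  integ <- integrate_cnv_expression(reg, mr, ch$annot)
  expect_equal(integ$n_consistent, 6L)
  expect_setequal(strsplit(integ$consistent_genes, ",")[[1L]],
                  ch$truth$deletion_genes)
  # a gene up in the deleted group is reported separately
  ann <- genome_annotation(data.frame(
    feature_id = c("gA", "gB"), symbol = c("GA", "GB"), chromosome = "chr1",
    start = c(100, 200), end = c(150, 260), strand = "+",
    feature_class = "gene", stringsAsFactors = FALSE))
  sigs <- list(GPG = signature_set("GPG", data.frame(feature = "GA")),
               IPG_PPG = signature_set("IPG_PPG", data.frame(feature = "GB")))
  regfx <- data.frame(chromosome = "chr1", start = 50, end = 300,
                      state = "loss", group = "IPG_PPG", support = 3,
                      samples = "x", cytoband = NA, stringsAsFactors = FALSE)
  out <- integrate_cnv_expression(regfx, sigs, ann)
  expect_equal(out$n_consistent, 1L)
  expect_equal(out$consistent_genes, "GA")
  expect_equal(out$n_inconsistent, 1L)
  expect_equal(out$inconsistent_genes, "GB")
  # region without signature genes counts zero
  reg0 <- regfx; reg0$start <- 1000; reg0$end <- 2000
  expect_equal(integrate_cnv_expression(reg0, sigs, ann)$n_consistent, 0L)
})
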