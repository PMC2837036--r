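#' Copy-number calling from LRR/BAF probe tracks
#'
#' A transparent median-filter + threshold + run-length caller with B-allele
#' corroboration. Per chromosome: (1) the log-R ratio is smoothed with a
#' running median of window `w`; (2) each probe is classified loss / neutral /
#' gain against the thresholds; (3) maximal same-state runs are merged,
#' absorbing interior runs of at most `max_gap_probes` dissenting probes;
#' (4) non-neutral runs with fewer than `min_probes` probes are set neutral;
#' (5) segments are emitted with mean raw LRR, probe count, and the fraction
#' of probes with BAF in (0.25, 0.75). Loss segments with `het_fraction >
#' 0.1` are flagged low-confidence (a hemizygous deletion has no heterozygous
#' probes). Chromosomes with fewer than `w` probes are emitted as a single
#' neutral segment with a warning. Input LRR is assumed baseline-normalized
#' (copy-neutral near 0); `recenter = TRUE` subtracts the per-sample median
#' first.
#'
#' @param sample A [snp_array_sample()].
#' @param w Running-median window (odd, default 5).
#' @param loss_thr,gain_thr Smoothed-LRR thresholds (defaults -0.30 / +0.25).
#' @param min_probes Minimum probes for a non-neutral segment (default 10).
#' @param max_gap_probes Dissenting probes absorbed inside a run (default 2).
#' @param recenter Subtract the sample-median LRR before calling.
#' @return `data.frame` of class `CnSegment` rows: `sample_id`, `chromosome`,
#'   `start`, `end`, `state`, `mean_lrr`, `n_probes`, `het_fraction`,
#'   `low_confidence`. Segments partition each chromosome's probe span.
#' @export
call_copy_number <- function(sample, w = 5, loss_thr = -0.30, gain_thr = 0.25,
                             min_probes = 10, max_gap_probes = 2,
                             recenter = FALSE) {
  stopifnot(inherits(sample, "SnpArraySample"), w >= 1, w %% 2 == 1,
            min_probes >= 1)
  probes <- sample$probes
  if (recenter) probes$lrr <- probes$lrr - stats::median(probes$lrr)
  segs <- list()
  for (chr in unique(probes$chromosome)) {
    pc <- probes[probes$chromosome == chr, , drop = FALSE]
    n <- nrow(pc)
    if (n < w) {
      warning("chromosome ", chr, " has fewer than ", w,
              " probes; emitted as one neutral segment")
      segs[[length(segs) + 1L]] <- data.frame(
        sample_id = sample$sample_id, chromosome = chr,
        start = pc$position[1L], end = pc$position[n], state = "neutral",
        mean_lrr = mean(pc$lrr), n_probes = n,
        het_fraction = mean(pc$baf > 0.25 & pc$baf < 0.75),
        low_confidence = FALSE, stringsAsFactors = FALSE)
      next
    }
    sm <- stats::runmed(pc$lrr, w, endrule = "median")
    state <- ifelse(sm < loss_thr, "loss", ifelse(sm > gain_thr, "gain", "neutral"))
    # absorb short dissenting runs between two runs of the same non-neutral state
    repeat {
      r <- rle(state)
      if (length(r$lengths) < 3L) break
      changed <- FALSE
      for (i in 2:(length(r$lengths) - 1L)) {
        if (r$lengths[i] <= max_gap_probes &&
            r$values[i - 1L] == r$values[i + 1L] &&
            r$values[i] != r$values[i - 1L] &&
            r$values[i - 1L] != "neutral") {
          idx <- sum(r$lengths[seq_len(i - 1L)]) + seq_len(r$lengths[i])
          state[idx] <- r$values[i - 1L]
          changed <- TRUE
          break
        }
      }
      if (!changed) break
    }
    # discard short non-neutral runs
    r <- rle(state)
    pos <- cumsum(r$lengths)
    for (i in seq_along(r$lengths)) {
      if (r$values[i] != "neutral" && r$lengths[i] < min_probes) {
        idx <- (pos[i] - r$lengths[i] + 1L):pos[i]
        state[idx] <- "neutral"
      }
    }
    r <- rle(state)
    pos <- cumsum(r$lengths)
    for (i in seq_along(r$lengths)) {
      idx <- (pos[i] - r$lengths[i] + 1L):pos[i]
      het <- mean(pc$baf[idx] > 0.25 & pc$baf[idx] < 0.75)
      segs[[length(segs) + 1L]] <- data.frame(
        sample_id = sample$sample_id, chromosome = chr,
        start = pc$position[idx[1L]], end = pc$position[idx[length(idx)]],
        state = r$values[i], mean_lrr = mean(pc$lrr[idx]),
        n_probes = length(idx), het_fraction = het,
        low_confidence = r$values[i] == "loss" && het > 0.1,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  out <- out[order(out$chromosome, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("CnSegment", "data.frame")
  out
}

band_label <- function(chromosome, position, cytobands) {
  b <- cytobands[cytobands$chromosome == chromosome &
                   cytobands$start <= position & cytobands$end >= position, ]
  if (nrow(b) == 0L) return(NA_character_)
  b$band[1L]
}

#' Cytoband span label for an interval
#'
#' Formats an interval as e.g. `"4q13.3-4q28.3"` (single-band intervals get a
#' single label). Band names in the map carry the arm (e.g. `"q13.3"`); the
#' chromosome prefix is the chromosome name without any `"chr"` prefix.
#'
#' @param chromosome,start,end Interval (1-based inclusive).
#' @param cytobands Cytoband `data.frame` (from a [genome_annotation()]).
#' @return Character label.
#' @export
cytoband_span <- function(chromosome, start, end, cytobands) {
  chr <- sub("^chr", "", chromosome)
  b1 <- band_label(chromosome, start, cytobands)
  b2 <- band_label(chromosome, end, cytobands)
  if (is.na(b1) || is.na(b2)) return(NA_character_)
  if (b1 == b2) paste0(chr, b1) else paste0(chr, b1, "-", chr, b2)
}

#' Per-sample aberration table with cytoband labels
#'
#' One row per non-neutral segment across samples, with the segment size and
#' its cytoband span.
#'
#' @param segments_list List of `CnSegment` data frames (one per sample, from
#'   [call_copy_number()]).
#' @param cytobands Cytoband `data.frame`.
#' @return `data.frame` with columns `sample_id`, `chromosome`, `start`,
#'   `end`, `size`, `state`, `cytoband`.
#' @export
aberration_table <- function(segments_list, cytobands) {
  segs <- do.call(rbind, lapply(segments_list, as.data.frame))
  segs <- segs[segs$state != "neutral", , drop = FALSE]
  if (nrow(segs) == 0L)
    return(data.frame(sample_id = character(), chromosome = character(),
                      start = integer(), end = integer(), size = integer(),
                      state = character(), cytoband = character(),
                      stringsAsFactors = FALSE))
  out <- data.frame(sample_id = segs$sample_id, chromosome = segs$chromosome,
                    start = segs$start, end = segs$end,
                    size = segs$end - segs$start + 1,
                    state = segs$state,
                    cytoband = vapply(seq_len(nrow(segs)), function(i)
                      cytoband_span(segs$chromosome[i], segs$start[i],
                                    segs$end[i], cytobands), character(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$sample_id, out$chromosome, out$start), , drop = FALSE]
}

#' Recurrent same-state regions within a sample group
#'
#' Sweep-line intersection: segment breakpoints split each chromosome into
#' elementary intervals over which the per-position count of group samples
#' carrying a same-state segment is constant; maximal runs of elementary
#' intervals with count >= `min_support` are emitted. The reported support and
#' supporting sample ids are the samples whose segments cover the entire
#' emitted region.
#'
#' @param segments_list Named list (sample id -> `CnSegment` data frame) or a
#'   list whose elements carry `sample_id` columns.
#' @param groups A [sample_groups()].
#' @param target_group Group label whose samples are intersected.
#' @param state `"loss"` or `"gain"`.
#' @param min_support Minimum number of supporting samples (default 3).
#' @param cytobands Optional cytoband map for span labels.
#' @return `data.frame` of class `RecurrentRegion` rows: `chromosome`,
#'   `start`, `end`, `state`, `group`, `support`, `samples`, `cytoband`.
#' @export
recurrent_regions <- function(segments_list, groups, target_group, state,
                              min_support = 3, cytobands = NULL) {
  segs <- do.call(rbind, lapply(segments_list, as.data.frame))
  members <- group_samples(groups, target_group)
  if (min_support > length(members))
    stop("min_support exceeds the size of group ", target_group)
  segs <- segs[segs$sample_id %in% members & segs$state == state, , drop = FALSE]
  out <- list()
  for (chr in unique(segs$chromosome)) {
    sc <- segs[segs$chromosome == chr, , drop = FALSE]
    bp <- sort(unique(c(sc$start, sc$end + 1)))
    if (length(bp) < 2L) next
    starts <- bp[-length(bp)]
    ends <- bp[-1L] - 1
    ids_all <- sort(unique(sc$sample_id))
    # per-sample coverage of each elementary interval (a sample may tile a
    # region with several abutting segments)
    cov <- vapply(seq_along(starts), function(i)
      vapply(ids_all, function(s)
        any(sc$sample_id == s & sc$start <= starts[i] & sc$end >= ends[i]),
        logical(1)),
      logical(length(ids_all)))
    cov <- matrix(cov, nrow = length(ids_all), dimnames = list(ids_all, NULL))
    count <- colSums(cov)
    keep <- count >= min_support
    r <- rle(keep)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (!r$values[i]) next
      rs <- starts[lo[i]]
      re <- ends[hi[i]]
      ids <- ids_all[rowSums(cov[, lo[i]:hi[i], drop = FALSE]) ==
                       hi[i] - lo[i] + 1L]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chr, start = rs, end = re, state = state,
        group = target_group, support = length(ids),
        samples = paste(ids, collapse = ","),
        cytoband = if (is.null(cytobands)) NA_character_ else
          cytoband_span(chr, rs, re, cytobands),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    res <- data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), state = character(), group = character(),
                      support = integer(), samples = character(),
                      cytoband = character(), stringsAsFactors = FALSE)
  else {
    res <- do.call(rbind, out)
    res <- res[order(res$chromosome, res$start), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("RecurrentRegion", "data.frame")
  res
}

#' Annotated features overlapping a region
#'
#' Overlap of at least 1 bp (not containment) qualifies, split by feature
#' class and sorted by start.
#'
#' @param region List or one-row `data.frame` with `chromosome`, `start`,
#'   `end`.
#' @param annot A [genome_annotation()].
#' @return List with `genes` and `mirnas` (`data.frame`s of annotation rows).
#' @export
features_in_region <- function(region, annot) {
  rec <- annot$records
  hit <- rec$chromosome == region$chromosome &
    rec$start <= region$end & rec$end >= region$start
  rec <- rec[hit, , drop = FALSE]
  rec <- rec[order(rec$start), , drop = FALSE]
  list(genes = rec[rec$feature_class == "gene", , drop = FALSE],
       mirnas = rec[rec$feature_class == "mirna", , drop = FALSE])
}

#' Integrate recurrent copy-number regions with expression signatures
#'
#' For each region lost in group G, intersects the genes inside it with the
#' opposite group's up-signature (the dosage-consistent direction: fewer
#' copies in G, relatively more transcript in the other group). Genes inside
#' the region that are instead up in the deleted group are reported
#' separately.
#'
#' @param regions A `RecurrentRegion` data frame (loss state).
#' @param mrna_sigs List of two mRNA `SignatureSet`s.
#' @param annot A [genome_annotation()].
#' @return `data.frame` with one row per region: `chromosome`, `start`, `end`,
#'   `group`, `n_consistent`, `consistent_genes`, `n_inconsistent`,
#'   `inconsistent_genes`.
#' @export
integrate_cnv_expression <- function(regions, mrna_sigs, annot) {
  grps <- vapply(mrna_sigs, function(s) s$group, character(1))
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, ]
    genes <- features_in_region(reg, annot)$genes$symbol
    opp <- setdiff(grps, reg$group)
    opp_sig <- toupper(signature_features(mrna_sigs[[which(grps == opp)]]))
    same_sig <- toupper(signature_features(mrna_sigs[[which(grps == reg$group)]]))
    cons <- sort(intersect(genes, opp_sig))
    incons <- sort(intersect(genes, same_sig))
    data.frame(chromosome = reg$chromosome, start = reg$start, end = reg$end,
               group = reg$group, n_consistent = length(cons),
               consistent_genes = paste(cons, collapse = ","),
               n_inconsistent = length(incons),
               inconsistent_genes = paste(incons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(chromosome = character(), start = numeric(), end = numeric(),
                      group = character(), n_consistent = integer(),
                      consistent_genes = character(), n_inconsistent = integer(),
                      inconsistent_genes = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
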