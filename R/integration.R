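#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with fixed margins; the two-sided p-value sums,
#' over all admissible tables, the point probabilities not larger than that of
#' the observed table (minimum-likelihood convention). Any zero margin is
#' degenerate and returns p = 1 with a warning.
#'
#' @param a,b,c,d Nonnegative counts: `a` = query-and-set overlap, `b` =
#'   query only, `c` = set only, `d` = remainder of the universe.
#' @param alternative `"two.sided"` (default) or `"greater"` (right tail,
#'   directional enrichment).
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be nonnegative integers")
  m1 <- a + b; m2 <- c + d; n1 <- a + c; n2 <- b + d
  if (m1 == 0L || m2 == 0L || n1 == 0L || n2 == 0L) {
    warning("degenerate 2x2 table (zero margin); p = 1")
    return(1)
  }
  xs <- max(0L, n1 - m2):min(n1, m1)
  probs <- stats::dhyper(xs, m1, m2, n1)
  pobs <- stats::dhyper(a, m1, m2, n1)
  p <- if (alternative == "two.sided")
    sum(probs[probs <= pobs * (1 + 1e-7)])
  else
    sum(probs[xs >= a])
  min(max(p, .Machine$double.xmin), 1)
}

#' Per-miRNA Fisher enrichment of a signature in predicted targets
#'
#' Builds the 2x2 table (signature membership x predicted-target membership)
#' over a gene universe and applies [fisher_exact_2x2()]. The default universe
#' is the full set of genes measured on the mRNA platform.
#'
#' @param mirna miRNA id.
#' @param sig_genes Gene symbols of the opposite group's mRNA signature.
#' @param preds A [target_prediction_map()].
#' @param universe Character vector of all gene symbols under consideration.
#' @param alternative Passed to [fisher_exact_2x2()].
#' @return p-value, or `NA` if the miRNA has no prediction entry.
#' @export
mirna_enrichment <- function(mirna, sig_genes, preds, universe,
                             alternative = "two.sided") {
  if (!mirna %in% names(preds)) return(NA_real_)
  universe <- unique(toupper(universe))
  sig <- unique(toupper(sig_genes))
  targets <- preds[[mirna]]
  if (!all(sig %in% universe) || !all(targets %in% universe))
    stop("universe smaller than the union of signature and target sets")
  a <- length(intersect(sig, targets))
  b <- length(setdiff(sig, targets))
  c <- length(setdiff(targets, sig))
  d <- length(universe) - a - b - c
  fisher_exact_2x2(a, b, c, d, alternative = alternative)
}

#' Anti-correlated miRNA-target pairs across prognostic groups
#'
#' For each signature miRNA up in group G, emits one pair per predicted target
#' present in the opposite group's mRNA signature (the inverse-expression
#' structure: an abundant miRNA and a repressed target in the same tumors).
#' miRNAs without a prediction entry are skipped with a message. Each miRNA's
#' target-set enrichment p (over `universe`) is attached to its pairs.
#'
#' @param mirna_sigs List of two miRNA `SignatureSet`s (from
#'   [mirna_signatures()]).
#' @param mrna_sigs List of two mRNA `SignatureSet`s (from
#'   [mrna_signatures()]); feature ids are treated as gene symbols.
#' @param preds A [target_prediction_map()].
#' @param universe Gene universe for the per-miRNA Fisher test; `NULL` skips
#'   the test (fisher_p = NA).
#' @param alternative Passed to [fisher_exact_2x2()].
#' @return `data.frame` with columns `mirna`, `target`, `mirna_up_group`,
#'   `target_up_group`, `fisher_p`, ordered by (mirna, target).
#' @export
anti_correlated_pairs <- function(mirna_sigs, mrna_sigs, preds,
                                  universe = NULL,
                                  alternative = "two.sided") {
  grps <- vapply(mirna_sigs, function(s) s$group, character(1))
  mgrps <- vapply(mrna_sigs, function(s) s$group, character(1))
  rows <- list()
  for (s in mirna_sigs) {
    opp <- setdiff(grps, s$group)
    if (length(opp) != 1L) stop("expected exactly two groups")
    opp_sig <- mrna_sigs[[which(mgrps == opp)]]
    opp_genes <- toupper(signature_features(opp_sig))
    for (mir in signature_features(s)) {
      if (!mir %in% names(preds)) {
        message("anti_correlated_pairs: no prediction entry for ", mir, "; skipped")
        next
      }
      hits <- intersect(preds[[mir]], opp_genes)
      if (length(hits) == 0L) next
      fp <- if (is.null(universe)) NA_real_ else
        mirna_enrichment(mir, opp_genes, preds, universe, alternative)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = mir, target = sort(hits), mirna_up_group = s$group,
        target_up_group = opp, fisher_p = fp, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(mirna = character(), target = character(),
                      mirna_up_group = character(), target_up_group = character(),
                      fisher_p = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multi-targeted mRNAs and miRNA pairs sharing targets
#'
#' Summarizes an anti-correlated pair list: how many distinct signature miRNAs
#' target each gene, and which miRNA pairs share a common target.
#'
#' @param pairs Output of [anti_correlated_pairs()].
#' @return List with `targets` (`data.frame`: `gene`, `n_mirnas`, `mirnas`)
#'   sorted by decreasing count, and `mirna_pairs` (`data.frame`: `mirna_a`,
#'   `mirna_b`, `shared_targets`, `n_shared`).
#' @export
multi_target_summary <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(list(targets = data.frame(gene = character(), n_mirnas = integer(),
                                     mirnas = character(), stringsAsFactors = FALSE),
                mirna_pairs = data.frame(mirna_a = character(), mirna_b = character(),
                                         shared_targets = character(),
                                         n_shared = integer(), stringsAsFactors = FALSE)))
  by_gene <- split(pairs$mirna, pairs$target)
  by_gene <- lapply(by_gene, function(m) sort(unique(m)))
  targets <- data.frame(gene = names(by_gene),
                        n_mirnas = lengths(by_gene),
                        mirnas = vapply(by_gene, paste, character(1), collapse = ","),
                        row.names = NULL, stringsAsFactors = FALSE)
  targets <- targets[order(-targets$n_mirnas, targets$gene), , drop = FALSE]
  rownames(targets) <- NULL
  by_mir <- split(pairs$target, pairs$mirna)
  mirs <- sort(names(by_mir))
  prs <- list()
  if (length(mirs) >= 2L) {
    for (i in seq_len(length(mirs) - 1L)) for (j in (i + 1L):length(mirs)) {
      shared <- intersect(by_mir[[mirs[i]]], by_mir[[mirs[j]]])
      if (length(shared))
        prs[[length(prs) + 1L]] <- data.frame(
          mirna_a = mirs[i], mirna_b = mirs[j],
          shared_targets = paste(sort(shared), collapse = ","),
          n_shared = length(shared), stringsAsFactors = FALSE)
    }
  }
  mirna_pairs <- if (length(prs)) do.call(rbind, prs) else
    data.frame(mirna_a = character(), mirna_b = character(),
               shared_targets = character(), n_shared = integer(),
               stringsAsFactors = FALSE)
  list(targets = targets, mirna_pairs = mirna_pairs)
}

#' Intragenic miRNA host assignment
#'
#' A miRNA is intragenic iff its interval is fully contained in a gene
#' interval on the same chromosome (strand ignored); when several genes
#' contain it, the smallest containing gene wins.
#'
#' @param annot A [genome_annotation()] holding both `mirna` and `gene`
#'   records.
#' @return `data.frame` with columns `mirna` (feature id) and `host_gene`
#'   (symbol, or `NA` if intergenic).
#' @export
annotate_intragenic <- function(annot) {
  rec <- annot$records
  mirs <- rec[rec$feature_class == "mirna", , drop = FALSE]
  genes <- rec[rec$feature_class == "gene", , drop = FALSE]
  host <- vapply(seq_len(nrow(mirs)), function(i) {
    g <- genes[genes$chromosome == mirs$chromosome[i] &
                 genes$start <= mirs$start[i] &
                 genes$end >= mirs$end[i], , drop = FALSE]
    if (nrow(g) == 0L) return(NA_character_)
    g <- g[order(g$end - g$start, g$start), , drop = FALSE]
    g$symbol[1L]
  }, character(1))
  data.frame(mirna = mirs$feature_id, host_gene = host,
             row.names = NULL, stringsAsFactors = FALSE)
}
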