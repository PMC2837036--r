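#' Hypergeometric over-representation of one gene set
#'
#' Right-tail hypergeometric test: with a universe of `N` genes, `K` of them
#' in the set (after intersecting the set with the universe) and a query of
#' `n` genes of which `k` fall in the set, `p = P(X >= k)`,
#' `X ~ Hypergeom(N, K, n)`.
#'
#' @param query Query gene symbols (must all be in `universe`).
#' @param set_genes Gene symbols of the set.
#' @param universe All gene symbols under consideration.
#' @param set_id,description Carried into the result row.
#' @return One-row `data.frame`: `set_id`, `description`, `k`, `n`, `K`, `N`,
#'   `p`, `overlap` (comma-joined symbols).
#' @export
overrepresentation <- function(query, set_genes, universe,
                               set_id = NA_character_,
                               description = NA_character_) {
  universe <- unique(toupper(universe))
  query <- unique(toupper(query))
  offenders <- setdiff(query, universe)
  if (length(offenders))
    stop("query genes outside the universe: ", paste(offenders, collapse = ", "))
  set_genes <- intersect(unique(toupper(set_genes)), universe)
  hits <- intersect(query, set_genes)
  k <- length(hits); n <- length(query); K <- length(set_genes); N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(set_id = set_id, description = description, k = k, n = n, K = K,
             N = N, p = min(max(p, .Machine$double.xmin), 1),
             overlap = paste(sort(hits), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Over-representation across a gene-set collection
#'
#' Tests every set in the collection, sorts by raw p and adds
#' Benjamini-Hochberg adjusted p-values alongside (raw p mirrors the
#' conventional p < 0.05 reporting of web ORA tools; the BH column is what
#' modern practice filters on).
#'
#' @param query Query gene symbols.
#' @param collection A [gene_set_collection()].
#' @param universe All gene symbols under consideration.
#' @param alpha Significance annotation threshold on raw p (default 0.05).
#' @return `data.frame` of per-set results sorted by `p`, with `p_adj` and
#'   `significant` columns.
#' @export
enrich_collection <- function(query, collection, universe, alpha = 0.05) {
  if (length(query) == 0L) stop("empty query")
  rows <- lapply(names(collection), function(id)
    overrepresentation(query, collection[[id]]$genes, universe,
                       set_id = id, description = collection[[id]]$description))
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Positional (cytoband) gene sets from an annotation
#'
#' One gene set per cytoband, with each gene assigned by the band containing
#' its interval midpoint (so every gene lands in exactly one band and
#' boundary-spanning genes are not double counted). Bands without genes are
#' dropped (gene sets must be non-empty).
#'
#' @param annot A [genome_annotation()] with cytobands.
#' @return A [gene_set_collection()] keyed by span label (e.g. `"4q13.3"`).
#' @export
cytoband_sets <- function(annot) {
  if (is.null(annot$cytobands)) stop("annotation carries no cytobands")
  genes <- annot$records[annot$records$feature_class == "gene", , drop = FALSE]
  mid <- floor((genes$start + genes$end) / 2)
  lab <- vapply(seq_len(nrow(genes)), function(i) {
    b <- band_label(genes$chromosome[i], mid[i], annot$cytobands)
    if (is.na(b)) NA_character_ else paste0(sub("^chr", "", genes$chromosome[i]), b)
  }, character(1))
  keep <- !is.na(lab)
  sets <- lapply(split(genes$symbol[keep], lab[keep]), function(g)
    list(description = "cytoband", genes = sort(unique(g))))
  gene_set_collection(sets)
}
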