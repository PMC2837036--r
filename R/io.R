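#' Construct a validated expression matrix
#'
#' The shared container for both the mRNA and the miRNA branches of the
#' pipeline: a log2 feature-by-sample matrix with unique feature and sample
#' identifiers and no non-finite values.
#'
#' @param values Numeric matrix of log2 expression, features in rows, samples
#'   in columns; `rownames` are feature ids, `colnames` sample ids.
#' @param feature_kind `"mrna_probe"` or `"mirna"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `feature_kind`.
#' @export
expression_matrix <- function(values, feature_kind = c("mrna_probe", "mirna")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite after missing-value handling")
  structure(list(values = values, feature_kind = feature_kind),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix (%s): %d features x %d samples\n",
              x$feature_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample ids and one row per feature with the feature
#' id in the first column. Features with more than 50\% missing values are
#' dropped; remaining missing cells are imputed by the feature median of the
#' observed values (observed values are never altered). Dropped/imputed counts
#' are reported with a message.
#'
#' @param path Path to the TSV file.
#' @param feature_kind `"mrna_probe"` or `"mirna"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, feature_kind = c("mrna_probe", "mirna")) {
  feature_kind <- match.arg(feature_kind)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (ncol(tab) < 2) stop("expression TSV needs a feature-id column plus >=1 sample")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(!is.na(vals[[j]]) & is.na(suppressWarnings(as.numeric(vals[[j]]))))
      if (length(bad))
        stop(sprintf("non-numeric cell at feature '%s', sample '%s'",
                     ids[bad[1L]], names(vals)[j]))
      vals[[j]] <- as.numeric(vals[[j]])
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  miss_frac <- rowMeans(is.na(m))
  drop <- miss_frac > 0.5
  if (any(drop)) m <- m[!drop, , drop = FALSE]
  n_imputed <- 0L
  if (anyNA(m)) {
    for (i in which(rowSums(is.na(m)) > 0L)) {
      na <- is.na(m[i, ])
      m[i, na] <- stats::median(m[i, !na])
      n_imputed <- n_imputed + sum(na)
    }
  }
  message(sprintf("read_expression_matrix: %d features dropped (>50%% missing), %d cells imputed",
                  sum(drop), n_imputed))
  expression_matrix(m, feature_kind)
}

#' Construct sample group assignments
#'
#' @param assignments Named character vector mapping sample id to one of the
#'   prognostic group labels `GPG`, `IPG_PPG`, `ESC`, `MT`, `other`.
#' @return Named character vector of class `SampleGroups`.
#' @export
sample_groups <- function(assignments) {
  if (is.null(names(assignments)) || any(names(assignments) == ""))
    stop("assignments must be a fully named character vector (sample id -> group)")
  if (anyDuplicated(names(assignments)))
    stop("each sample must have exactly one group label")
  allowed <- c("GPG", "IPG_PPG", "ESC", "MT", "other")
  bad <- setdiff(unique(assignments), allowed)
  if (length(bad))
    stop("unknown group labels: ", paste(bad, collapse = ", "))
  structure(as.character(stats::setNames(assignments, names(assignments))),
            names = names(assignments), class = "SampleGroups")
}

group_samples <- function(groups, label) names(groups)[unclass(groups) == label]

#' Percentage composition of a clinical series
#'
#' Turns per-subtype case counts into the percentages a clinical series table
#' reports (rounded to one decimal).
#'
#' @param counts Named integer vector of case counts per subtype/group.
#' @return `data.frame` with columns `group`, `n`, `percent`.
#' @export
series_composition <- function(counts) {
  if (is.null(names(counts)) || any(counts < 0) || sum(counts) == 0)
    stop("`counts` must be a named nonnegative vector with a positive total")
  data.frame(group = names(counts), n = as.integer(counts),
             percent = round(100 * counts / sum(counts), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct a genome annotation
#'
#' Coordinates are 1-based inclusive throughout the package. Cytobands must
#' tile each chromosome contiguously without overlap with band labels unique
#' per chromosome.
#'
#' @param records `data.frame` with columns `feature_id`, `symbol`,
#'   `chromosome`, `start`, `end`, `strand`, `feature_class`
#'   (`"gene"`/`"mirna"`).
#' @param cytobands Optional `data.frame` with columns `chromosome`, `start`,
#'   `end`, `band`.
#' @return Object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(records, cytobands = NULL) {
  need <- c("feature_id", "symbol", "chromosome", "start", "end", "strand", "feature_class")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (any(records$start > records$end))
    stop("annotation has start > end for: ",
         paste(records$feature_id[records$start > records$end], collapse = ", "))
  records$symbol <- toupper(records$symbol)
  if (!is.null(cytobands)) {
    needb <- c("chromosome", "start", "end", "band")
    if (!all(needb %in% names(cytobands)))
      stop("cytobands must have columns: ", paste(needb, collapse = ", "))
    for (chr in unique(cytobands$chromosome)) {
      b <- cytobands[cytobands$chromosome == chr, ]
      b <- b[order(b$start), ]
      if (anyDuplicated(b$band)) stop("cytoband labels must be unique per chromosome")
      if (any(b$start > b$end)) stop("cytoband with start > end on ", chr)
      if (nrow(b) > 1 && any(b$start[-1L] != b$end[-nrow(b)] + 1L))
        stop("cytobands must tile ", chr, " contiguously without overlap")
    }
  }
  structure(list(records = records, cytobands = cytobands), class = "GenomeAnnotation")
}

#' Read a genome annotation table
#'
#' Accepts either 0-based half-open BED-style coordinates (`coords = "bed0"`,
#' converted on read) or 1-based inclusive coordinates (`coords = "one"`).
#' Stored coordinates are always 1-based inclusive.
#'
#' @param path TSV with header columns `feature_id`, `symbol`, `chromosome`,
#'   `start`, `end`, `strand`, `feature_class`.
#' @param coords Coordinate dialect of the input file.
#' @param cytobands_path Optional TSV with header columns `chromosome`,
#'   `start`, `end`, `band` (same dialect as `coords`).
#' @return A [genome_annotation()].
#' @export
read_genome_annotation <- function(path, coords = c("one", "bed0"),
                                   cytobands_path = NULL) {
  coords <- match.arg(coords)
  rec <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (coords == "bed0") rec$start <- rec$start + 1L
  bands <- NULL
  if (!is.null(cytobands_path)) {
    bands <- utils::read.delim(cytobands_path, header = TRUE, stringsAsFactors = FALSE)
    if (coords == "bed0") bands$start <- bands$start + 1L
  }
  genome_annotation(rec, bands)
}

#' Convert stored 1-based inclusive intervals back to BED coordinates
#'
#' Inverse of the `bed0` read conversion (an involution together with it).
#'
#' @param start,end 1-based inclusive coordinates.
#' @return `data.frame` with 0-based half-open `start`, `end`.
#' @export
to_bed0 <- function(start, end) data.frame(start = start - 1L, end = end)

#' Read miRNA target predictions
#'
#' Two-column TSV (miRNA id, gene symbol), one predicted pair per line, no
#' header. Duplicate pairs are collapsed; gene symbols are uppercased.
#'
#' @param path Path to the TSV file.
#' @return Named list of class `TargetPredictionMap`: miRNA id -> character
#'   vector of predicted target symbols.
#' @export
read_target_predictions <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("empty or unreadable prediction file: ", path))
  if (nrow(tab) == 0L) stop("empty prediction file: ", path)
  target_prediction_map(tab[[1L]], tab[[2L]])
}

#' Build a target prediction map from paired vectors
#'
#' @param mirna,gene Equal-length vectors of miRNA ids and predicted target
#'   gene symbols.
#' @return Named list of class `TargetPredictionMap`.
#' @export
target_prediction_map <- function(mirna, gene) {
  stopifnot(length(mirna) == length(gene), length(mirna) > 0L)
  preds <- lapply(split(toupper(as.character(gene)), as.character(mirna)),
                  function(g) sort(unique(g)))
  if (any(lengths(preds) == 0L)) stop("every stored miRNA needs a non-empty target set")
  structure(preds, class = "TargetPredictionMap")
}

#' Construct a per-sample SNP-array probe track
#'
#' Probes are sorted by (chromosome, position, probe id); duplicate positions
#' are kept in stable probe-id order.
#'
#' @param sample_id Sample identifier.
#' @param probes `data.frame` with columns `probe_id`, `chromosome`,
#'   `position`, `lrr` (log-R ratio), `baf` (B-allele frequency in \[0,1\]).
#' @return Object of class `SnpArraySample`.
#' @export
snp_array_sample <- function(sample_id, probes) {
  need <- c("probe_id", "chromosome", "position", "lrr", "baf")
  if (!all(need %in% names(probes)))
    stop("probes must have columns: ", paste(need, collapse = ", "))
  if (any(probes$baf < 0 | probes$baf > 1))
    stop("baf outside [0,1] for sample ", sample_id)
  if (!all(is.finite(probes$lrr)))
    stop("non-finite lrr for sample ", sample_id)
  o <- order(probes$chromosome, probes$position, probes$probe_id)
  probes <- probes[o, , drop = FALSE]
  rownames(probes) <- NULL
  structure(list(sample_id = sample_id, probes = probes), class = "SnpArraySample")
}

#' Read a SNP-array probe table
#'
#' @param path TSV with header columns `probe_id`, `chromosome`, `position`,
#'   `lrr`, `baf`; any row order.
#' @param sample_id Sample id to attach; defaults to the file base name.
#' @return A [snp_array_sample()].
#' @export
read_snp_array <- function(path, sample_id = sub("\\.[^.]*$", "", basename(path))) {
  probes <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  snp_array_sample(sample_id, probes)
}

#' Construct a survival table
#'
#' @param records `data.frame` with columns `sample_id`, `time` (years, >= 0),
#'   `event` (1 death, 0 censored), `group`.
#' @return `data.frame` of class `SurvivalTable`.
#' @export
survival_table <- function(records) {
  need <- c("sample_id", "time", "event", "group")
  if (!all(need %in% names(records)))
    stop("survival records must have columns: ", paste(need, collapse = ", "))
  if (any(records$time < 0)) stop("survival time must be >= 0")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
  records <- records[, need]
  class(records) <- c("SurvivalTable", "data.frame")
  records
}

#' Read survival records from CSV
#'
#' @param path CSV with header columns `sample_id` (or `sample`), `time` (or
#'   `time_years`), `event`, `group`.
#' @return A [survival_table()].
#' @export
read_survival <- function(path) {
  tab <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if ("sample" %in% names(tab) && !"sample_id" %in% names(tab))
    names(tab)[names(tab) == "sample"] <- "sample_id"
  if ("time_years" %in% names(tab) && !"time" %in% names(tab))
    names(tab)[names(tab) == "time_years"] <- "time"
  survival_table(tab)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated `set_id`,
#' `description`, then member gene symbols (uppercased on read).
#'
#' @param path Path to the GMT file.
#' @return Object of class `GeneSetCollection`: named list of
#'   `list(description, genes)`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line (<3 fields): ", substr(ln, 1, 60))
    sets[[f[1L]]] <- list(description = f[2L],
                          genes = sort(unique(toupper(f[-(1:2)]))))
  }
  gene_set_collection(sets)
}

#' Construct a gene-set collection
#'
#' @param sets Named list; each element `list(description, genes)`.
#' @return Object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("set ids must be unique and non-empty")
  if (any(vapply(sets, function(s) length(s$genes) == 0L, logical(1))))
    stop("every gene set must be non-empty")
  structure(sets, class = "GeneSetCollection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, sets[[id]]$description, sets[[id]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Numeric columns are serialized at full double precision (%.17g) so that all
# result tables round-trip losslessly through write_table()/read_table().
#' Write a result table as TSV (lossless for doubles)
#'
#' @param x `data.frame`.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) y[[j]] <- sprintf("%.17g", y[[j]])
  }
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
read_table <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an expression matrix as TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(feature = feature_ids(x),
                   apply(x$values, 2, function(v) sprintf("%.17g", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("feature", sample_ids(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
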