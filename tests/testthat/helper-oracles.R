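# Independent oracles used across test files. All deliberately brute-force
# and written against the definitions, not against the package code paths.

# quick ExpressionMatrix from a plain matrix
em <- function(values, kind = "mrna_probe") {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  expression_matrix(values, kind)
}

# two-sided Fisher p by direct enumeration with log-binomial coefficients
oracle_fisher_two_sided <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c; N <- a + b + c + d
  xs <- max(0, n1 - m2):min(n1, m1)
  logp <- lchoose(m1, xs) + lchoose(m2, n1 - xs) - lchoose(N, n1)
  probs <- exp(logp)
  pobs <- exp(lchoose(m1, a) + lchoose(m2, n1 - a) - lchoose(N, n1))
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# max |implementation - enumeration| over every non-degenerate 2x2 table
# with grand total <= max_total
fisher_sweep_maxdiff <- function(max_total) {
  worst <- 0
  for (total in 2:max_total) {
    for (m1 in 0:total) {
      n2 <- total - m1
      for (a in 0:m1) {
        b <- m1 - a
        for (c_ in 0:n2) {
          d <- n2 - c_
          if (m1 == 0 || n2 == 0 || (a + c_) == 0 || (b + d) == 0) next
          diff <- abs(fisher_exact_2x2(a, b, c_, d) -
                        oracle_fisher_two_sided(a, b, c_, d))
          if (diff > worst) worst <- diff
        }
      }
    }
  }
  worst
}

# per-base recurrent-region counter over a small coordinate space
oracle_recurrent_per_base <- function(segs, members, state, min_support, max_pos) {
  segs <- segs[segs$sample_id %in% members & segs$state == state, , drop = FALSE]
  out <- list()
  for (chr in unique(segs$chromosome)) {
    sc <- segs[segs$chromosome == chr, , drop = FALSE]
    cov <- matrix(FALSE, nrow = length(unique(sc$sample_id)), ncol = max_pos,
                  dimnames = list(unique(sc$sample_id), NULL))
    for (i in seq_len(nrow(sc)))
      cov[sc$sample_id[i], sc$start[i]:sc$end[i]] <- TRUE
    count <- colSums(cov)
    keep <- count >= min_support
    r <- rle(keep)
    hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (!r$values[i]) next
      ids <- sort(rownames(cov)[apply(cov[, lo[i]:hi[i], drop = FALSE], 1, all)])
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chr, start = lo[i], end = hi[i], state = state,
        support = length(ids), samples = paste(ids, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$chromosome, res$start), , drop = FALSE]
}

# stepwise UPGMA recomputing average linkage at every merge
oracle_upgma_heights <- function(x) {
  # x: samples in columns
  clusters <- as.list(seq_len(ncol(x)))
  d <- as.matrix(dist(t(x)))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1L)) for (j in (i + 1L):length(clusters)) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    merges[[length(merges) + 1L]] <- sort(unlist(clusters[best]))
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# hand log-rank statistic (observed - expected with hypergeometric variance)
oracle_logrank_chisq <- function(time, event, grp) {
  tms <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tt in tms) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & grp == levels(factor(grp))[1L])
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & grp == levels(factor(grp))[1L])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# mean silhouette width on 1-d coordinates with two known groups
silhouette_1d <- function(coord, grp) {
  s <- vapply(seq_along(coord), function(i) {
    same <- grp == grp[i]; same[i] <- FALSE
    a <- mean(abs(coord[i] - coord[same]))
    b <- mean(abs(coord[i] - coord[!same]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
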