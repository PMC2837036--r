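#' Pooled-variance two-sample Student's t per feature
#'
#' The miRNA-branch test: a classical two-sided Student's t with pooled
#' variance on `n_a + n_b - 2` degrees of freedom, computed row-wise over the
#' log2 matrix. Features with zero pooled variance get `t = 0, p = 1` when the
#' group means are equal; when the means differ the p-value is set to the
#' machine minimum and the feature is flagged (`zero_variance`).
#'
#' @param mat An [expression_matrix()].
#' @param groups A [sample_groups()] covering the matrix samples.
#' @param a,b Group labels to compare (difference is `mean(a) - mean(b)`).
#' @return `data.frame` with columns `feature`, `mean_a`, `mean_b`, `delta`,
#'   `t`, `df`, `p`, `zero_variance`.
#' @export
student_t <- function(mat, groups, a, b) {
  sa <- intersect(sample_ids(mat), group_samples(groups, a))
  sb <- intersect(sample_ids(mat), group_samples(groups, b))
  if (length(sa) < 2L || length(sb) < 2L)
    stop("both groups need >= 2 samples in the matrix (", a, ": ", length(sa),
         ", ", b, ": ", length(sb), ")")
  xa <- mat$values[, sa, drop = FALSE]
  xb <- mat$values[, sb, drop = FALSE]
  na <- length(sa); nb <- length(sb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  df <- na + nb - 2L
  ss <- rowSums((xa - ma)^2) + rowSums((xb - mb)^2)
  s2 <- ss / df
  se <- sqrt(s2 * (1 / na + 1 / nb))
  delta <- ma - mb
  t <- ifelse(se > 0, delta / se, 0)
  p <- 2 * stats::pt(-abs(t), df)
  zero_var <- s2 <= 0
  deg <- zero_var & delta != 0
  if (any(deg)) {
    p[deg] <- .Machine$double.xmin
    t[deg] <- sign(delta[deg]) * Inf
  }
  p[zero_var & delta == 0] <- 1
  data.frame(feature = feature_ids(mat), mean_a = ma, mean_b = mb,
             delta = delta, t = t, df = df, p = p, zero_variance = zero_var,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-feature fold change between two groups
#'
#' Fold change is computed on the log2 group means (a geometric-mean ratio):
#' `FC = 2^|delta|` with `delta = mean_log2(a) - mean_log2(b)`; the direction
#' is the sign of `delta`.
#'
#' @inheritParams student_t
#' @return `data.frame` with columns `feature`, `delta`, `fc`, `direction`
#'   (`up_in_A` / `up_in_B`).
#' @export
fold_change <- function(mat, groups, a, b) {
  sa <- intersect(sample_ids(mat), group_samples(groups, a))
  sb <- intersect(sample_ids(mat), group_samples(groups, b))
  if (length(sa) < 1L || length(sb) < 1L) stop("both groups must be non-empty")
  delta <- rowMeans(mat$values[, sa, drop = FALSE]) -
    rowMeans(mat$values[, sb, drop = FALSE])
  data.frame(feature = feature_ids(mat), delta = delta, fc = 2^abs(delta),
             direction = ifelse(delta >= 0, "up_in_A", "up_in_B"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct a signature set
#'
#' A direction-tagged set of differentially expressed features for one group,
#' with the per-feature statistics and the thresholds that defined membership.
#' Usually produced by [mirna_signatures()] / [mrna_signatures()]; the
#' constructor is exported so externally derived signature lists can enter the
#' integration stages.
#'
#' @param group Group label the features are up in.
#' @param table Per-feature `data.frame`; must contain a `feature` column.
#' @param thresholds Named list of the thresholds used.
#' @return Object of class `SignatureSet`.
#' @export
signature_set <- function(group, table, thresholds = list()) {
  stopifnot("feature" %in% names(table))
  structure(list(group = group, table = table, thresholds = thresholds),
            class = "SignatureSet")
}

#' @export
print.SignatureSet <- function(x, ...) {
  cat(sprintf("SignatureSet: %d features up in %s\n", nrow(x$table), x$group))
  invisible(x)
}

#' Feature ids of a signature set
#' @param x A `SignatureSet`.
#' @return Character vector of member feature ids.
#' @export
signature_features <- function(x) x$table$feature

#' miRNA signatures: Student's t plus fold-change filter
#'
#' Features with two-sided `p < alpha` and fold change `>= min_fc` are
#' partitioned by direction into one signature per group. No multiplicity
#' correction is applied on this branch.
#'
#' @inheritParams student_t
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @param min_fc Minimum fold change on the log2-mean scale (default 2).
#' @return List with `SignatureSet` elements named by `a` and `b`.
#' @export
mirna_signatures <- function(mat, groups, a = "GPG", b = "IPG_PPG",
                             alpha = 0.05, min_fc = 2) {
  tt <- student_t(mat, groups, a, b)
  fc <- fold_change(mat, groups, a, b)
  tab <- cbind(tt, fc = fc$fc, direction = fc$direction,
               stringsAsFactors = FALSE)
  tab$passes <- tab$p < alpha & tab$fc >= min_fc
  thr <- list(alpha = alpha, min_fc = min_fc)
  out <- list(
    signature_set(a, tab[tab$passes & tab$direction == "up_in_A", , drop = FALSE], thr),
    signature_set(b, tab[tab$passes & tab$direction == "up_in_B", , drop = FALSE], thr))
  names(out) <- c(a, b)
  attr(out, "full_table") <- tab
  out
}

# Newton inversion of the trigamma function (for the method-of-moments
# hyperparameter fit); monotone decreasing, so the iteration is safe.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    y <- 0.5 + 1 / xi
    for (i in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) < 1e-10 * y) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderated t per feature
#'
#' Shrinks each feature's pooled residual variance toward an ensemble prior
#' estimated across all features, then forms a t statistic on augmented
#' degrees of freedom. The prior `(d0, s0^2)` is fitted by method of moments
#' on `log(s^2)` using digamma/trigamma relations; the posterior variance is
#' `s2_post = (d0*s0^2 + d*s^2) / (d0 + d)` and `t = delta / sqrt(s2_post *
#' (1/n_a + 1/n_b))`, two-sided p on `d0 + d` df. An infinite fitted `d0`
#' collapses every posterior variance to `s0^2`. Features with zero pooled
#' variance are excluded from the hyperparameter fit (and flagged) but still
#' receive a shrunken variance.
#'
#' @inheritParams student_t
#' @param d0,s02 Optional hyperparameter overrides (e.g. `d0 = 0` turns the
#'   shrinkage off and reproduces the ordinary pooled t exactly).
#' @return `data.frame` with columns `feature`, `mean_a`, `mean_b`, `delta`,
#'   `s2`, `s2_post`, `t`, `df_total`, `p`, `zero_variance`; fitted
#'   hyperparameters in attributes `d0` and `s02`.
#' @export
moderated_t <- function(mat, groups, a, b, d0 = NULL, s02 = NULL) {
  sa <- intersect(sample_ids(mat), group_samples(groups, a))
  sb <- intersect(sample_ids(mat), group_samples(groups, b))
  if (length(sa) < 2L || length(sb) < 2L)
    stop("both groups need >= 2 samples")
  if (nrow(mat$values) < 10L && is.null(d0))
    stop("hyperparameter estimation needs >= 10 features")
  xa <- mat$values[, sa, drop = FALSE]
  xb <- mat$values[, sb, drop = FALSE]
  na <- length(sa); nb <- length(sb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  d <- na + nb - 2L
  s2 <- (rowSums((xa - ma)^2) + rowSums((xb - mb)^2)) / d
  ok <- s2 > 0
  if (is.null(d0) || is.null(s02)) {
    if (!any(ok)) stop("all features have zero pooled variance; hyperparameters undefined")
    # method of moments on z = log(s2): E z = log(s02) + digamma(d/2) - log(d/2)
    #                                        + log(d0/2) - digamma(d0/2) shifts
    z <- log(s2[ok])
    e <- z - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    n <- length(e)
    evar <- sum((e - emean)^2) / (n - 1L) - trigamma(d / 2)
    if (is.na(evar) || evar <= 0) {
      # no excess dispersion beyond chi-square sampling noise: infinite prior
      # df; the scale reduces to the mean observed variance
      fit_d0 <- Inf
      fit_s02 <- mean(s2[ok])
    } else {
      fit_d0 <- 2 * trigamma_inverse(evar)
      fit_s02 <- exp(emean + digamma(fit_d0 / 2) - log(fit_d0 / 2))
    }
    if (is.null(d0)) d0 <- fit_d0
    if (is.null(s02)) s02 <- fit_s02
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  delta <- ma - mb
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t <- ifelse(se > 0, delta / se, 0)
  df_total <- d0 + d
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t)) else
    2 * stats::pt(-abs(t), df_total)
  deg <- se == 0 & delta != 0
  if (any(deg)) { p[deg] <- .Machine$double.xmin; t[deg] <- sign(delta[deg]) * Inf }
  p[se == 0 & delta == 0] <- 1
  out <- data.frame(feature = feature_ids(mat), mean_a = ma, mean_b = mb,
                    delta = delta, s2 = s2, s2_post = s2_post, t = t,
                    df_total = df_total, p = p, zero_variance = !ok,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Storey positive-FDR q-values
#'
#' The simple fixed-lambda estimator: `pi0 = #\{p > lambda\} / ((1 - lambda)
#' m)` at `lambda = 0.5`, clipped to `[1/m, 1]`, followed by the step-up
#' `q_(i) = min_(j >= i) pi0 * m * p_(j) / j` on the sorted p-values; the
#' result is returned in input order and capped at 1.
#'
#' @param p Vector of p-values in (0, 1].
#' @param lambda Fixed tuning parameter for the null-proportion estimate.
#' @return Vector of q-values, same order as `p`.
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  m <- length(p)
  if (m == 0L) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  pi0 <- sum(p > lambda) / ((1 - lambda) * m)
  pi0 <- min(1, max(pi0, 1 / m))
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' mRNA signatures: moderated t with a positive-FDR threshold
#'
#' Runs [moderated_t()], converts p-values to Storey q-values and partitions
#' the features with `q < q_max` by direction into one signature per group.
#'
#' @inheritParams student_t
#' @param q_max q-value threshold (default 0.001).
#' @return List with `SignatureSet` elements named by `a` and `b`.
#' @export
mrna_signatures <- function(mat, groups, a = "GPG", b = "IPG_PPG", q_max = 0.001) {
  mt <- moderated_t(mat, groups, a, b)
  mt$q <- storey_qvalues(mt$p)
  mt$fc <- 2^abs(mt$delta)
  mt$direction <- ifelse(mt$delta >= 0, "up_in_A", "up_in_B")
  mt$passes <- mt$q < q_max
  thr <- list(q_max = q_max)
  out <- list(
    signature_set(a, mt[mt$passes & mt$direction == "up_in_A", , drop = FALSE], thr),
    signature_set(b, mt[mt$passes & mt$direction == "up_in_B", , drop = FALSE], thr))
  names(out) <- c(a, b)
  attr(out, "full_table") <- mt
  attr(out, "d0") <- attr(mt, "d0")
  attr(out, "s02") <- attr(mt, "s02")
  out
}

#' Write / read a signature table
#'
#' @param sig A `SignatureSet`.
#' @param path TSV path.
#' @export
write_signature_table <- function(sig, path) {
  write_table(sig$table, path)
}

#' @rdname write_signature_table
#' @param group Group label to attach on read.
#' @param thresholds Threshold list to attach on read.
#' @export
read_signature_table <- function(path, group, thresholds = list()) {
  signature_set(group, read_table(path), thresholds)
}
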