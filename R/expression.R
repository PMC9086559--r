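#' TMM scale factors
#'
#' Trimmed mean of M-values normalisation for between-sample composition
#' bias in count data. Each sample is compared to a reference sample (the
#' one whose upper-quartile of depth-scaled counts is closest to the mean
#' upper-quartile); per-feature log2 ratios (M) are trimmed symmetrically
#' by `trim_m`, per-feature mean log2 abundances (A) by `trim_a`, and the
#' surviving M values are averaged with inverse-variance (delta-method
#' binomial) weights. Factors are rescaled so their geometric mean is 1.
#' Features with a zero count in either the sample or the reference are
#' excluded before trimming.
#'
#' @param counts count `ExprMatrix` (lib_sizes optional; column sums are
#'   used when absent).
#' @param trim_m fraction of M values trimmed from each tail (default 0.30).
#' @param trim_a fraction of A values trimmed from each tail (default 0.05).
#' @return named numeric vector of per-sample scale factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  stopifnot_counts(counts)
  y <- counts$values
  if (ncol(y) < 2) stop("TMM needs at least 2 samples")
  if (any(colSums(y) == 0)) stop("all-zero sample: ",
                                 colnames(y)[colSums(y) == 0][1])
  N <- if (!is.null(counts$lib_sizes)) counts$lib_sizes else colSums(y)
  p <- sweep(y, 2, N, "/")                       # depth-scaled proportions
  uq <- apply(p, 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(y)), function(j) {
    if (j == ref) return(1)
    keep <- y[, j] > 0 & y[, ref] > 0
    if (!any(keep)) return(1)
    yj <- y[keep, j]; yr <- y[keep, ref]
    M <- log2((yj / N[j]) / (yr / N[ref]))
    A <- 0.5 * log2((yj / N[j]) * (yr / N[ref]))
    w <- 1 / ((N[j] - yj) / (N[j] * yj) + (N[ref] - yr) / (N[ref] * yr))
    if (max(abs(M)) < 1e-10) return(1)           # columns proportional
    loM <- stats::quantile(M, trim_m); hiM <- stats::quantile(M, 1 - trim_m)
    loA <- stats::quantile(A, trim_a); hiA <- stats::quantile(A, 1 - trim_a)
    keep2 <- M >= loM & M <= hiM & A >= loA & A <= hiA
    if (!any(keep2)) return(1)
    2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(y))
}

#' Two-group differential expression test for counts
#'
#' Per feature, counts are summed within each group and compared with an
#' exact conditional binomial test: conditional on the total, the group-A
#' sum is Binomial with success probability equal to group A's share of
#' the effective (TMM-scaled) sequencing depth. This is the Poisson-limit
#' analogue of the exact negative-binomial count test; the interface
#' leaves room for an NB test later. Two-sided p values double the smaller
#' tail (capped at 1). log2 fold-changes come from effective-depth
#' normalised group means with a pseudo-count of 0.5; BH adjustment is
#' applied across features.
#'
#' @param counts count `ExprMatrix`.
#' @param groups factor or vector with exactly two levels, one entry per
#'   sample; the fold-change is level2 vs level1 (second over first).
#' @param paired if `TRUE`, per-pair depth imbalances are removed by
#'   conditioning within pairs: samples must be ordered so that the i-th
#'   sample of group 1 is paired with the i-th of group 2, and the test
#'   statistic aggregates the within-pair binomial evidence.
#' @param normalize apply TMM factors to the effective depths (default TRUE).
#' @return data.frame with columns `feature_id`, `logFC`, `p`, `adj_p`,
#'   `direction` (`up`/`down`/`ns`, filled by [call_de()]).
#' @export
de_test <- function(counts, groups, paired = FALSE, normalize = TRUE) {
  stopifnot_counts(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (length(groups) != ncol(counts$values))
    stop("groups length must equal the number of samples")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  y <- counts$values
  N <- if (!is.null(counts$lib_sizes)) counts$lib_sizes else colSums(y)
  f <- if (normalize && ncol(y) >= 2) tmm_factors(counts) else rep(1, ncol(y))
  eff <- N * f                                   # effective depths
  g1 <- groups == levels(groups)[1]
  g2 <- !g1

  s1 <- rowSums(y[, g1, drop = FALSE]); s2 <- rowSums(y[, g2, drop = FALSE])
  E1 <- sum(eff[g1]); E2 <- sum(eff[g2])
  # logFC: normalized group means with pseudo-count 0.5
  m1 <- (s1 + 0.5) / E1
  m2 <- (s2 + 0.5) / E2
  logFC <- log2(m2 / m1)

  if (!paired) {
    tot <- s1 + s2
    pr <- E2 / (E1 + E2)                         # P(count lands in group 2)
    lo <- stats::pbinom(s2, tot, pr)             # P(X <= s2)
    hi <- stats::pbinom(s2 - 1, tot, pr, lower.tail = FALSE)  # P(X >= s2)
    p <- pmin(1, 2 * pmin(lo, hi))
    p[tot == 0] <- 1
  } else {
    n1 <- sum(g1)
    if (sum(g2) != n1) stop("paired design needs equal group sizes")
    i1 <- which(g1); i2 <- which(g2)
    # within-pair conditional binomials aggregated by summing the group-2
    # members against pair totals at pair-specific depth shares; exact
    # p from the sum of independent binomials via convolution
    p <- numeric(nrow(y)); obs <- integer(nrow(y))
    prs <- eff[i2] / (eff[i1] + eff[i2])
    for (i in seq_len(nrow(y))) {
      tots <- y[i, i1] + y[i, i2]
      if (sum(tots) == 0) { p[i] <- 1; next }
      # distribution of sum of Binomial(tots[k], prs[k]) by convolution
      dist <- 1
      for (k in seq_along(tots)) {
        if (tots[k] == 0) next
        dist <- stats::convolve(dist, rev(stats::dbinom(0:tots[k], tots[k], prs[k])),
                                type = "open")
      }
      dist[dist < 0] <- 0
      s <- sum(y[i, i2])
      lo <- sum(dist[seq_len(s + 1)])
      hi <- sum(dist[(s + 1):length(dist)])
      p[i] <- min(1, 2 * min(lo, hi))
    }
  }
  data.frame(feature_id = rownames(y), logFC = logFC, p = p,
             adj_p = stats::p.adjust(p, "BH"),
             direction = "ns",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter differential-expression results
#'
#' Keeps features with `|logFC| > min_abs_logfc` (strict) and adjusted or
#' raw p below `max_p` (strict), setting `direction` from the sign of the
#' fold-change. The mRNA screen uses the BH-adjusted p
#' (`use_adjusted = TRUE`); the circRNA screen uses the raw p.
#'
#' @param results data.frame from [de_test()].
#' @param min_abs_logfc minimum absolute log2 fold-change (exclusive).
#' @param max_p p-value ceiling (exclusive).
#' @param use_adjusted compare `adj_p` (TRUE) or raw `p` (FALSE).
#' @return the subset of `results` passing both filters, with `direction`
#'   set to `"up"` or `"down"`.
#' @export
call_de <- function(results, min_abs_logfc = 2, max_p = 0.05,
                    use_adjusted = TRUE) {
  if (min_abs_logfc <= 0 || max_p <= 0) stop("thresholds must be positive")
  pv <- if (use_adjusted) results$adj_p else results$p
  keep <- abs(results$logFC) > min_abs_logfc & pv < max_p
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$logFC > 0, "up", "down")
  rownames(out) <- NULL
  out
}
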