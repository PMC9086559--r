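# Independent oracles used to validate the fast implementations.

# Best local alignment score by exhaustive top-down search with caching,
# formulated suffix-first (best continuation from each cell), independent
# of the iterative bottom-up matrix recurrence in the package.
oracle_align <- function(mirna5to3, window, wc = 5, gu = 1, mm = -3,
                         gap_open = -9, gap_extend = -4, seed_scale = 2) {
  q <- rev(strsplit(mirna5to3, "")[[1]])  # 3'->5'
  w <- strsplit(window, "")[[1]]
  m <- length(q); n <- length(w)
  scale_of <- function(i) if ((m - i + 1) >= 2 && (m - i + 1) <= 8) seed_scale else 1
  pair <- function(a, b) {
    if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
        (a == "C" && b == "G") || (a == "G" && b == "C")) wc
    else if ((a == "G" && b == "U") || (a == "U" && b == "G")) gu
    else mm
  }
  memo <- new.env(hash = TRUE)
  # best score of an alignment continuing at (i, j); state: 0 after a
  # paired/mismatch column, 1 inside a query gap, 2 inside a target gap
  cont <- function(i, j, state) {
    if (i > m || j > n) return(0)
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- 0  # stop here
    d <- scale_of(i) * pair(q[i], w[j]) + cont(i + 1, j + 1, 0)
    if (d > best) best <- d
    og <- if (state == 1) gap_extend else gap_open
    g1 <- og + cont(i + 1, j, 1)
    if (g1 > best) best <- g1
    og2 <- if (state == 2) gap_extend else gap_open
    g2 <- og2 + cont(i, j + 1, 2)
    if (g2 > best) best <- g2
    memo[[key]] <- best
    best
  }
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    s <- cont(i, j, 0)
    if (s > best) best <- s
  }
  best
}

# Maximal-clique MCC by direct subset enumeration (n <= 15 or so).
oracle_mcc <- function(edges, nodes) {
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    adj[edges$from[k], edges$to[k]] <- TRUE
    adj[edges$to[k], edges$from[k]] <- TRUE
  }
  is_clique <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    all(adj[idx, idx][upper.tri(diag(length(idx)))])
  }
  mcc <- stats::setNames(rep(0, n), nodes)
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!is_clique(idx)) next
    # maximal iff no outside vertex adjacent to all members
    outside <- setdiff(seq_len(n), idx)
    maximal <- !any(vapply(outside, function(v) all(adj[v, idx]), TRUE))
    if (maximal) mcc[idx] <- mcc[idx] + factorial(length(idx) - 1)
  }
  mcc
}

# Log-rank statistic from first principles (pooled hypergeometric terms).
oracle_logrank <- function(time, event, group) {
  g1 <- group == unique(group)[1]
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Classic (unweighted) KS enrichment score on a ranked id list.
oracle_ks <- function(ids, gene_set) {
  inset <- ids %in% gene_set
  nh <- sum(inset); nm <- length(ids) - nh
  running <- cumsum(ifelse(inset, 1 / nh, -1 / nm))
  running[which.max(abs(running))]
}

make_counts <- function(values, lib_sizes = NULL, lengths = NULL) {
  v <- as.matrix(values)
  if (is.null(rownames(v))) rownames(v) <- paste0("g", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- paste0("s", seq_len(ncol(v)))
  expr_matrix(v, "count", lib_sizes = lib_sizes, feature_lengths = lengths)
}

rand_rna_str <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                  collapse = "")
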