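#' Synthetic ground truth descriptor
#'
#' Every generator returns, alongside its data, a `SyntheticTruth` object
#' recording exactly what was planted: differential features and their
#' direction, miRNA binding-site positions, ceRNA triples, PPI cliques,
#' and true log-hazard coefficients. The seed fully determines all
#' outputs.
#'
#' @param ... fields to set (see Details).
#' @return object of class `SyntheticTruth`.
#' @details Fields: `de_features` (data.frame feature_id/direction),
#'   `planted_sites` (data.frame mirna_id/target_id/start), `planted_triples`
#'   (data.frame circ_id/mir_id/mrna_id), `planted_cliques` (list of
#'   character vectors), `prognostic_betas` (named numeric), `seed`.
#' @export
synthetic_truth <- function(...) {
  x <- list(de_features = data.frame(feature_id = character(),
                                     direction = character()),
            planted_sites = data.frame(mirna_id = character(),
                                       target_id = character(),
                                       start = integer()),
            planted_triples = data.frame(circ_id = character(),
                                         mir_id = character(),
                                         mrna_id = character()),
            planted_cliques = list(),
            prognostic_betas = numeric(0),
            seed = NA_integer_)
  dots <- list(...)
  x[names(dots)] <- dots
  structure(x, class = "SyntheticTruth")
}

#' @method print SyntheticTruth
#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf(
    "SyntheticTruth(seed %s): %d DE features, %d sites, %d triples, %d cliques, %d betas\n",
    x$seed, nrow(x$de_features), nrow(x$planted_sites),
    nrow(x$planted_triples), length(x$planted_cliques),
    length(x$prognostic_betas)))
  invisible(x)
}

#' Simulate a paired tumor/normal count matrix with planted fold-changes
#'
#' Negative-binomial (gamma-Poisson) counts for `n_features` features over
#' `n_pairs` tumor/normal pairs. Feature base means are drawn log-normally;
#' per-sample means scale with library size; a fraction `frac_de` of
#' features (round(frac_de * n_features), direction split ~50/50) have
#' their tumor-group mean multiplied or divided by `fc_de`.
#'
#' @param n_features number of features.
#' @param n_pairs number of tumor/normal pairs (>= 2).
#' @param frac_de fraction of features planted as differential.
#' @param fc_de planted fold-change (>= 1).
#' @param dispersion NB dispersion (0 gives Poisson).
#' @param lib_sizes vector of 2*n_pairs library sizes (normals first),
#'   or a single value recycled.
#' @param mean_log,sd_log log-normal parameters for feature base means.
#' @param feature_prefix id prefix (e.g. `"gene"` or a circRNA-style id
#'   generator via `circ_ids = TRUE`).
#' @param circ_ids emit circBase-style `chrN:start-end` feature ids.
#' @param seed integer RNG seed.
#' @return list with `counts` (count `ExprMatrix` carrying lib_sizes and,
#'   for gene-style ids, feature lengths in kb) and `truth`
#'   (`SyntheticTruth` whose `de_features` direction is tumor vs normal).
#' @export
gen_count_matrix <- function(n_features, n_pairs, frac_de = 0.1, fc_de = 4,
                             dispersion = 0.1, lib_sizes = 2e7,
                             mean_log = log(100), sd_log = 1,
                             feature_prefix = "gene", circ_ids = FALSE,
                             seed = 1) {
  if (n_pairs < 2) stop("need at least 2 pairs")
  if (frac_de < 0 || frac_de > 1) stop("frac_de must be in [0,1]")
  if (fc_de < 1) stop("fc_de must be >= 1")
  n_samp <- 2L * n_pairs
  if (length(lib_sizes) == 1) lib_sizes <- rep(lib_sizes, n_samp)
  if (length(lib_sizes) != n_samp) stop("need 2*n_pairs library sizes")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  set.seed(seed)
  if (circ_ids) {
    chr <- sample(c(1:22, "X"), n_features, replace = TRUE)
    st <- sample.int(2e8, n_features)
    ids <- sprintf("chr%s:%d-%d", chr, st, st + sample(200:50000, n_features,
                                                       replace = TRUE))
    while (anyDuplicated(ids)) {
      d <- which(duplicated(ids))
      ids[d] <- sprintf("chr%s:%d-%d", sample(c(1:22, "X"), length(d), TRUE),
                        st[d] + d, st[d] + d + 1000L)
    }
    lengths_kb <- NULL
  } else {
    ids <- sprintf("%s%04d", feature_prefix, seq_len(n_features))
    lengths_kb <- round(stats::rlnorm(n_features, log(2), 0.5), 3)
  }
  base_mu <- stats::rlnorm(n_features, mean_log, sd_log)
  n_de <- round(frac_de * n_features)
  de_idx <- if (n_de > 0) sample.int(n_features, n_de) else integer(0)
  up <- rep(FALSE, n_features)
  if (n_de > 0) up[de_idx] <- seq_along(de_idx) %% 2 == 0 | n_de == 1
  # tumor-group multiplier
  mult <- rep(1, n_features)
  mult[de_idx] <- ifelse(up[de_idx], fc_de, 1 / fc_de)

  samp <- c(sprintf("normal_%02d", seq_len(n_pairs)),
            sprintf("tumor_%02d", seq_len(n_pairs)))
  rel <- lib_sizes / mean(lib_sizes)
  mu <- cbind(outer(base_mu, rel[seq_len(n_pairs)]),
              outer(base_mu * mult, rel[n_pairs + seq_len(n_pairs)]))
  counts <- matrix(0L, n_features, n_samp, dimnames = list(ids, samp))
  for (j in seq_len(n_samp)) {
    counts[, j] <- if (dispersion > 0)
      stats::rnbinom(n_features, mu = mu[, j], size = 1 / dispersion)
    else stats::rpois(n_features, mu[, j])
  }
  truth <- synthetic_truth(
    de_features = data.frame(
      feature_id = ids[sort(de_idx)],
      direction = ifelse(up[sort(de_idx)], "up", "down"),
      stringsAsFactors = FALSE),
    seed = seed)
  list(counts = expr_matrix(counts, "count", lib_sizes = lib_sizes,
                            feature_lengths = lengths_kb),
       truth = truth)
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                              collapse = "")

#' Simulate miRNA and target sequence sets with planted binding sites
#'
#' Backgrounds are uniform random RNA; each entry of `site_plan` embeds
#' `n_sites` copies of the exact reverse complement of the full miRNA at
#' recorded, non-overlapping positions in the target. miRNAs are
#' `mirna_len` nt (canonical 22 by default); circRNA and mRNA targets are
#' uniform in the given length ranges.
#'
#' @param n_mirna,n_circ,n_mrna set sizes.
#' @param site_plan data.frame with columns `mir`, `target`, `n_sites`
#'   (miRNA/target indices or ids).
#' @param mirna_len miRNA length, 19-24.
#' @param circ_len,mrna_len length ranges (c(min, max)).
#' @param seed integer RNG seed.
#' @return list with `mirnas`, `circs`, `mrnas` (named character vectors,
#'   RNA alphabet) and `truth` with `planted_sites` (1-based start).
#' @export
gen_sequences <- function(n_mirna, n_circ, n_mrna,
                          site_plan = NULL, mirna_len = 22L,
                          circ_len = c(300L, 800L), mrna_len = c(400L, 1200L),
                          seed = 1) {
  if (mirna_len < 19 || mirna_len > 24) stop("miRNA length must be 19-24")
  if (min(circ_len, mrna_len) < 200 || max(circ_len, mrna_len) > 3000)
    stop("target lengths must lie in 200-3000 nt")
  set.seed(seed)
  mir_ids <- sprintf("mir-%03d", seq_len(n_mirna))
  circ_ids <- sprintf("circ-%03d", seq_len(n_circ))
  mrna_ids <- sprintf("mrna-%03d", seq_len(n_mrna))
  mirnas <- stats::setNames(vapply(seq_len(n_mirna),
                                   function(i) rand_rna(mirna_len), ""), mir_ids)
  circs <- stats::setNames(vapply(seq_len(n_circ), function(i)
    rand_rna(sample(circ_len[1]:circ_len[2], 1)), ""), circ_ids)
  mrnas <- stats::setNames(vapply(seq_len(n_mrna), function(i)
    rand_rna(sample(mrna_len[1]:mrna_len[2], 1)), ""), mrna_ids)
  sites <- data.frame(mirna_id = character(), target_id = character(),
                      start = integer(), stringsAsFactors = FALSE)
  if (!is.null(site_plan) && nrow(site_plan) > 0) {
    all_targets <- c(circs, mrnas)
    used_slots <- stats::setNames(vector("list", length(all_targets)),
                                  names(all_targets))
    for (k in seq_len(nrow(site_plan))) {
      mid <- as.character(site_plan$mir[k])
      tid <- as.character(site_plan$target[k])
      ns <- site_plan$n_sites[k]
      if (!mid %in% mir_ids) stop("unknown miRNA id: ", mid)
      if (!tid %in% names(all_targets)) stop("unknown target id: ", tid)
      site <- rna_revcomp(mirnas[[mid]])
      L <- nchar(site)
      tg <- all_targets[[tid]]
      lt <- nchar(tg)
      # non-overlapping slots with >= 8 nt spacing so each site scores alone
      slot <- L + 8L
      free <- setdiff(seq_len(lt %/% slot), used_slots[[tid]])
      if (ns > length(free))
        stop(sprintf("site plan overruns target %s (%d sites, room for %d)",
                     tid, ns, length(free)))
      chosen <- sort(free[sample.int(length(free), ns)])
      used_slots[[tid]] <- c(used_slots[[tid]], chosen)
      for (s in chosen) {
        pos <- (s - 1L) * slot + 1L
        substr(tg, pos, pos + L - 1L) <- site
        sites <- rbind(sites, data.frame(mirna_id = mid, target_id = tid,
                                         start = pos, stringsAsFactors = FALSE))
      }
      all_targets[[tid]] <- tg
    }
    circs <- all_targets[circ_ids]
    mrnas <- all_targets[mrna_ids]
  }
  list(mirnas = mirnas, circs = circs, mrnas = mrnas,
       truth = synthetic_truth(planted_sites = sites, seed = seed))
}

#' Simulate a survival table driven by gene expression
#'
#' Event times are exponential with hazard proportional to
#' `exp(sum(beta * x))`; censoring times are independent Uniform(0, cmax)
#' with `cmax` solved so that the expected censoring fraction matches
#' `censor_rate`.
#'
#' @param n_patients number of patients (ignored if `expr` given; then
#'   the samples of `expr` are used).
#' @param betas named numeric of true log-hazard coefficients; names must
#'   be genes of `expr` if `expr` is supplied.
#' @param expr optional `ExprMatrix` of covariates (genes x samples);
#'   when `NULL`, standard-normal expression is simulated for the beta
#'   genes plus `n_null_genes` nulls.
#' @param n_null_genes extra unassociated genes when simulating expression.
#' @param censor_rate target censoring fraction in [0, 1).
#' @param baseline_hazard events per year at x = 0 (default ln(2)/5:
#'   five-year median survival).
#' @param seed integer RNG seed.
#' @return list with `survival` (data.frame sample/time/event plus one
#'   column per gene) and `truth` carrying `prognostic_betas`.
#' @export
gen_survival <- function(n_patients, betas = numeric(0), expr = NULL,
                         n_null_genes = 0, censor_rate = 0.2,
                         baseline_hazard = log(2) / 5, seed = 1) {
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0,1)")
  set.seed(seed)
  if (!is.null(expr)) {
    x <- t(expr$values)
    if (!all(names(betas) %in% colnames(x)))
      stop("beta genes missing from expr")
    n_patients <- nrow(x)
    samples <- rownames(x)
  } else {
    genes <- names(betas)
    if (is.null(genes) && length(betas) > 0)
      stop("betas must be named")
    if (n_null_genes > 0)
      genes <- c(genes, sprintf("null%03d", seq_len(n_null_genes)))
    x <- matrix(stats::rnorm(n_patients * length(genes)), n_patients,
                dimnames = list(sprintf("pt_%04d", seq_len(n_patients)), genes))
    samples <- rownames(x)
  }
  lp <- if (length(betas) > 0)
    drop(x[, names(betas), drop = FALSE] %*% betas) else rep(0, n_patients)
  tt <- stats::rexp(n_patients, rate = baseline_hazard * exp(lp))
  if (censor_rate == 0) {
    time <- tt; event <- rep(1L, n_patients)
  } else {
    # E[fraction censored] = mean_i P(U(0,cmax) < t_i) = mean min(t_i/cmax, 1)
    fr <- function(cmax) mean(pmin(tt / cmax, 1)) - censor_rate
    cmax <- stats::uniroot(fr, c(min(tt) * 1e-3, max(tt) * 1e3))$root
    cc <- stats::runif(n_patients, 0, cmax)
    time <- pmin(tt, cc)
    event <- as.integer(tt <= cc)
  }
  surv <- data.frame(sample = samples, time = time, event = event,
                     stringsAsFactors = FALSE)
  surv <- cbind(surv, as.data.frame(x))
  rownames(surv) <- NULL
  list(survival = surv,
       truth = synthetic_truth(prognostic_betas = betas, seed = seed))
}

#' Simulate a PPI edge list with planted cliques
#'
#' Emits every within-clique edge for each planted clique, then adds
#' `noise_edges` random edges that do not duplicate existing ones; the
#' graph is undirected and simple.
#'
#' @param nodes character vector of node ids.
#' @param planted_cliques list of character vectors (each of size >= 2),
#'   subsets of `nodes`.
#' @param noise_edges number of random extra edges.
#' @param seed integer RNG seed.
#' @return list with `edges` (data.frame from/to) and `truth` carrying
#'   `planted_cliques`.
#' @export
gen_ppi <- function(nodes, planted_cliques = list(), noise_edges = 0,
                    seed = 1) {
  set.seed(seed)
  nodes <- as.character(nodes)
  edges <- data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE)
  for (cl in planted_cliques) {
    cl <- as.character(cl)
    if (length(cl) < 2) stop("cliques must have at least 2 nodes")
    if (!all(cl %in% nodes)) stop("clique nodes must be a subset of nodes")
    pr <- t(utils::combn(sort(cl), 2))
    edges <- rbind(edges, data.frame(from = pr[, 1], to = pr[, 2],
                                     stringsAsFactors = FALSE))
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  seen <- unique(key(edges$from, edges$to))
  edges <- edges[!duplicated(key(edges$from, edges$to)), , drop = FALSE]
  n_try <- 0
  while (noise_edges > 0 && n_try < 100 * noise_edges + 1000) {
    a <- sample(nodes, 1); b <- sample(nodes, 1)
    n_try <- n_try + 1
    if (a == b || key(a, b) %in% seen) next
    edges <- rbind(edges, data.frame(from = a, to = b,
                                     stringsAsFactors = FALSE))
    seen <- c(seen, key(a, b))
    noise_edges <- noise_edges - 1
  }
  rownames(edges) <- NULL
  list(edges = edges,
       truth = synthetic_truth(planted_cliques = planted_cliques,
                               seed = seed))
}
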