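#' @useDynLib cernaforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Scoring parameters for miRNA site alignment
#'
#' miRanda-lineage parameters: Watson-Crick pair +5, G:U wobble +1,
#' mismatch -3, gap open -9, gap extend -4, with pair/mismatch
#' contributions at miRNA seed positions 2-8 (from the 5' end) multiplied
#' by `seed_scale`.
#'
#' @param wc,gu,mm,gap_open,gap_extend,seed_scale scoring values.
#' @return a named list of parameters.
#' @export
mir_params <- function(wc = 5, gu = 1, mm = -3, gap_open = -9,
                       gap_extend = -4, seed_scale = 2.0) {
  list(wc = wc, gu = gu, mm = mm, gap_open = gap_open,
       gap_extend = gap_extend, seed_scale = seed_scale)
}

normalize_rna <- function(x) {
  x <- toupper(x)
  gsub("T", "U", x, fixed = TRUE)
}

#' Reverse complement of an RNA string
#' @param x RNA (or DNA) string; normalised to RNA first.
#' @return RNA string.
#' @export
rna_revcomp <- function(x) {
  x <- normalize_rna(x)
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]), collapse = "")
}

#' Align a miRNA against a candidate target window
#'
#' Best local alignment (affine-gap Gotoh dynamic programme) of the miRNA,
#' read 3'->5', against the window read 5'->3', under the scoring scheme
#' of [mir_params()]. The returned alignment strings give the miRNA
#' 3'->5', a pairing line (`|` Watson-Crick, `:` G:U wobble) and the
#' target 5'->3'.
#'
#' @param mirna miRNA sequence, 5'->3', 19-24 nt.
#' @param window target subsequence, 5'->3', at least as long as the miRNA.
#' @param params list from [mir_params()].
#' @return list with `score`, `target_start`/`target_end` (1-based on the
#'   window), and `alignment` (mirna/pairing/target strings).
#' @export
align_site <- function(mirna, window, params = mir_params()) {
  mirna <- normalize_rna(mirna); window <- normalize_rna(window)
  if (nchar(mirna) < 19 || nchar(mirna) > 24)
    stop("miRNA length must be 19-24 nt")
  if (nchar(window) < nchar(mirna))
    stop("window shorter than the miRNA")
  if (grepl("[^ACGU]", mirna) || grepl("[^ACGU]", window))
    stop("non-ACGU characters in input")
  q <- paste(rev(strsplit(mirna, "")[[1]]), collapse = "")  # 3'->5'
  r <- .align_core(q, window, params$wc, params$gu, params$mm,
                   params$gap_open, params$gap_extend, params$seed_scale)
  list(score = r$score,
       target_start = r$target_start, target_end = r$target_end,
       alignment = list(mirna = r$mirna_aln, pairing = r$pairing,
                        target = r$target_aln))
}

# Watson-Crick nearest-neighbour stack free energies (kcal/mol, 37 C),
# keyed by the target-strand dinucleotide read 5'->3'; the paired miRNA
# dinucleotide is implied by complementarity. Standard RNA duplex values.
.nn_wc <- c(AA = -0.93, UU = -0.93, AU = -1.10, UA = -1.33,
            CU = -2.08, AG = -2.08, CA = -2.11, UG = -2.11,
            GU = -2.24, AC = -2.24, GA = -2.35, UC = -2.35,
            CG = -2.36, GG = -3.26, CC = -3.26, GC = -3.42)
.nn_init <- 4.09     # duplex initiation
.nn_gu_stack <- -1.0 # flat value for stacks involving a G:U wobble pair

#' Duplex free-energy estimate for an alignment
#'
#' Nearest-neighbour stacking sum over runs of consecutive paired columns
#' plus a constant duplex-initiation penalty. Gapped or mismatched columns
#' contribute nothing and break stacks. Watson-Crick/Watson-Crick stacks
#' use the embedded published stack table; any stack involving a G:U
#' wobble uses a single flat destabilised value. More negative = more
#' stable; units kcal/mol.
#'
#' @param alignment the `alignment` element returned by [align_site()].
#' @return free energy in kcal/mol.
#' @export
duplex_energy <- function(alignment) {
  pr <- strsplit(alignment$pairing, "")[[1]]
  tg <- strsplit(alignment$target, "")[[1]]
  paired <- pr %in% c("|", ":")
  e <- .nn_init
  if (length(pr) >= 2) {
    for (k in seq_len(length(pr) - 1)) {
      if (paired[k] && paired[k + 1]) {
        if (pr[k] == "|" && pr[k + 1] == "|") {
          e <- e + .nn_wc[[paste0(tg[k], tg[k + 1])]]
        } else {
          e <- e + .nn_gu_stack
        }
      }
    }
  }
  e
}

#' Scan target sequences for miRNA binding sites
#'
#' Slides an alignment window along each target, scores every window with
#' [align_site()], estimates the duplex free energy of each alignment, and
#' reports non-overlapping sites with `score > min_score` and
#' `energy < max_energy`. Overlap resolution is greedy by descending
#' score, ties broken by leftmost position; output is sorted by
#' (miRNA, target, position).
#'
#' @param mirnas named character vector (or `Biostrings::RNAStringSet`) of
#'   miRNA sequences 5'->3'.
#' @param targets named character vector (or `RNAStringSet`) of target
#'   sequences 5'->3'.
#' @param min_score minimum alignment score (exclusive; default 140).
#' @param max_energy maximum duplex energy in kcal/mol (exclusive;
#'   default -20).
#' @param params scoring parameters from [mir_params()].
#' @param step window stride in nt.
#' @return data.frame of hits: `mirna_id`, `target_id`, `score`, `energy`,
#'   `target_start`, `target_end`, `mirna_aln`, `pairing`, `target_aln`.
#' @export
scan_targets <- function(mirnas, targets, min_score = 140,
                         max_energy = -20, params = mir_params(),
                         step = 6L) {
  mirnas <- as_seq_vector(mirnas); targets <- as_seq_vector(targets)
  empty <- data.frame(mirna_id = character(), target_id = character(),
                      score = numeric(), energy = numeric(),
                      target_start = integer(), target_end = integer(),
                      mirna_aln = character(), pairing = character(),
                      target_aln = character(), stringsAsFactors = FALSE)
  if (length(mirnas) == 0 || length(targets) == 0) return(empty)
  out <- list()
  for (mid in names(mirnas)) {
    mir <- normalize_rna(mirnas[[mid]])
    lm <- nchar(mir)
    width <- lm + 12L
    for (tid in names(targets)) {
      tg <- normalize_rna(targets[[tid]])
      lt <- nchar(tg)
      if (lt < lm) next
      starts <- unique(c(seq(1L, max(1L, lt - width + 1L), by = step),
                         max(1L, lt - width + 1L)))
      hits <- list()
      for (s in starts) {
        w <- substr(tg, s, min(lt, s + width - 1L))
        a <- align_site(mir, w, params)
        if (a$score <= min_score || is.na(a$target_start)) next
        en <- duplex_energy(a$alignment)
        if (en >= max_energy) next
        hits[[length(hits) + 1L]] <- data.frame(
          mirna_id = mid, target_id = tid, score = a$score, energy = en,
          target_start = s + a$target_start - 1L,
          target_end = s + a$target_end - 1L,
          mirna_aln = a$alignment$mirna, pairing = a$alignment$pairing,
          target_aln = a$alignment$target, stringsAsFactors = FALSE)
      }
      if (length(hits) == 0) next
      h <- unique(do.call(rbind, hits))
      h <- h[order(-h$score, h$target_start), , drop = FALSE]
      kept <- h[0, , drop = FALSE]
      for (i in seq_len(nrow(h))) {
        if (nrow(kept) == 0 ||
            all(h$target_start[i] > kept$target_end |
                h$target_end[i] < kept$target_start)) {
          kept <- rbind(kept, h[i, , drop = FALSE])
        }
      }
      out[[length(out) + 1L]] <- kept
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$mirna_id, res$target_id, res$target_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

as_seq_vector <- function(x) {
  if (inherits(x, "XStringSet")) {
    v <- as.character(x)
    stats::setNames(as.vector(v), names(x))
  } else {
    if (is.null(names(x)) && length(x) > 0)
      stop("sequences must be named")
    as.list(x)
  }
}
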