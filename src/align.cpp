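#include <Rcpp.h>
using namespace Rcpp;

// Seed-weighted Gotoh local alignment of a miRNA against a target window.
//
// The miRNA is aligned antiparallel: the caller passes it 3'->5' so that
// successive query positions pair successive target positions read 5'->3'.
// Pair scores: Watson-Crick +5, G:U wobble +1, mismatch -3; affine gaps
// (open -9, extend -4). Columns pairing a miRNA seed base (positions 2-8
// from the miRNA 5' end, i.e. the last 7 bases of the reversed query save
// the terminal one) have their pair/mismatch contribution multiplied by
// seed_scale.

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'U': return 3;
    default: return -1;
  }
}

static inline double pair_score(int a, int b, double wc, double gu, double mm) {
  // a, b are base indices; complementary test on (query base, target base)
  if ((a == 0 && b == 3) || (a == 3 && b == 0) ||
      (a == 1 && b == 2) || (a == 2 && b == 1)) return wc;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return gu;
  return mm;
}

static inline char pair_char(char q, char t) {
  int a = base_idx(q), b = base_idx(t);
  if ((a == 0 && b == 3) || (a == 3 && b == 0) ||
      (a == 1 && b == 2) || (a == 2 && b == 1)) return '|';
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return ':';
  return ' ';
}

// [[Rcpp::export(name = ".align_core")]]
List align_core(std::string query, std::string target,
                double wc = 5.0, double gu = 1.0, double mm = -3.0,
                double gap_open = -9.0, double gap_extend = -4.0,
                double seed_scale = 2.0) {
  const int m = query.size(), n = target.size();
  const double NEG = -1e30;
  for (int i = 0; i < m; ++i)
    if (base_idx(query[i]) < 0) stop("non-ACGU character in miRNA");
  for (int j = 0; j < n; ++j)
    if (base_idx(target[j]) < 0) stop("non-ACGU character in target");

  // query is the miRNA written 3'->5': query index i (1-based) corresponds
  // to miRNA 5'-position m - i + 1; seed = 5'-positions 2..8
  std::vector<double> scale(m + 1, 1.0);
  for (int i = 1; i <= m; ++i) {
    int pos5 = m - i + 1;
    if (pos5 >= 2 && pos5 <= 8) scale[i] = seed_scale;
  }

  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  IntegerMatrix TB(m + 1, n + 1);  // 0 stop, 1 diag, 2 up(E), 3 left(F)
  IntegerMatrix TE(m + 1, n + 1), TF(m + 1, n + 1); // 1 = came from H
  for (int j = 0; j <= n; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  double best = 0.0; int bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    E(i, 0) = NEG; F(i, 0) = NEG;
    const int qa = base_idx(query[i - 1]);
    for (int j = 1; j <= n; ++j) {
      double eo = H(i - 1, j) + gap_open, ee = E(i - 1, j) + gap_extend;
      E(i, j) = eo >= ee ? eo : ee; TE(i, j) = eo >= ee ? 1 : 0;
      double fo = H(i, j - 1) + gap_open, fe = F(i, j - 1) + gap_extend;
      F(i, j) = fo >= fe ? fo : fe; TF(i, j) = fo >= fe ? 1 : 0;
      double diag = H(i - 1, j - 1) +
        scale[i] * pair_score(qa, base_idx(target[j - 1]), wc, gu, mm);
      double h = 0.0; int tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E(i, j) > h) { h = E(i, j); tb = 2; }
      if (F(i, j) > h) { h = F(i, j); tb = 3; }
      H(i, j) = h; TB(i, j) = tb;
      if (h > best + 1e-12) { best = h; bi = i; bj = j; }
    }
  }

  std::string aq, at, ap;
  int i = bi, j = bj;
  int state = 0; // 0 in H, 1 in E, 2 in F
  while (i > 0 && j > 0) {
    if (state == 0) {
      int tb = TB(i, j);
      if (tb == 0) break;
      if (tb == 1) {
        aq.push_back(query[i - 1]); at.push_back(target[j - 1]);
        ap.push_back(pair_char(query[i - 1], target[j - 1]));
        --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      aq.push_back(query[i - 1]); at.push_back('-'); ap.push_back(' ');
      if (TE(i, j) == 1) state = 0;
      --i;
    } else {
      aq.push_back('-'); at.push_back(target[j - 1]); ap.push_back(' ');
      if (TF(i, j) == 1) state = 0;
      --j;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(at.begin(), at.end());
  std::reverse(ap.begin(), ap.end());

  return List::create(
    _["score"] = best,
    _["query_start"] = best > 0 ? i + 1 : NA_INTEGER,
    _["query_end"] = best > 0 ? bi : NA_INTEGER,
    _["target_start"] = best > 0 ? j + 1 : NA_INTEGER,
    _["target_end"] = best > 0 ? bj : NA_INTEGER,
    _["mirna_aln"] = aq, _["pairing"] = ap, _["target_aln"] = at);
}
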