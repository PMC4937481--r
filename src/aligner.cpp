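#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap pairwise alignment over integer-coded sequences.
// A gap of length k costs gap_open + k * gap_extend (BLAST convention).
// local = true  -> Smith-Waterman (best local alignment)
// local = false -> Needleman-Wunsch (global, end gaps penalised)
//
// Sequences are 1-based codes into the substitution matrix rows/cols.
// Returns score, 1-based aligned index vectors (0 = gap), and for local
// alignments the start/end coordinates in each sequence.

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".align_affine_cpp")]]
List align_affine_cpp(IntegerVector a, IntegerVector b, NumericMatrix subst,
                      double gap_open, double gap_extend, bool local) {
  const int n = a.size(), m = b.size();
  // M: a[i] aligned to b[j]; X: gap in b (a[i] against '-'); Y: gap in a
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  const double open_cost = gap_open + gap_extend;

  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = local ? 0.0 : NEG_INF;  // local alignments may start anywhere
    X(i, 0) = local ? NEG_INF : -(gap_open + gap_extend * i);
    Y(i, 0) = NEG_INF;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = local ? 0.0 : NEG_INF;
    X(0, j) = NEG_INF;
    Y(0, j) = local ? NEG_INF : -(gap_open + gap_extend * j);
  }

  double best = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = subst(a[i - 1] - 1, b[j - 1] - 1);
      double diag = std::max(M(i - 1, j - 1),
                             std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      double mm = diag + s;
      if (local && mm < 0) mm = 0;  // restart a local alignment
      M(i, j) = mm;
      X(i, j) = std::max(M(i - 1, j) - open_cost, X(i - 1, j) - gap_extend);
      Y(i, j) = std::max(M(i, j - 1) - open_cost, Y(i, j - 1) - gap_extend);
      if (local && M(i, j) > best) { best = M(i, j); best_i = i; best_j = j; }
    }
  }

  double score;
  int ei, ej;
  if (local) {
    score = best; ei = best_i; ej = best_j;
  } else {
    score = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
    ei = n; ej = m;
  }

  // traceback
  std::vector<int> ai, bi;
  int i = ei, j = ej;
  int state;  // 0 = M, 1 = X, 2 = Y
  if (local) state = 0;
  else state = (score == M(n, m)) ? 0 : ((score == X(n, m)) ? 1 : 2);

  while (i > 0 || j > 0) {
    if (local && state == 0 && M(i, j) == 0) break;
    if (!local && i == 0) { ai.push_back(0); bi.push_back(j); --j; continue; }
    if (!local && j == 0) { ai.push_back(i); bi.push_back(0); --i; continue; }
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      double diag = M(i, j) - subst(a[i - 1] - 1, b[j - 1] - 1);
      // decide predecessor state
      if (diag == M(i - 1, j - 1)) state = 0;
      else if (diag == X(i - 1, j - 1)) state = 1;
      else state = 2;
      --i; --j;
      if (local && i > 0 && j > 0 && M(i, j) == 0 && state == 0) break;
    } else if (state == 1) {
      ai.push_back(i); bi.push_back(0);
      if (X(i, j) == M(i - 1, j) - open_cost) state = 0; else state = 1;
      --i;
    } else {
      ai.push_back(0); bi.push_back(j);
      if (Y(i, j) == M(i, j - 1) - open_cost) state = 0; else state = 2;
      --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  int sa = n + 1, sb = m + 1;
  for (size_t k = 0; k < ai.size(); ++k) {
    if (ai[k] > 0 && ai[k] < sa) sa = ai[k];
    if (bi[k] > 0 && bi[k] < sb) sb = bi[k];
  }
  if (ai.empty()) { sa = 0; sb = 0; ei = 0; ej = 0; }

  return List::create(_["score"] = score,
                      _["a_idx"] = wrap(ai), _["b_idx"] = wrap(bi),
                      _["a_start"] = sa, _["a_end"] = ei,
                      _["b_start"] = sb, _["b_end"] = ej);
}

// Ungapped X-drop extension along a diagonal from a seed, both directions.
// Returns the best-scoring ungapped segment [a_start, a_end] x [b_start, b_end]
// (1-based, inclusive) containing the seed, and its score.
// [[Rcpp::export(name = ".xdrop_extend_cpp")]]
List xdrop_extend_cpp(IntegerVector a, IntegerVector b, NumericMatrix subst,
                      int a_seed, int b_seed, int seed_len, double xdrop) {
  const int n = a.size(), m = b.size();
  double score = 0.0;
  for (int k = 0; k < seed_len; ++k)
    score += subst(a[a_seed - 1 + k] - 1, b[b_seed - 1 + k] - 1);

  // extend right
  double run = score, best_r = score;
  int a_end = a_seed + seed_len - 1, b_end = b_seed + seed_len - 1;
  int ar = a_end, br = b_end;
  while (ar < n && br < m) {
    ++ar; ++br;
    run += subst(a[ar - 1] - 1, b[br - 1] - 1);
    if (run > best_r) { best_r = run; a_end = ar; b_end = br; }
    if (best_r - run > xdrop) break;
  }
  // extend left
  run = best_r;
  double best_l = best_r;
  int a_start = a_seed, b_start = b_seed;
  int al = a_seed, bl = b_seed;
  while (al > 1 && bl > 1) {
    --al; --bl;
    run += subst(a[al - 1] - 1, b[bl - 1] - 1);
    if (run > best_l) { best_l = run; a_start = al; b_start = bl; }
    if (best_l - run > xdrop) break;
  }
  return List::create(_["score"] = best_l,
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end);
}
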