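#include <Rcpp.h>
using namespace Rcpp;

// Maximum-score nested folding over an arbitrary pair-score matrix
// (Nussinov-style DP with an explicit paired state so that a stacking
// bonus can be awarded to helically adjacent pairs).
//
//   P(i,j) = pair(i,j) + max(S(i+1,j-1) - helix_open, P(i+1,j-1) + stack)
//   S(i,j) = max(S(i+1,j), S(i,j-1), P(i,j), max_k S(i,k) + S(k+1,j))
//
// pair(i,j) = NA/-Inf marks a disallowed pair; min_sep is the minimum
// number of unpaired positions between i and j (hairpin loop size).
// Traceback is deterministic: prefer closing the pair (i,j), then
// leaving i unpaired, then j, then the leftmost bifurcation.
//
// Returns total score and the partner vector (0 = unpaired, 1-based).

static const double NEG = -1e18;
static const double EPS = 1e-9;

// [[Rcpp::export(name = ".fold_pairs_cpp")]]
List fold_pairs_cpp(NumericMatrix pair_score, int min_sep, double stack_bonus,
                    double helix_open) {
  const int n = pair_score.nrow();
  if (n == 0)
    return List::create(_["score"] = 0.0, _["partner"] = IntegerVector(0));

  NumericMatrix S(n, n), P(n, n);
  std::fill(P.begin(), P.end(), NEG);

  for (int d = 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      double ps = pair_score(i, j);
      bool allowed = R_finite(ps) && (j - i - 1) >= min_sep;
      if (allowed) {
        double inner = (i + 1 <= j - 1) ? S(i + 1, j - 1) : 0.0;
        double opennew = inner - helix_open;
        double stacked = (i + 1 <= j - 1 && P(i + 1, j - 1) > NEG / 2)
                             ? P(i + 1, j - 1) + stack_bonus
                             : NEG;
        P(i, j) = ps + std::max(opennew, stacked);
      }
      double best = std::max(S(i + 1, j), S(i, j - 1));
      if (allowed && P(i, j) > best) best = P(i, j);
      for (int k = i + 1; k < j; ++k) {
        double v = S(i, k) + S(k + 1, j);
        if (v > best) best = v;
      }
      S(i, j) = best;
    }
  }

  IntegerVector partner(n, 0);
  // iterative traceback over a stack of (i, j, in_paired_state) frames
  std::vector<std::array<int, 3>> stack;
  stack.push_back({0, n - 1, 0});
  while (!stack.empty()) {
    std::array<int, 3> fr = stack.back();
    stack.pop_back();
    int i = fr[0], j = fr[1], paired = fr[2];
    if (i >= j) continue;
    if (paired) {
      // (i,j) is paired; decide how the inside was scored
      partner[i] = j + 1;
      partner[j] = i + 1;
      if (i + 1 > j - 1) continue;
      double ps = pair_score(i, j);
      double stacked = (P(i + 1, j - 1) > NEG / 2)
                           ? ps + P(i + 1, j - 1) + stack_bonus
                           : NEG;
      if (std::abs(P(i, j) - stacked) < EPS)
        stack.push_back({i + 1, j - 1, 1});
      else
        stack.push_back({i + 1, j - 1, 0});
      continue;
      // (opening case falls through to the unpaired state above)
    }
    double s = S(i, j);
    if (s <= EPS && s >= -EPS && P(i, j) < EPS) continue;  // nothing scored
    if (P(i, j) > NEG / 2 && std::abs(s - P(i, j)) < EPS) {
      stack.push_back({i, j, 1});
    } else if (std::abs(s - S(i + 1, j)) < EPS) {
      stack.push_back({i + 1, j, 0});
    } else if (std::abs(s - S(i, j - 1)) < EPS) {
      stack.push_back({i, j - 1, 0});
    } else {
      for (int k = i + 1; k < j; ++k) {
        if (std::abs(s - (S(i, k) + S(k + 1, j))) < EPS) {
          stack.push_back({i, k, 0});
          stack.push_back({k + 1, j, 0});
          break;
        }
      }
    }
  }

  return List::create(_["score"] = S(0, n - 1), _["partner"] = partner);
}

// Single-sequence folding score for integer-coded RNA/DNA
// (1=A, 2=C, 3=G, 4=U/T; anything else never pairs).
// Pair weights by type (G:C, A:U, G:U wobble), +stack_bonus per
// stacked pair, -helix_open for starting a new helix. The opening
// penalty is a linearised stand-in for thermodynamic loop costs: it
// stops scattered lone pairs from saturating the score of random
// sequence, which a plain maximum-pairing DP does. Used for the
// z-score: energy = -score.
// [[Rcpp::export(name = ".fold_energy_cpp")]]
double fold_energy_cpp(IntegerVector seq, int min_sep, double stack_bonus,
                       double helix_open, double w_gc, double w_au,
                       double w_gu) {
  const int n = seq.size();
  if (n < min_sep + 2) return 0.0;
  NumericMatrix S(n, n), P(n, n);
  std::fill(P.begin(), P.end(), NEG);
  auto pair_w = [&](int x, int y) -> double {
    if (x > y) std::swap(x, y);
    if (x == 2 && y == 3) return w_gc;
    if (x == 1 && y == 4) return w_au;
    if (x == 3 && y == 4) return w_gu;
    return NEG;
  };
  for (int d = 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      double w = (j - i - 1) >= min_sep ? pair_w(seq[i], seq[j]) : NEG;
      bool allowed = w > NEG / 2;
      if (allowed) {
        double inner = (i + 1 <= j - 1) ? S(i + 1, j - 1) : 0.0;
        double opennew = inner + w - helix_open;
        double stacked = (i + 1 <= j - 1 && P(i + 1, j - 1) > NEG / 2)
                             ? P(i + 1, j - 1) + w + stack_bonus
                             : NEG;
        P(i, j) = std::max(opennew, stacked);
      }
      double best = std::max(S(i + 1, j), S(i, j - 1));
      if (allowed && P(i, j) > best) best = P(i, j);
      for (int k = i + 1; k < j; ++k) {
        double v = S(i, k) + S(k + 1, j);
        if (v > best) best = v;
      }
      S(i, j) = best;
    }
  }
  return S(0, n - 1);
}
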