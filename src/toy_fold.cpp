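#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Additive pair-energy folding model with an optional helix-stacking
// bonus (Nussinov/Jacobson-style recursions with a minimum hairpin
// loop).  Energies come in as a 4x4 matrix indexed A=0, C=1, G=2, U=3;
// NA marks a disallowed pair.  Characters outside ACGU/acgu/Tt (N, IUPAC
// ambiguity codes) never pair.  `stack` (<= 0) is added once for every
// pair whose immediate interior neighbour is also paired, which makes
// contiguous helices strictly preferable to scattered pairings.

static inline int code_of(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::vector<int> encode(const std::string& seq) {
  std::vector<int> s(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) s[i] = code_of(seq[i]);
  return s;
}

static inline bool pairable(const std::vector<int>& s, const NumericMatrix& E,
                            int i, int j) {
  if (s[i] < 0 || s[j] < 0) return false;
  return !ISNAN(E(s[i], s[j]));
}

static const double EPS = 1e-9;
typedef std::vector<std::vector<double> > Mat;

// Fill W (free) and V (i,j paired) minimum-energy matrices.
static void fill_mfe(const std::vector<int>& s, const NumericMatrix& E,
                     int minloop, double stack, Mat& W, Mat& V) {
  int n = (int)s.size();
  const double INF = 1e30;
  W.assign(n + 1, std::vector<double>(n + 1, 0.0));
  V.assign(n + 1, std::vector<double>(n + 1, INF));
  for (int span = minloop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (pairable(s, E, i, j)) {
        double interior = W[i + 1][j - 1];
        if (V[i + 1][j - 1] < INF / 2 &&
            V[i + 1][j - 1] + stack < interior)
          interior = V[i + 1][j - 1] + stack;
        V[i][j] = E(s[i], s[j]) + interior;
      }
      double best = W[i + 1][j];
      for (int k = i + minloop + 1; k <= j; ++k) {
        if (V[i][k] >= INF / 2) continue;
        double v = V[i][k] + (k + 1 <= j ? W[k + 1][j] : 0.0);
        if (v < best) best = v;
      }
      W[i][j] = best;
    }
  }
}

// [[Rcpp::export]]
List toy_mfe_cpp(std::string seq, NumericMatrix E, int minloop,
                 double stack) {
  std::vector<int> s = encode(seq);
  int n = (int)s.size();
  if (n == 0) stop("empty sequence");
  Mat W, V;
  fill_mfe(s, E, minloop, stack, W, V);
  // Deterministic traceback: in W prefer leaving i unpaired, then the
  // smallest helix start k; in V prefer the unstacked interior.
  std::vector<int> pi, pj;
  // state 0 = W interval, 1 = V interval
  std::vector<std::pair<std::pair<int, int>, int> > todo;
  todo.push_back(std::make_pair(std::make_pair(0, n - 1), 0));
  while (!todo.empty()) {
    int i = todo.back().first.first, j = todo.back().first.second;
    int state = todo.back().second;
    todo.pop_back();
    if (i >= j || j - i < minloop + 1) continue;
    if (state == 1) {
      pi.push_back(i); pj.push_back(j);
      double interior = V[i][j] - E(s[i], s[j]);
      if (std::fabs(interior - W[i + 1][j - 1]) < EPS)
        todo.push_back(std::make_pair(std::make_pair(i + 1, j - 1), 0));
      else
        todo.push_back(std::make_pair(std::make_pair(i + 1, j - 1), 1));
      continue;
    }
    if (std::fabs(W[i][j] - W[i + 1][j]) < EPS) {
      todo.push_back(std::make_pair(std::make_pair(i + 1, j), 0));
      continue;
    }
    bool found = false;
    for (int k = i + minloop + 1; k <= j && !found; ++k) {
      if (V[i][k] >= 1e29) continue;
      double v = V[i][k] + (k + 1 <= j ? W[k + 1][j] : 0.0);
      if (std::fabs(v - W[i][j]) < EPS) {
        todo.push_back(std::make_pair(std::make_pair(i, k), 1));
        if (k + 1 <= j)
          todo.push_back(std::make_pair(std::make_pair(k + 1, j), 0));
        found = true;
      }
    }
    if (!found) stop("traceback failed (internal error)");
  }
  return List::create(_["mfe"] = W[0][n - 1],
                      _["i"] = wrap(pi), _["j"] = wrap(pj));
}

// [[Rcpp::export]]
NumericVector toy_mfe_batch_cpp(CharacterVector seqs, NumericMatrix E,
                                int minloop, double stack) {
  int m = seqs.size();
  NumericVector out(m);
  Mat W, V;
  for (int q = 0; q < m; ++q) {
    std::string seq = as<std::string>(seqs[q]);
    std::vector<int> s = encode(seq);
    if (s.empty()) stop("empty sequence in batch");
    fill_mfe(s, E, minloop, stack, W, V);
    out[q] = W[0][(int)s.size() - 1];
  }
  return out;
}

// McCaskill-style inside/outside recursions for the stacking-aware
// additive model.  Boltzmann factors are rescaled per nucleotide by
// sigma = exp(mfe/(kT*n)) so that partition sums stay in double range
// for long, GC-rich windows; the scaling cancels exactly in the pair
// probabilities.
// [[Rcpp::export]]
List toy_ensemble_cpp(std::string seq, NumericMatrix E, int minloop,
                      double stack, double kT, double mfe) {
  std::vector<int> s = encode(seq);
  int n = (int)s.size();
  if (n == 0) stop("empty sequence");
  double sigma = std::exp(mfe / (kT * n));
  double sb = std::exp(-stack / kT);   // stacking Boltzmann factor

  // Inside.  Q over closed intervals (empty interval = 1); Qb(i,j) =
  // scaled partition of [i, j] given that (i, j) pair.  A structure in
  // which (i+1, j-1) also pair picks up the stacking factor.
  Mat Q(n, std::vector<double>(n, 0.0));
  Mat Qb(n, std::vector<double>(n, 0.0));
  for (int i = 0; i < n; ++i) Q[i][i] = sigma;
  for (int span = 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (span >= minloop + 1 && pairable(s, E, i, j)) {
        double bf = std::exp(-E(s[i], s[j]) / kT) * sigma * sigma;
        double qin = 1.0, qbin = 0.0;
        if (j - 1 >= i + 1) { qin = Q[i + 1][j - 1]; qbin = Qb[i + 1][j - 1]; }
        Qb[i][j] = bf * ((qin - qbin) + sb * qbin);
      }
      double q = sigma * Q[i + 1][j];
      for (int k = i + minloop + 1; k <= j; ++k) {
        if (Qb[i][k] <= 0.0) continue;
        q += Qb[i][k] * (k + 1 <= j ? Q[k + 1][j] : 1.0);
      }
      Q[i][j] = q;
    }
  }
  double Qtot = Q[0][n - 1];

  // Outside: Qout(i,j) = scaled partition over the exterior of [i, j]
  // given that (i, j) pair, decomposed by the innermost enclosing pair
  // (k, l); (k, l) stacks on (i, j) exactly when it is adjacent.
  Mat Qout(n, std::vector<double>(n, 0.0));
  NumericMatrix P(n, n);
  double ed = 0.0;
  std::vector<int> ci, cj;
  for (int span = n - 1; span >= minloop + 1; --span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (Qb[i][j] <= 0.0) continue;
      double left = (i - 1 >= 0) ? Q[0][i - 1] : 1.0;
      double right = (j + 1 <= n - 1) ? Q[j + 1][n - 1] : 1.0;
      double qo = left * right;
      for (int k = 0; k < i; ++k) {
        for (int l = j + 1; l < n; ++l) {
          if (Qb[k][l] <= 0.0 || Qout[k][l] <= 0.0) continue;
          double bf = std::exp(-E(s[k], s[l]) / kT) * sigma * sigma;
          double mid;
          if (k + 1 == i && l - 1 == j) {
            mid = sb;
          } else {
            double a = (k + 1 <= i - 1) ? Q[k + 1][i - 1] : 1.0;
            double b = (j + 1 <= l - 1) ? Q[j + 1][l - 1] : 1.0;
            mid = a * b;
          }
          qo += Qout[k][l] * bf * mid;
        }
      }
      Qout[i][j] = qo;
      double p = Qb[i][j] * qo / Qtot;
      if (p < 0.0) p = 0.0;
      if (p > 1.0) p = 1.0;
      P(i, j) = p;
      ed += 2.0 * p * (1.0 - p);
      if (p > 0.5) { ci.push_back(i); cj.push_back(j); }
    }
  }
  return List::create(_["pair_prob"] = P, _["ensemble_diversity"] = ed,
                      _["centroid_i"] = wrap(ci), _["centroid_j"] = wrap(cj));
}
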