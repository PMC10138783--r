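// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps.
// Among all optimal-score alignments the reported match count is the
// maximum attainable, so identity scores are deterministic.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

struct Cell { double s; double m; };  // score, max matches among optima

static inline void take_best(Cell &dst, double s, double m) {
  if (s > dst.s || (s == dst.s && m > dst.m)) { dst.s = s; dst.m = m; }
}

// returns (score, matches)
static Cell gotoh(const std::string &a, const std::string &b,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  // three-state DP over rows; M: a_i~b_j, X: gap in b, Y: gap in a
  std::vector<Cell> M0(m + 1), X0(m + 1), Y0(m + 1), M1(m + 1), X1(m + 1), Y1(m + 1);
  M0[0] = {0.0, 0.0}; X0[0] = {NEG, 0.0}; Y0[0] = {NEG, 0.0};
  for (int j = 1; j <= m; ++j) {
    Y0[j] = {gap_open + (j - 1) * gap_extend, 0.0};
    M0[j] = {NEG, 0.0}; X0[j] = {NEG, 0.0};
  }
  for (int i = 1; i <= n; ++i) {
    M1[0] = {NEG, 0.0}; Y1[0] = {NEG, 0.0};
    X1[0] = {gap_open + (i - 1) * gap_extend, 0.0};
    for (int j = 1; j <= m; ++j) {
      const bool eq = a[i - 1] == b[j - 1];
      const double s = eq ? match : mismatch;
      Cell best = {NEG, 0.0};
      take_best(best, M0[j - 1].s, M0[j - 1].m);
      take_best(best, X0[j - 1].s, X0[j - 1].m);
      take_best(best, Y0[j - 1].s, Y0[j - 1].m);
      M1[j] = {best.s + s, best.m + (eq ? 1.0 : 0.0)};

      Cell bx = {NEG, 0.0};
      take_best(bx, M0[j].s + gap_open, M0[j].m);
      take_best(bx, X0[j].s + gap_extend, X0[j].m);
      take_best(bx, Y0[j].s + gap_open, Y0[j].m);
      X1[j] = bx;

      Cell by = {NEG, 0.0};
      take_best(by, M1[j - 1].s + gap_open, M1[j - 1].m);
      take_best(by, X1[j - 1].s + gap_open, X1[j - 1].m);
      take_best(by, Y1[j - 1].s + gap_extend, Y1[j - 1].m);
      Y1[j] = by;
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  Cell fin = {NEG, 0.0};
  take_best(fin, M0[m].s, M0[m].m);
  take_best(fin, X0[m].s, X0[m].m);
  take_best(fin, Y0[m].s, Y0[m].m);
  return fin;
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
NumericVector nw_align_cpp(std::string a, std::string b,
                           double match, double mismatch,
                           double gap_open, double gap_extend) {
  Cell r = gotoh(a, b, match, mismatch, gap_open, gap_extend);
  return NumericVector::create(_["score"] = r.s, _["matches"] = r.m);
}

// All-pairs identity between two sets of strings.
// denom: 0 = mean length, 1 = shorter length.
// [[Rcpp::export(name = ".nw_identity_matrix_cpp")]]
NumericMatrix nw_identity_matrix_cpp(CharacterVector A, CharacterVector B,
                                     double match, double mismatch,
                                     double gap_open, double gap_extend,
                                     int denom) {
  const int n = A.size(), m = B.size();
  NumericMatrix out(n, m);
  std::vector<std::string> as(n), bs(m);
  for (int i = 0; i < n; ++i) as[i] = Rcpp::as<std::string>(A[i]);
  for (int j = 0; j < m; ++j) bs[j] = Rcpp::as<std::string>(B[j]);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      Cell r = gotoh(as[i], bs[j], match, mismatch, gap_open, gap_extend);
      double den = denom == 1
        ? std::min(as[i].size(), bs[j].size())
        : 0.5 * (as[i].size() + bs[j].size());
      out(i, j) = den > 0 ? r.m / den : 0.0;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
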