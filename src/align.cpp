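#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh). A gap of length L costs
// gap_open + L * gap_extend. Deterministic tie-breaking at equal score:
// match/mismatch over deletion over insertion (D = ref base vs read gap,
// I = read base vs ref gap). Returns score, CIGAR (M/D/I), match count and
// alignment length.
// [[Rcpp::export]]
List align_affine_cpp(std::string read, std::string ref,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = read.size(), m = ref.size();
  const double NEG = -1e18;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), D((n + 1) * W, NEG),
      I((n + 1) * W, NEG);
  auto at = [W](int i, int j) { return i * W + j; };

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) D[at(0, j)] = gap_open + gap_extend * j;
  for (int i = 1; i <= n; ++i) I[at(i, 0)] = gap_open + gap_extend * i;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      double prev = std::max(M[at(i - 1, j - 1)],
                    std::max(D[at(i - 1, j - 1)], I[at(i - 1, j - 1)]));
      M[at(i, j)] = prev + s;
      D[at(i, j)] = std::max(D[at(i, j - 1)] + gap_extend,
                    std::max(M[at(i, j - 1)], I[at(i, j - 1)]) +
                        gap_open + gap_extend);
      I[at(i, j)] = std::max(I[at(i - 1, j)] + gap_extend,
                    std::max(M[at(i - 1, j)], D[at(i - 1, j)]) +
                        gap_open + gap_extend);
    }
  }

  // final state: prefer M, then D, then I
  int i = n, j = m, state;
  double score;
  {
    double sm = M[at(n, m)], sd = D[at(n, m)], si = I[at(n, m)];
    score = std::max(sm, std::max(sd, si));
    state = (sm >= sd && sm >= si) ? 0 : (sd >= si ? 1 : 2);
  }

  std::string ops;
  ops.reserve(n + m);
  int n_match = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ops.push_back('M');
      if (read[i - 1] == ref[j - 1]) ++n_match;
      double target = M[at(i, j)] -
                      ((read[i - 1] == ref[j - 1]) ? match : mismatch);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[at(i, j)] == target) state = 0;
      else if (D[at(i, j)] == target) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back('D');
      double cur = D[at(i, j)];
      double close = cur - gap_open - gap_extend;
      double ext = cur - gap_extend;
      --j;
      if (M[at(i, j)] == close) state = 0;
      else if (D[at(i, j)] == ext) state = 1;
      else state = 2;
    } else {
      ops.push_back('I');
      double cur = I[at(i, j)];
      double close = cur - gap_open - gap_extend;
      double ext = cur - gap_extend;
      --i;
      if (M[at(i, j)] == close) state = 0;
      else if (D[at(i, j)] == ext) state = 1;
      else state = 2;
    }
    if (i == 0 && j == 0) break;
    if (i == 0 && state != 1) state = 1;  // only deletions remain
    if (j == 0 && state != 2) state = 2;  // only insertions remain
  }

  // run-length encode the reversed op string into a CIGAR
  std::string cigar;
  int len = ops.size();
  int k = len - 1;
  while (k >= 0) {
    char op = ops[k];
    int run = 0;
    while (k >= 0 && ops[k] == op) { ++run; --k; }
    cigar += std::to_string(run);
    cigar.push_back(op);
  }

  return List::create(_["score"] = score, _["cigar"] = cigar,
                      _["n_match"] = n_match, _["align_len"] = len);
}
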