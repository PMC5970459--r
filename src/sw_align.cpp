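#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman local alignment for short DNA sequences.
//
// Gap cost convention (BLAST-style): a gap of length k costs
// gap_open + k * gap_extend, so a 1-base gap costs gap_open + gap_extend.
//
// Determinism:
//  * the best cell is the first maximum encountered in row-major order
//    (smallest query end, then smallest subject end);
//  * traceback prefers diagonal (match/mismatch) over up (base consumed
//    from the query, gap in the subject) over left (gap in the query).
//
// Returned coordinates are 0-based half-open on query and subject.

static const double NEG = -1e18;

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = query.size(), m = subject.size();
  if (n == 0 || m == 0)
    stop("sequences must be non-empty");

  const double go = gap_open + gap_extend;  // cost of opening a 1-base gap
  const double ge = gap_extend;

  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { Ix(0, j) = NEG; Iy(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { Ix(i, 0) = NEG; Iy(i, 0) = NEG; }

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (query[i - 1] == subject[j - 1]) ? match : mismatch;
      double d = M(i - 1, j - 1);
      if (Ix(i - 1, j - 1) > d) d = Ix(i - 1, j - 1);
      if (Iy(i - 1, j - 1) > d) d = Iy(i - 1, j - 1);
      double mv = d + s;
      if (mv < 0.0) mv = 0.0;
      M(i, j) = mv;
      Ix(i, j) = std::max(M(i - 1, j) - go, Ix(i - 1, j) - ge);
      Iy(i, j) = std::max(M(i, j - 1) - go, Iy(i, j - 1) - ge);
      if (mv > best) { best = mv; bi = i; bj = j; }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0,
                        _["q_aln"] = "", _["s_aln"] = "");
  }

  // Traceback from (bi, bj) in state M until the running score reaches 0.
  std::string qa, sa;
  int i = bi, j = bj;
  int state = 0;  // 0 = M, 1 = Ix (up), 2 = Iy (left)
  while (true) {
    if (state == 0) {
      const double s = (query[i - 1] == subject[j - 1]) ? match : mismatch;
      qa.push_back(query[i - 1]);
      sa.push_back(subject[j - 1]);
      const double v = M(i, j) - s;
      --i; --j;
      if (v <= 0.0) break;  // local alignment starts here
      if (M(i, j) == v) state = 0;
      else if (Ix(i, j) == v) state = 1;
      else state = 2;
    } else if (state == 1) {
      qa.push_back(query[i - 1]);
      sa.push_back('-');
      const double v = Ix(i, j);
      state = (M(i - 1, j) - go == v) ? 0 : 1;
      --i;
    } else {
      qa.push_back('-');
      sa.push_back(subject[j - 1]);
      const double v = Iy(i, j);
      state = (M(i, j - 1) - go == v) ? 0 : 2;
      --j;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());

  return List::create(_["score"] = best,
                      _["q_start"] = i, _["q_end"] = bi,
                      _["s_start"] = j, _["s_end"] = bj,
                      _["q_aln"] = qa, _["s_aln"] = sa);
}
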