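#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman over pre-encoded sequences (1-based indices into
// the substitution matrix). A gap of length L costs gap_open + L * gap_extend.
// Alongside the score, the number of aligned columns of the optimal traceback
// is tracked; ties on score are broken toward the longest alignment by
// maximizing (score, length) lexicographically at every DP cell.

struct Cell {
  double score;
  int len;
};

static inline void take_max(Cell &best, double score, int len) {
  if (score > best.score || (score == best.score && len > best.len)) {
    best.score = score;
    best.len = len;
  }
}

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int n = q.size(), m = s.size();
  if (n == 0 || m == 0) {
    return List::create(_["score"] = 0.0, _["aln_len"] = 0);
  }
  const double open1 = gap_open + gap_extend;  // cost of a length-1 gap
  const double NEG = -1e300;

  std::vector<Cell> Hprev(m + 1, Cell{0.0, 0});
  std::vector<Cell> Hcur(m + 1, Cell{0.0, 0});
  std::vector<Cell> Fcol(m + 1, Cell{NEG, 0});  // vertical gap state per column
  Cell best{0.0, 0};

  for (int i = 1; i <= n; ++i) {
    Hcur[0] = Cell{0.0, 0};
    Cell E{NEG, 0};  // horizontal gap state along the current row
    for (int j = 1; j <= m; ++j) {
      // E(i,j): gap in the subject dimension (consumes q? no: consumes s)
      Cell e{NEG, 0};
      take_max(e, Hcur[j - 1].score - open1, Hcur[j - 1].len + 1);
      if (E.score > NEG) take_max(e, E.score - gap_extend, E.len + 1);
      E = e;

      // F(i,j): vertical gap state
      Cell f{NEG, 0};
      take_max(f, Hprev[j].score - open1, Hprev[j].len + 1);
      if (Fcol[j].score > NEG) take_max(f, Fcol[j].score - gap_extend, Fcol[j].len + 1);
      Fcol[j] = f;

      Cell h{0.0, 0};
      take_max(h, Hprev[j - 1].score + sub(q[i - 1] - 1, s[j - 1] - 1),
               Hprev[j - 1].len + 1);
      take_max(h, e.score, e.len);
      take_max(h, f.score, f.len);
      Hcur[j] = h;
      take_max(best, h.score, h.len);
    }
    std::swap(Hprev, Hcur);
  }
  return List::create(_["score"] = best.score, _["aln_len"] = best.len);
}
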