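#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).
// Gap cost model: a run of L gap columns costs gap_open + L * gap_extend
// (BLAST protein convention: open 11, extend 1 -> a single gap costs 12).
// Traceback tie-break in the match state: diagonal, then up (gap in target),
// then left (gap in query). Within a gap state the gap is closed as early as
// possible. The maximal cell is the lexicographically smallest (i, j) among
// score ties, so the reported alignment is fully deterministic.

static inline int imax3(int a, int b, int c) {
  return std::max(a, std::max(b, c));
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string target,
                  IntegerMatrix subst, IntegerVector char_index,
                  int gap_open, int gap_extend) {
  const int n = (int) query.size();
  const int m = (int) target.size();
  const int NEG = INT_MIN / 4;
  const int go = gap_open + gap_extend;  // cost of opening a length-1 gap
  const int ge = gap_extend;

  // residue -> substitution-matrix row, unknowns already mapped in R
  std::vector<int> qi(n), ti(m);
  for (int i = 0; i < n; ++i) qi[i] = char_index[(unsigned char) query[i]];
  for (int j = 0; j < m; ++j) ti[j] = char_index[(unsigned char) target[j]];

  std::vector<int> H((n + 1) * (m + 1), 0);
  std::vector<int> E((n + 1) * (m + 1), NEG);  // gap in query (left moves)
  std::vector<int> F((n + 1) * (m + 1), NEG);  // gap in target (up moves)
  const int W = m + 1;

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      E[idx] = std::max(H[idx - 1] - go, E[idx - 1] - ge);
      F[idx] = std::max(H[idx - W] - go, F[idx - W] - ge);
      const int diag = H[idx - W - 1] + subst(qi[i - 1], ti[j - 1]);
      int h = imax3(diag, F[idx], E[idx]);
      if (h < 0) h = 0;
      H[idx] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback
  std::vector<int> qpos, tpos;
  int gap_cols = 0;
  int i = bi, j = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    const int idx = i * W + j;
    if (state == 'H') {
      if (H[idx] == 0) break;
      const int diag = H[idx - W - 1] + subst(qi[i - 1], ti[j - 1]);
      if (H[idx] == diag) {
        qpos.push_back(i); tpos.push_back(j);
        --i; --j;
      } else if (H[idx] == F[idx]) {
        state = 'F';
      } else {
        state = 'E';
      }
    } else if (state == 'F') {
      const int idx2 = i * W + j;
      ++gap_cols;
      if (F[idx2] == H[idx2 - W] - go) state = 'H';
      --i;
    } else {  // E
      const int idx2 = i * W + j;
      ++gap_cols;
      if (E[idx2] == H[idx2 - 1] - go) state = 'H';
      --j;
    }
  }
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(tpos.begin(), tpos.end());

  return List::create(_["score"] = best,
                      _["query_pos"] = wrap(qpos),
                      _["target_pos"] = wrap(tpos),
                      _["gap_cols"] = gap_cols);
}

// score-only variant used for threshold calibration (no traceback state kept)
// [[Rcpp::export(name = ".sw_score_cpp")]]
int sw_score_cpp(std::string query, std::string target,
                 IntegerMatrix subst, IntegerVector char_index,
                 int gap_open, int gap_extend) {
  const int n = (int) query.size();
  const int m = (int) target.size();
  const int NEG = INT_MIN / 4;
  const int go = gap_open + gap_extend;
  const int ge = gap_extend;

  std::vector<int> qi(n), ti(m);
  for (int i = 0; i < n; ++i) qi[i] = char_index[(unsigned char) query[i]];
  for (int j = 0; j < m; ++j) ti[j] = char_index[(unsigned char) target[j]];

  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  std::vector<int> Fcur(m + 1, NEG), Fprev(m + 1, NEG);

  int best = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG; Fcur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      Ecur[j] = std::max(Hcur[j - 1] - go, Ecur[j - 1] - ge);
      Fcur[j] = std::max(Hprev[j] - go, Fprev[j] - ge);
      int h = imax3(Hprev[j - 1] + subst(qi[i - 1], ti[j - 1]), Ecur[j], Fcur[j]);
      if (h < 0) h = 0;
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
  }
  return best;
}
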