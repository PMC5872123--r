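#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
// Penalty convention: a gap of length L costs open + (L-1) * extend
// (the opening penalty covers the first gap residue).

static inline int imax3(int a, int b, int c) {
  return std::max(a, std::max(b, c));
}

// score-only SW, two-row memory
static int sw_score2(const std::vector<int>& a, const std::vector<int>& b,
                     const IntegerMatrix& S, int open, int extend) {
  const int n = (int)a.size(), m = (int)b.size();
  const int NEG = INT_MIN / 4;
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int F = NEG;
    Hcur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      Ecur[j] = std::max(Hprev[j] - open, Eprev[j] - extend); // gap in a
      F = std::max(Hcur[j - 1] - open, F - extend);           // gap in b
      int h = imax3(Hprev[j - 1] + S(a[i - 1], b[j - 1]), Ecur[j], F);
      if (h < 0) h = 0;
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  return best;
}

static std::vector<int> encode(const std::string& s) {
  // alphabet: ARNDCQEGHILKMFPSTWYVX -> 0..20
  static const std::string alpha = "ARNDCQEGHILKMFPSTWYVX";
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    size_t p = alpha.find(s[i]);
    if (p == std::string::npos)
      stop("illegal amino-acid character '%s' at position %d",
           std::string(1, s[i]).c_str(), (int)(i + 1));
    v[i] = (int)p;
  }
  return v;
}

// [[Rcpp::export(name = ".sw_score_one")]]
int sw_score_one(std::string a, std::string b, IntegerMatrix S,
                 int open, int extend) {
  return sw_score2(encode(a), encode(b), S, open, extend);
}

// Full DP with traceback; returns score, matches, alignment columns and
// the aligned spans on both sequences.
// [[Rcpp::export(name = ".sw_align_full")]]
List sw_align_full(std::string as, std::string bs, IntegerMatrix S,
                   int open, int extend) {
  std::vector<int> a = encode(as), b = encode(bs);
  const int n = (int)a.size(), m = (int)b.size();
  const int NEG = INT_MIN / 4;
  // 0 = H, 1 = E (gap in a / horizontal on b), 2 = F (gap in b)
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[at(i, j)] = std::max(H[at(i, j - 1)] - open, E[at(i, j - 1)] - extend);
      F[at(i, j)] = std::max(H[at(i - 1, j)] - open, F[at(i - 1, j)] - extend);
      int h = imax3(H[at(i - 1, j - 1)] + S(a[i - 1], b[j - 1]),
                    E[at(i, j)], F[at(i, j)]);
      if (h < 0) h = 0;
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int matches = 0, cols = 0;
  int i = bi, j = bj, qend = bi, tend = bj;
  int state = 0;
  while (i > 0 && j > 0 && !(state == 0 && H[at(i, j)] == 0)) {
    if (state == 0) {
      int h = H[at(i, j)];
      if (h == H[at(i - 1, j - 1)] + S(a[i - 1], b[j - 1])) {
        if (a[i - 1] == b[j - 1]) ++matches;
        ++cols; --i; --j;
      } else if (h == E[at(i, j)]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // gap in a, consume b
      ++cols;
      if (E[at(i, j)] == H[at(i, j - 1)] - open) state = 0;
      --j;
    } else {                  // gap in b, consume a
      ++cols;
      if (F[at(i, j)] == H[at(i - 1, j)] - open) state = 0;
      --i;
    }
  }
  int qstart = i + 1, tstart = j + 1;
  if (best == 0) { qstart = qend = tstart = tend = 0; cols = 0; }
  return List::create(
      _["score"] = best, _["matches"] = matches, _["columns"] = cols,
      _["query_start"] = qstart, _["query_end"] = qend,
      _["target_start"] = tstart, _["target_end"] = tend);
}

// Batch score computation over candidate index pairs (0-based into seqs).
// [[Rcpp::export(name = ".sw_score_batch")]]
IntegerVector sw_score_batch(CharacterVector seqs, IntegerMatrix pairs,
                             IntegerMatrix S, int open, int extend) {
  const int ns = seqs.size();
  std::vector<std::vector<int> > enc(ns);
  for (int k = 0; k < ns; ++k) enc[k] = encode(as<std::string>(seqs[k]));
  const int np = pairs.nrow();
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    out[p] = sw_score2(enc[pairs(p, 0)], enc[pairs(p, 1)], S, open, extend);
    if (p % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
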