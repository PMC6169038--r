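#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// Local alignment engine with affine gaps (Smith-Waterman semantics).
// A gap of length L costs gap_open + L * gap_extend.
// Bases are encoded A=0, C=1, G=2, T=3, anything else (incl. N) = 4;
// code 4 never matches, not even against itself.

static inline std::vector<uint8_t> encode_seq(const char *s, size_t n) {
  std::vector<uint8_t> v(n);
  for (size_t i = 0; i < n; ++i) {
    switch (s[i]) {
    case 'A': case 'a': v[i] = 0; break;
    case 'C': case 'c': v[i] = 1; break;
    case 'G': case 'g': v[i] = 2; break;
    case 'T': case 't': v[i] = 3; break;
    default: v[i] = 4;
    }
  }
  return v;
}

struct SwParams {
  int match, mismatch, gap_open, gap_extend;
};

static inline int subst(uint8_t a, uint8_t b, const SwParams &p) {
  return (a == b && a < 4) ? p.match : -p.mismatch;
}

// Score-only pass over the full DP matrix; O(n) memory.
// Returns best score and the 1-based (query, subject) end coordinates of the
// first best-scoring cell in row-major scan order (smallest query end, then
// smallest subject end), which makes tie resolution deterministic.
static void sw_score_pass(const std::vector<uint8_t> &q,
                           const std::vector<uint8_t> &s,
                           const SwParams &p,
                           int &best, int &best_i, int &best_j) {
  const int m = (int)q.size(), n = (int)s.size();
  const int NEG = INT32_MIN / 4;
  const int go = p.gap_open + p.gap_extend, ge = p.gap_extend;
  std::vector<int> H(n + 1, 0), E(n + 1, NEG);
  best = 0; best_i = 0; best_j = 0;
  for (int i = 1; i <= m; ++i) {
    int diag = 0;  // H[i-1][0]
    int hleft = 0; // H[i][j-1]
    int f = NEG;   // F[i][j-1] -> extended to F[i][j]
    const uint8_t qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int hup = H[j]; // H[i-1][j]
      int e = E[j] - ge;
      const int eo = hup - go;
      if (eo > e) e = eo;           // E[i][j]: gap in query
      int fo = hleft - go;
      f = (f - ge > fo) ? f - ge : fo; // F[i][j]: gap in subject
      int h = diag + ((qi == s[j - 1] && qi < 4) ? p.match : -p.mismatch);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E[j] = e;
      diag = hup;
      hleft = h;
      H[j] = h;
      if (h > best) { best = h; best_i = i; best_j = j; }
    }
  }
}

// Four interleaved score passes over the same subject. The four DP chains are
// independent, which exposes instruction-level parallelism / SIMD that a
// single chain cannot. Queries shorter than the longest in the group are
// padded with code 5 (a base that never matches anything); trailing columns
// involving a pad char can only lower an alignment's score, so padded rows
// can never claim the recorded optimum (updates require a strictly greater
// score). Results are identical to the scalar pass.
static void sw_score_pass4(const uint8_t *const q[4], const int mlen[4],
                           const std::vector<uint8_t> &s, const SwParams &p,
                           int best[4], int best_i[4], int best_j[4]) {
  const int n = (int)s.size();
  int m = 0;
  for (int k = 0; k < 4; ++k) m = std::max(m, mlen[k]);
  const int NEG = INT32_MIN / 4;
  const int go = p.gap_open + p.gap_extend, ge = p.gap_extend;
  std::vector<int> H(4 * (n + 1), 0), E(4 * (n + 1), NEG);
  for (int k = 0; k < 4; ++k) { best[k] = 0; best_i[k] = 0; best_j[k] = 0; }
  for (int i = 1; i <= m; ++i) {
    int diag[4] = {0, 0, 0, 0};
    int hleft[4] = {0, 0, 0, 0};
    int f[4] = {NEG, NEG, NEG, NEG};
    int qi[4];
    for (int k = 0; k < 4; ++k)
      qi[k] = (i <= mlen[k]) ? q[k][i - 1] : 5;
    const uint8_t *sp = s.data();
    for (int j = 1; j <= n; ++j) {
      const int sj = sp[j - 1];
      int h4[4];
      for (int k = 0; k < 4; ++k) {
        int *Hk = &H[4 * j], *Ek = &E[4 * j];
        const int hup = Hk[k];
        int e = Ek[k] - ge;
        const int eo = hup - go;
        if (eo > e) e = eo;
        const int fo = hleft[k] - go;
        f[k] = (f[k] - ge > fo) ? f[k] - ge : fo;
        int h = diag[k] + ((qi[k] == sj && qi[k] < 4) ? p.match : -p.mismatch);
        if (e > h) h = e;
        if (f[k] > h) h = f[k];
        if (h < 0) h = 0;
        Ek[k] = e;
        diag[k] = hup;
        hleft[k] = h;
        Hk[k] = h;
        h4[k] = h;
      }
      for (int k = 0; k < 4; ++k)
        if (h4[k] > best[k]) { best[k] = h4[k]; best_i[k] = i; best_j[k] = j; }
    }
  }
}

// [[Rcpp::export(name = ".sw_scores")]]
IntegerMatrix sw_scores_cpp(CharacterVector queries, std::string subject,
                            int match, int mismatch, int gap_open,
                            int gap_extend) {
  SwParams p{match, mismatch, gap_open, gap_extend};
  std::vector<uint8_t> s = encode_seq(subject.c_str(), subject.size());
  const int nq = queries.size();
  IntegerMatrix out(nq, 3);
  colnames(out) = CharacterVector::create("score", "q_end", "s_end");
  std::vector<std::vector<uint8_t> > enc(4);
  for (int k0 = 0; k0 < nq; k0 += 4) {
    const int nb = std::min(4, nq - k0);
    const uint8_t *qp[4];
    int mlen[4];
    for (int k = 0; k < 4; ++k) {
      const int src = k0 + (k < nb ? k : 0); // duplicate first query as filler
      enc[k] = encode_seq(CHAR(STRING_ELT(queries, src)),
                          LENGTH(STRING_ELT(queries, src)));
      qp[k] = enc[k].data();
      mlen[k] = (int)enc[k].size();
    }
    int b[4], bi[4], bj[4];
    if (nb == 1) {
      sw_score_pass(enc[0], s, p, b[0], bi[0], bj[0]);
    } else {
      sw_score_pass4(qp, mlen, s, p, b, bi, bj);
    }
    for (int k = 0; k < nb; ++k) {
      out(k0 + k, 0) = b[k];
      out(k0 + k, 1) = bi[k];
      out(k0 + k, 2) = bj[k];
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Global (Needleman-Wunsch) alignment of q[si..ei) vs s[sj..ej) with the same
// affine scheme and *no* clamping at zero; the optimal local alignment ending
// at (ei, ej) and starting at (si, sj) is the optimal global alignment of
// those substrings, so traceback over this small rectangle recovers it.
static List nw_traceback(const std::vector<uint8_t> &q,
                         const std::vector<uint8_t> &s,
                         int si, int ei, int sj, int ej, const SwParams &p) {
  const int m = ei - si, n = ej - sj;
  const int NEG = INT32_MIN / 4;
  const int go = p.gap_open + p.gap_extend, ge = p.gap_extend;
  std::vector<int> H((m + 1) * (n + 1), NEG), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  H[at(0, 0)] = 0;
  for (int j = 1; j <= n; ++j) {
    E[at(0, j)] = (j == 1 ? H[at(0, 0)] - go : E[at(0, j - 1)] - ge);
    H[at(0, j)] = E[at(0, j)];
  }
  for (int i = 1; i <= m; ++i) {
    F[at(i, 0)] = (i == 1 ? H[at(0, 0)] - go : F[at(i - 1, 0)] - ge);
    H[at(i, 0)] = F[at(i, 0)];
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[at(i, j - 1)] - go, E[at(i, j - 1)] - ge);
      int f = std::max(H[at(i - 1, j)] - go, F[at(i - 1, j)] - ge);
      int d = H[at(i - 1, j - 1)] + subst(q[si + i - 1], s[sj + j - 1], p);
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = std::max(d, std::max(e, f));
    }
  }
  // traceback from (m, n)
  int i = m, j = n;
  int n_ident = 0, n_mismatch = 0, n_gapopen = 0, gap_cols = 0, aln_len = 0;
  int state = 0; // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i > 0 && j > 0 &&
          H[at(i, j)] == H[at(i - 1, j - 1)] + subst(q[si + i - 1], s[sj + j - 1], p)) {
        if (subst(q[si + i - 1], s[sj + j - 1], p) == p.match) ++n_ident;
        else ++n_mismatch;
        ++aln_len; --i; --j;
      } else if (j > 0 && H[at(i, j)] == E[at(i, j)]) {
        state = 1;
      } else if (i > 0 && H[at(i, j)] == F[at(i, j)]) {
        state = 2;
      } else {
        stop("alignment traceback failed (internal error)");
      }
    } else if (state == 1) {
      ++aln_len; ++gap_cols;
      if (E[at(i, j)] == E[at(i, j - 1)] - ge && j > 1) { --j; }
      else { ++n_gapopen; --j; state = 0; }
    } else {
      ++aln_len; ++gap_cols;
      if (F[at(i, j)] == F[at(i - 1, j)] - ge && i > 1) { --i; }
      else { ++n_gapopen; --i; state = 0; }
    }
  }
  return List::create(_["n_ident"] = n_ident, _["n_mismatch"] = n_mismatch,
                      _["n_gapopen"] = n_gapopen, _["gap_cols"] = gap_cols,
                      _["aln_length"] = aln_len, _["score"] = H[at(m, n)]);
}

// Given the end cell of the best local alignment (1-based inclusive, from
// .sw_scores), find its start by running the score pass on the reversed
// prefixes, then recover column counts by traceback over the small rectangle.
// [[Rcpp::export(name = ".sw_extend")]]
List sw_extend_cpp(std::string query, std::string subject, int q_end,
                   int s_end, int match, int mismatch, int gap_open,
                   int gap_extend) {
  SwParams p{match, mismatch, gap_open, gap_extend};
  std::vector<uint8_t> q = encode_seq(query.c_str(), query.size());
  std::vector<uint8_t> s = encode_seq(subject.c_str(), subject.size());
  if (q_end < 1 || s_end < 1 || q_end > (int)q.size() || s_end > (int)s.size())
    stop("alignment end coordinates out of range");
  std::vector<uint8_t> qr(q.begin(), q.begin() + q_end);
  std::vector<uint8_t> sr(s.begin(), s.begin() + s_end);
  std::reverse(qr.begin(), qr.end());
  std::reverse(sr.begin(), sr.end());
  int b, bi, bj;
  sw_score_pass(qr, sr, p, b, bi, bj);
  const int q_start = q_end - bi; // 0-based start
  const int s_start = s_end - bj;
  List tb = nw_traceback(q, s, q_start, q_end, s_start, s_end, p);
  tb["q_start"] = q_start;
  tb["q_end"] = q_end;
  tb["s_start"] = s_start;
  tb["s_end"] = s_end;
  return tb;
}
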