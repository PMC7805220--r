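#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (gap of length L costs
// open + L * ext, the BLAST convention). Sequences arrive as 0-based index
// vectors into the substitution matrix rows/cols.
//
// Traceback preference on score ties: diagonal > up (gap in subject) >
// left (gap in query); the traceback anchor is the first maximal cell in
// row-major order, which fixes coordinates deterministically.

struct AlnResult {
  int score, q_start, q_end, s_start, s_end, matches, aln_len, gap_opens;
};

static AlnResult sw_core(const int *q, int m, const int *s, int n,
                         const IntegerMatrix &sub, int go, int ge) {
  const int NEG = -1000000000;
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> U((m + 1) * (n + 1), NEG);  // gap in subject (consumes query)
  std::vector<int> L((m + 1) * (n + 1), NEG);  // gap in query (consumes subject)
  int best = 0, bi = 0, bj = 0;
  const int W = n + 1;
  for (int i = 1; i <= m; ++i) {
    const int qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j;
      int u = H[(i - 1) * W + j] - go - ge;
      int u2 = U[(i - 1) * W + j] - ge;
      U[idx] = u >= u2 ? u : u2;
      int l = H[i * W + (j - 1)] - go - ge;
      int l2 = L[i * W + (j - 1)] - ge;
      L[idx] = l >= l2 ? l : l2;
      int d = H[(i - 1) * W + (j - 1)] + sub(qi, s[j - 1]);
      int h = 0;
      if (d > h) h = d;
      if (U[idx] > h) h = U[idx];
      if (L[idx] > h) h = L[idx];
      H[idx] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  AlnResult r;
  r.score = best;
  r.matches = 0; r.aln_len = 0; r.gap_opens = 0;
  if (best == 0) {
    r.q_start = r.q_end = r.s_start = r.s_end = 0;
    return r;
  }
  // traceback; state 0 = H, 1 = U (up), 2 = L (left)
  int i = bi, j = bj, state = 0;
  r.q_end = bi; r.s_end = bj;
  while (true) {
    const int idx = i * W + j;
    if (state == 0) {
      if (H[idx] == 0) break;
      int d = H[(i - 1) * W + (j - 1)] + sub(q[i - 1], s[j - 1]);
      if (H[idx] == d) {
        if (q[i - 1] == s[j - 1]) r.matches++;
        r.aln_len++;
        i--; j--;
      } else if (H[idx] == U[idx]) {
        state = 1;
        r.gap_opens++;
      } else {
        state = 2;
        r.gap_opens++;
      }
    } else if (state == 1) {
      // in a gap consuming query rows
      r.aln_len++;
      int from_h = H[(i - 1) * W + j] - go - ge;
      bool close = (U[idx] == from_h);
      i--;
      if (close) state = 0;
    } else {
      r.aln_len++;
      int from_h = H[i * W + (j - 1)] - go - ge;
      bool close = (L[idx] == from_h);
      j--;
      if (close) state = 0;
    }
  }
  r.q_start = i; r.s_start = j;  // 0-based half-open with q_end/s_end
  return r;
}

// [[Rcpp::export]]
IntegerVector sw_align_pair_cpp(IntegerVector q, IntegerVector s,
                                IntegerMatrix sub, int gap_open, int gap_ext) {
  AlnResult r = sw_core(q.begin(), q.size(), s.begin(), s.size(),
                        sub, gap_open, gap_ext);
  return IntegerVector::create(r.score, r.q_start, r.q_end, r.s_start,
                               r.s_end, r.matches, r.aln_len, r.gap_opens);
}

// Score-only Smith-Waterman: rolling one-row buffers, no traceback, no
// per-pair allocation. Used as the fast first pass; survivors get the
// full traceback via sw_align_batch_cpp.
// [[Rcpp::export]]
IntegerVector sw_score_batch_cpp(List seqs_q, List seqs_s,
                                 IntegerVector qi, IntegerVector si,
                                 IntegerMatrix sub, int gap_open, int gap_ext) {
  const int np = qi.size();
  IntegerVector out(np);
  const int *subp = sub.begin();
  const int nalpha = sub.nrow();
  std::vector<int> H, U;
  for (int k = 0; k < np; ++k) {
    IntegerVector q = seqs_q[qi[k] - 1];
    IntegerVector s = seqs_s[si[k] - 1];
    const int m = q.size(), n = s.size();
    if ((int)H.size() < n + 1) { H.resize(n + 1); U.resize(n + 1); }
    std::fill(H.begin(), H.begin() + n + 1, 0);
    std::fill(U.begin(), U.begin() + n + 1, -1000000000);
    int best = 0;
    const int go = gap_open + gap_ext, ge = gap_ext;
    const int *sp = s.begin();
    for (int i = 1; i <= m; ++i) {
      const int *subrow = subp + q[i - 1];
      int diag = H[0];  // H[i-1][0] = 0
      int h_prev = 0;   // H[i][0]
      int l_prev = -1000000000;
      for (int j = 1; j <= n; ++j) {
        int up = H[j] - go;
        int u2 = U[j] - ge;
        int u = up >= u2 ? up : u2;
        U[j] = u;
        int lo = h_prev - go;
        int l2 = l_prev - ge;
        int l = lo >= l2 ? lo : l2;
        l_prev = l;
        int d = diag + subrow[(size_t)sp[j - 1] * nalpha];
        int h = 0;
        if (d > h) h = d;
        if (u > h) h = u;
        if (l > h) h = l;
        diag = H[j];
        H[j] = h;
        h_prev = h;
        if (h > best) best = h;
      }
    }
    out[k] = best;
    if (k % 16384 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Batch interface: seqs is a list of encoded integer vectors; qi/si are
// 1-based indices of the pairs to align. Returns an 8-column matrix.
// [[Rcpp::export]]
IntegerMatrix sw_align_batch_cpp(List seqs_q, List seqs_s,
                                 IntegerVector qi, IntegerVector si,
                                 IntegerMatrix sub, int gap_open, int gap_ext) {
  const int np = qi.size();
  IntegerMatrix out(np, 8);
  for (int k = 0; k < np; ++k) {
    IntegerVector q = seqs_q[qi[k] - 1];
    IntegerVector s = seqs_s[si[k] - 1];
    AlnResult r = sw_core(q.begin(), q.size(), s.begin(), s.size(),
                          sub, gap_open, gap_ext);
    out(k, 0) = r.score;   out(k, 1) = r.q_start; out(k, 2) = r.q_end;
    out(k, 3) = r.s_start; out(k, 4) = r.s_end;   out(k, 5) = r.matches;
    out(k, 6) = r.aln_len; out(k, 7) = r.gap_opens;
    if (k % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Local profile-to-sequence alignment with affine gaps, double scores.
// prof: ncols x alphabet matrix of per-position scores.
// [[Rcpp::export]]
NumericVector profile_align_cpp(NumericMatrix prof, IntegerVector s,
                                double go, double ge) {
  const int m = prof.nrow(), n = s.size();
  const double NEG = -1e30;
  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> U((m + 1) * (n + 1), NEG);
  std::vector<double> L((m + 1) * (n + 1), NEG);
  double best = 0.0;
  int bi = 0, bj = 0;
  const int W = n + 1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j;
      double u = H[(i - 1) * W + j] - go - ge;
      double u2 = U[(i - 1) * W + j] - ge;
      U[idx] = u >= u2 ? u : u2;
      double l = H[i * W + (j - 1)] - go - ge;
      double l2 = L[i * W + (j - 1)] - ge;
      L[idx] = l >= l2 ? l : l2;
      double d = H[(i - 1) * W + (j - 1)] + prof(i - 1, s[j - 1]);
      double h = 0.0;
      if (d > h) h = d;
      if (U[idx] > h) h = U[idx];
      if (L[idx] > h) h = L[idx];
      H[idx] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // simple backtrace for start coordinates (score ties: diagonal first)
  int i = bi, j = bj, state = 0;
  if (best > 0.0) {
    while (true) {
      const int idx = i * W + j;
      if (state == 0) {
        if (H[idx] <= 0.0) break;
        double d = H[(i - 1) * W + (j - 1)] + prof(i - 1, s[j - 1]);
        if (H[idx] == d) { i--; j--; }
        else if (H[idx] == U[idx]) state = 1;
        else state = 2;
      } else if (state == 1) {
        bool close = (U[idx] == H[(i - 1) * W + j] - go - ge);
        i--;
        if (close) state = 0;
      } else {
        bool close = (L[idx] == H[i * W + (j - 1)] - go - ge);
        j--;
        if (close) state = 0;
      }
    }
  }
  return NumericVector::create(best, (double)i, (double)bi,
                               (double)j, (double)bj);
}
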