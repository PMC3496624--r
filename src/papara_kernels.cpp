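#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Infinity sentinel: half the max representable value of the score width,
// so adding any penalty cannot overflow.
static inline int sentinel_for(int score_width) {
  return score_width == 16 ? (32767 / 2) : (INT_MAX / 2);
}

// Sequential reference kernel: semi-global scoring of one query against one
// ancestral state profile with single-row storage.
//
// Recurrence (lower is better), column i = reference site, row j = query
// position:
//   CG_i = cgap_penalty if cgap[i] else 0
//   (GPOE_i, GPE_i) = gap_open_extend, replaced by the cgap pair at CGAP
//       sites
//   M_{i,j} = 0 if state sets intersect else mismatch
//   I_{i,j} = S_{i,j-1} + insertion
//   D_{i,j} = min(S_{i-1,j} + GPOE_i, D_{i-1,j} + GPE_i)
//   S_{i,j} = min(S_{i-1,j-1} + M_{i,j} + CG_i, D_{i,j}, I_{i,j})
// Boundaries: S_{i,0} = 0 (free reference prefix), S_{0,j} = j*insertion,
// D_{0,j} = infinity sentinel; result = min_i S_{i,m} (free suffix).
// [[Rcpp::export]]
int cpp_score_alignment(IntegerVector states, LogicalVector cgap,
                        IntegerVector query,
                        int mismatch, int cgap_penalty,
                        int gpoe, int gpe, int gpoe_cg, int gpe_cg,
                        int insertion) {
  const int n = states.size(), m = query.size();
  const int INF = INT_MAX / 2;
  std::vector<int> S(n + 1, 0);  // row j-1, then overwritten in place
  int best = INF;
  for (int j = 1; j <= m; ++j) {
    const int qs = query[j - 1];
    int diag = S[0];          // S[0, j-1]
    S[0] = j * insertion;     // S[0, j]
    int dprev = INF;          // D[0, j]
    int sprev = S[0];         // S[i-1, j]
    for (int i = 1; i <= n; ++i) {
      const bool cg = cgap[i - 1];
      const int go = cg ? gpoe_cg : gpoe;
      const int ge = cg ? gpe_cg : gpe;
      const int cgi = cg ? cgap_penalty : 0;
      const int match = (states[i - 1] & qs) ? 0 : mismatch;
      int d = std::min(sprev + go, dprev + ge);
      if (d > INF) d = INF;
      const int oldSi = S[i];               // S[i, j-1]
      int s = diag + match + cgi;
      if (d < s) s = d;
      const int ins = oldSi + insertion;    // I_{i,j}
      if (ins < s) s = ins;
      S[i] = s;
      diag = oldSi;
      dprev = d;
      sprev = s;
      if (j == m && s < best) best = s;
    }
  }
  return best;
}

// W-lane batch kernel over the site-major inter-reference layout, computed
// block-by-block over column ranges of the schedule (a single block spanning
// all columns reproduces the straightforward row-by-row order).  Only the
// current row of the active block plus the per-row boundary columns of the
// previous block are kept, mirroring the single-line storage of the
// sequential kernel.  Lane k's final minimum is restricted to its true
// reference length so match-all padding sites never contribute.
//
// In 16-bit mode any lane whose stored S value reaches the 16-bit sentinel
// is flagged as overflowed (its score is unreliable and must be recomputed
// at 32 bits); values are clamped at the sentinel so arithmetic cannot wrap.
// [[Rcpp::export]]
List cpp_batch_score(IntegerVector inter_states, LogicalVector inter_cgap,
                     int W, int n_max, IntegerVector lane_len,
                     LogicalVector valid,
                     IntegerVector query,
                     int mismatch, int cgap_penalty,
                     int gpoe, int gpe, int gpoe_cg, int gpe_cg,
                     int insertion,
                     IntegerVector block_start, IntegerVector block_end,
                     int score_width) {
  const int m = query.size();
  const int INF = sentinel_for(score_width);
  const int nb = block_start.size();
  if (inter_states.size() != (R_xlen_t)n_max * W)
    stop("interleaved state vector has wrong length");

  // per-row boundary columns carried between blocks:
  // carryS[j*W+k] = S[a-1, j] of lane k (a = current block start),
  // carryD likewise.  Row 0 boundary is S[i,0] = 0 for every i.
  std::vector<int> carryS((m + 1) * W), carryD((m + 1) * W, INF);
  for (int j = 0; j <= m; ++j) {
    int v = j * insertion;        // S[0, j]
    if (v > INF) v = INF;
    for (int k = 0; k < W; ++k) carryS[j * W + k] = v;
  }
  for (int k = 0; k < W; ++k) carryS[k] = 0;  // S[0,0] = 0 (row 0 is free)

  std::vector<int> best(W, INF);
  std::vector<bool> oflow(W, false);

  int max_bw = 0;
  for (int b = 0; b < nb; ++b)
    max_bw = std::max(max_bw, block_end[b] - block_start[b]);
  std::vector<int> Sprev((size_t)max_bw * W), Scur((size_t)max_bw * W);
  std::vector<int> drun(W), sleft(W), diag0(W), prev_bound(W);

  for (int b = 0; b < nb; ++b) {
    const int a = block_start[b];
    const int bw = block_end[b] - a;
    if (bw <= 0) continue;
    // row 0 of this block: S[a+t, 0] = 0
    std::fill(Sprev.begin(), Sprev.begin() + (size_t)bw * W, 0);
    for (int k = 0; k < W; ++k) prev_bound[k] = (a == 0) ? 0 : 0;
    // prev_bound holds S[a-1, j-1]; for j = 1 that is S[a-1, 0] = 0.
    for (int j = 1; j <= m; ++j) {
      const int qs = query[j - 1];
      for (int k = 0; k < W; ++k) {
        diag0[k] = prev_bound[k];          // S[a-1, j-1]
        drun[k] = carryD[j * W + k];       // D[a-1, j]
        sleft[k] = carryS[j * W + k];      // S[a-1, j]
      }
      for (int t = 0; t < bw; ++t) {
        const int site = a + t;
        const int base = site * W;
        const int rbase = t * W;
        for (int k = 0; k < W; ++k) {
          const bool cg = inter_cgap[base + k];
          const int go = cg ? gpoe_cg : gpoe;
          const int ge = cg ? gpe_cg : gpe;
          const int cgi = cg ? cgap_penalty : 0;
          const int match = (inter_states[base + k] & qs) ? 0 : mismatch;
          int d = std::min(sleft[k] + go, drun[k] + ge);
          if (d > INF) d = INF;
          const int sdiag = (t == 0) ? diag0[k] : Sprev[rbase - W + k];
          int s = sdiag + match + cgi;
          if (d < s) s = d;
          const int ins = Sprev[rbase + k] + insertion;
          if (ins < s) s = ins;
          if (s >= INF) { s = INF; oflow[k] = true; }
          Scur[rbase + k] = s;
          drun[k] = d;
          sleft[k] = s;
          if (j == m && site < lane_len[k] && s < best[k]) best[k] = s;
        }
      }
      for (int k = 0; k < W; ++k) {
        prev_bound[k] = carryS[j * W + k];       // old S[a-1, j]
        carryS[j * W + k] = Scur[(size_t)(bw - 1) * W + k];
        carryD[j * W + k] = drun[k];
      }
      std::swap(Sprev, Scur);
    }
  }

  IntegerVector scores(W);
  LogicalVector overflow(W);
  for (int k = 0; k < W; ++k) {
    scores[k] = valid[k] ? best[k] : INF;
    overflow[k] = valid[k] ? (bool)oflow[k] : false;
  }
  return List::create(_["scores"] = scores, _["overflow"] = overflow,
                      _["sentinel"] = INF);
}
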