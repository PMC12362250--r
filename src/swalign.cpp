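#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Smith-Waterman-Gotoh local alignment with affine gaps.
// A gap of length L scores gap_open + (L - 1) * gap_extend (penalties <= 0),
// i.e. the open penalty covers the first gapped base.
// Tie-breaks are fixed so output is reproducible:
//  - the best cell is the one with the smallest reference end, then the
//    smallest read end;
//  - traceback prefers diagonal, then the ref-gap state (deletion from the
//    read's perspective: reference base unmatched), then the read-gap state.

static const int NEG = -1000000000;

// [[Rcpp::export]]
List sw_align_cpp(std::string read, std::string ref, int match, int mismatch,
                  int gap_open, int gap_extend) {
  const int n = (int)read.size(), m = (int)ref.size();
  if (n == 0 || m == 0) stop("empty sequence");
  // H: best local score ending at (i, j); E: ending with ref consumed /
  // read gap (deletion); F: ending with read consumed / ref gap (insertion).
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int e = std::max(H[at(i, j - 1)] + gap_open, E[at(i, j - 1)] + gap_extend);
      int f = std::max(H[at(i - 1, j)] + gap_open, F[at(i - 1, j)] + gap_extend);
      int s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      int d = H[at(i - 1, j - 1)] + s;
      int h = std::max(0, std::max(d, std::max(e, f)));
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
    }
  }
  // best cell: strictly greater keeps the first hit scanning j (ref end)
  // outer, i (read end) inner => smallest ref end, then smallest read end.
  int best = 0, bi = 0, bj = 0;
  for (int j = 1; j <= m; ++j)
    for (int i = 1; i <= n; ++i)
      if (H[at(i, j)] > best) { best = H[at(i, j)]; bi = i; bj = j; }

  std::vector<int> rpos, qpos, op; // op: 0 match, 1 mismatch, 2 ins, 3 del
  int i = bi, j = bj, state = 0;   // 0 = H, 1 = E, 2 = F
  while (best > 0 && (i > 0 || j > 0)) {
    if (state == 0) {
      int h = H[at(i, j)];
      if (h == 0) break;
      int s = (i > 0 && j > 0 && read[i - 1] == ref[j - 1]) ? match : mismatch;
      if (i > 0 && j > 0 && h == H[at(i - 1, j - 1)] + s) {
        qpos.push_back(i - 1); rpos.push_back(j - 1);
        op.push_back(read[i - 1] == ref[j - 1] ? 0 : 1);
        --i; --j;
      } else if (j > 0 && h == E[at(i, j)]) {
        state = 1;
      } else if (i > 0 && h == F[at(i, j)]) {
        state = 2;
      } else {
        stop("traceback failure"); // unreachable
      }
    } else if (state == 1) { // deletion: ref base j-1 against gap
      qpos.push_back(-1); rpos.push_back(j - 1); op.push_back(3);
      int e = E[at(i, j)];
      if (e == H[at(i, j - 1)] + gap_open) state = 0;
      --j;
    } else { // insertion: read base i-1 against gap
      qpos.push_back(i - 1); rpos.push_back(-1); op.push_back(2);
      int f = F[at(i, j)];
      if (f == H[at(i - 1, j)] + gap_open) state = 0;
      --i;
    }
  }
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(rpos.begin(), rpos.end());
  std::reverse(op.begin(), op.end());
  return List::create(_["score"] = best,
                      _["read_pos"] = IntegerVector(qpos.begin(), qpos.end()),
                      _["ref_pos"] = IntegerVector(rpos.begin(), rpos.end()),
                      _["op"] = IntegerVector(op.begin(), op.end()),
                      _["read_start"] = best > 0 ? i : 0,
                      _["read_end"] = best > 0 ? bi : 0,
                      _["ref_start"] = best > 0 ? j : 0,
                      _["ref_end"] = best > 0 ? bj : 0);
}
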