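#include <Rcpp.h>
using namespace Rcpp;

// Semi-global (glocal) scan of a monomer consensus against a chromosome.
//
// Classic column-wise edit-distance DP with free start/end in the text and
// the full consensus consumed.  For every text end position j (1-based,
// inclusive) whose minimal alignment cost is <= emax we emit one candidate
// (start0, end, cost), where start0 is the 0-based window start.  Among
// co-optimal alignments ending at j the largest start (shortest window) is
// kept; the (cost, -start) pair is optimized lexicographically cell by cell,
// which is exact because every prefix of an optimal path is optimal.
//
// [[Rcpp::export]]
List scan_motif_cpp(std::string text, std::string motif, int emax) {
  const int n = (int) text.size(), L = (int) motif.size();
  std::vector<int> cost(L + 1), st(L + 1), ncost(L + 1), nst(L + 1);
  for (int i = 0; i <= L; ++i) { cost[i] = i; st[i] = 0; }
  std::vector<int> outS, outE, outC;
  for (int j = 1; j <= n; ++j) {
    ncost[0] = 0; nst[0] = j;
    const char tc = text[j - 1];
    for (int i = 1; i <= L; ++i) {
      int c = cost[i - 1] + (motif[i - 1] == tc ? 0 : 1);  // diagonal
      int s = st[i - 1];
      const int cu = ncost[i - 1] + 1;   // gap in text (consensus base deleted)
      if (cu < c || (cu == c && nst[i - 1] > s)) { c = cu; s = nst[i - 1]; }
      const int cl = cost[i] + 1;        // gap in consensus (text base inserted)
      if (cl < c || (cl == c && st[i] > s)) { c = cl; s = st[i]; }
      ncost[i] = c; nst[i] = s;
    }
    if (ncost[L] <= emax) {
      outS.push_back(nst[L]); outE.push_back(j); outC.push_back(ncost[L]);
    }
    std::swap(cost, ncost);
    std::swap(st, nst);
  }
  return List::create(_["start0"] = wrap(outS), _["end"] = wrap(outE),
                      _["cost"] = wrap(outC));
}
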