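#include <Rcpp.h>
using namespace Rcpp;

// Semi-global scan of a short adaptor tail inside a search window.
//
// For every 0-based end position j (exclusive, i.e. the first base after the
// alignment) the DP computes the minimal unit-cost edit distance of the FULL
// adaptor against a window substring ending at j, with a free start anywhere
// in the window.  Any window character outside {A,C,G,T} (e.g. N) counts as a
// mismatch against every adaptor base.
//
// Candidate end positions with cost <= max_ed are then collapsed: runs of
// candidates whose consecutive end positions differ by <= gap keep only the
// cheapest placement (ties: smallest end position).  Placements further apart
// than gap remain distinct candidates.
//
// Returns, per window, an integer matrix with columns end_pos (0-based) and
// edit_dist.
// [[Rcpp::export]]
List scan_adaptor(CharacterVector windows, std::string adaptor,
                  int max_ed, int gap) {
  const int m = adaptor.size();
  const int nw = windows.size();
  List out(nw);
  IntegerMatrix empty(0, 2);
  colnames(empty) = CharacterVector::create("end_pos", "edit_dist");

  for (int w = 0; w < nw; ++w) {
    if (windows[w] == NA_STRING) { out[w] = empty; continue; }
    std::string s = as<std::string>(windows[w]);
    const int L = s.size();
    if (L == 0) { out[w] = empty; continue; }

    std::vector<int> prev(L + 1, 0), cur(L + 1, 0);  // free start: row 0 all 0
    for (int i = 1; i <= m; ++i) {
      cur[0] = i;
      const char a = adaptor[i - 1];
      for (int j = 1; j <= L; ++j) {
        const char c = s[j - 1];
        const bool match = (c == a) &&
          (c == 'A' || c == 'C' || c == 'G' || c == 'T');
        int v = prev[j - 1] + (match ? 0 : 1);
        if (prev[j] + 1 < v) v = prev[j] + 1;   // adaptor base unmatched
        if (cur[j - 1] + 1 < v) v = cur[j - 1] + 1;  // extra window base
        cur[j] = v;
      }
      std::swap(prev, cur);
    }

    std::vector<int> pos, cost;
    for (int j = 0; j <= L; ++j)
      if (prev[j] <= max_ed) { pos.push_back(j); cost.push_back(prev[j]); }
    if (pos.empty()) { out[w] = empty; continue; }

    std::vector<int> kp, kc;
    size_t start = 0;
    for (size_t k = 1; k <= pos.size(); ++k) {
      if (k == pos.size() || pos[k] - pos[k - 1] > gap) {
        size_t best = start;
        for (size_t t = start + 1; t < k; ++t)
          if (cost[t] < cost[best]) best = t;
        kp.push_back(pos[best]);
        kc.push_back(cost[best]);
        start = k;
      }
    }
    IntegerMatrix res(kp.size(), 2);
    for (size_t t = 0; t < kp.size(); ++t) {
      res(t, 0) = kp[t];
      res(t, 1) = kc[t];
    }
    colnames(res) = CharacterVector::create("end_pos", "edit_dist");
    out[w] = res;
  }
  return out;
}
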