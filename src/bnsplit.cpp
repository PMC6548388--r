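#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Union-find (union by size, path halving) over nodes 1..n.
// ia/ib are parallel 1-based endpoint vectors of the edges.
// Returns the root representative of each node 1..n.
// [[Rcpp::export]]
IntegerVector uf_components(IntegerVector ia, IntegerVector ib, int n) {
  std::vector<int> parent(n + 1), sz(n + 1, 1);
  for (int i = 0; i <= n; ++i) parent[i] = i;
  auto find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  const int ne = ia.size();
  for (int k = 0; k < ne; ++k) {
    int ra = find(ia[k]), rb = find(ib[k]);
    if (ra == rb) continue;
    if (sz[ra] < sz[rb]) std::swap(ra, rb);
    parent[rb] = ra;
    sz[ra] += sz[rb];
  }
  IntegerVector root(n);
  for (int i = 1; i <= n; ++i) root[i - 1] = find(i);
  return root;
}

static void oms_dfs(const std::vector<int>& s, int i, std::vector<long long>& bins,
                    long long cur_max, long long remaining, long long lb, long long& best) {
  if (cur_max >= best) return;                 // cannot improve
  if (i == (int)s.size()) { best = cur_max; return; }
  // bound: even spreading the rest perfectly cannot beat lb
  if (best <= lb) return;
  int m = bins.size();
  for (int j = 0; j < m; ++j) {
    bool dup = false;                          // skip bins with a load already tried
    for (int k = 0; k < j; ++k) if (bins[k] == bins[j]) { dup = true; break; }
    if (dup) continue;
    bins[j] += s[i];
    long long nm = std::max(cur_max, bins[j]);
    oms_dfs(s, i + 1, bins, nm, remaining - s[i], lb, best);
    bins[j] -= s[i];
    if (best == lb) return;                    // provably optimal already
  }
}

// Exact minimum makespan by exhaustive branch-and-bound; sizes need not be
// sorted. Intended for small instances (n <= 14 enforced by the R wrapper).
// [[Rcpp::export]]
double opt_makespan_cpp(IntegerVector sizes, int m) {
  std::vector<int> s(sizes.begin(), sizes.end());
  std::sort(s.begin(), s.end(), std::greater<int>());
  long long total = 0, mx = 0;
  for (int v : s) { total += v; mx = std::max<long long>(mx, v); }
  long long lb = std::max<long long>(mx, (total + m - 1) / m);
  long long best = total;                      // m = 1 upper bound
  std::vector<long long> bins(m, 0);
  oms_dfs(s, 0, bins, 0, total, lb, best);
  return (double)best;
}
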