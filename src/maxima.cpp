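#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

static int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Prominence-gated local maxima (8-connectivity) by a watershed-style
// union-find over pixels in descending value order. When two components
// merge at level v, the lower component's peak has prominence
// peak_height - v (height above the highest saddle to a higher maximum).
// The final component's peak gets prominence peak_height - image minimum.
// Plateau maxima are reported at the centroid of their equal-valued plateau.
// [[Rcpp::export]]
NumericMatrix cpp_find_maxima(NumericMatrix img, double prominence) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  const double* v = img.begin();  // column-major: idx = r + c * nr

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    return a < b;
  });

  std::vector<int> parent(n, -1), peak(n, -1);
  std::vector<char> processed(n, 0);
  std::vector<std::pair<int, double>> accepted;  // (peak index, prominence)
  const double vmin = *std::min_element(v, v + n);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  for (int oi = 0; oi < n; ++oi) {
    const int p = order[oi];
    const int r = p % nr, c = p / nr;
    parent[p] = p;
    peak[p] = p;
    int roots[8];
    int nroots = 0;
    for (int k = 0; k < 8; ++k) {
      const int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int q = rr + cc * nr;
      if (!processed[q]) continue;
      const int rt = find_root(parent, q);
      bool seen = false;
      for (int t = 0; t < nroots; ++t) {
        if (roots[t] == rt) { seen = true; break; }
      }
      if (!seen) roots[nroots++] = rt;
    }
    if (nroots > 0) {
      int best = roots[0];
      for (int t = 1; t < nroots; ++t) {
        const int rt = roots[t];
        if (v[peak[rt]] > v[peak[best]] ||
            (v[peak[rt]] == v[peak[best]] && peak[rt] < peak[best])) {
          best = rt;
        }
      }
      parent[p] = best;
      for (int t = 0; t < nroots; ++t) {
        const int rt = roots[t];
        if (rt == best) continue;
        const double prom = v[peak[rt]] - v[p];
        if (prom > prominence) accepted.push_back({peak[rt], prom});
        parent[rt] = best;
      }
    }
    processed[p] = 1;
  }
  for (int i = 0; i < n; ++i) {
    if (parent[i] == i) {
      const double prom = v[peak[i]] - vmin;
      if (prom > prominence) accepted.push_back({peak[i], prom});
    }
  }

  // plateau centroids
  NumericMatrix out(accepted.size(), 4);
  std::vector<char> visited(n, 0);
  for (size_t a = 0; a < accepted.size(); ++a) {
    const int p0 = accepted[a].first;
    const double val = v[p0];
    double sr = 0, sc = 0;
    int cnt = 0;
    std::queue<int> q;
    std::vector<int> touched;
    q.push(p0);
    visited[p0] = 1;
    touched.push_back(p0);
    while (!q.empty()) {
      const int p = q.front();
      q.pop();
      const int r = p % nr, c = p / nr;
      sr += r + 1;
      sc += c + 1;
      ++cnt;
      for (int k = 0; k < 8; ++k) {
        const int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int pq = rr + cc * nr;
        if (!visited[pq] && v[pq] == val) {
          visited[pq] = 1;
          touched.push_back(pq);
          q.push(pq);
        }
      }
    }
    for (int p : touched) visited[p] = 0;
    out(a, 0) = sr / cnt;
    out(a, 1) = sc / cnt;
    out(a, 2) = val;
    out(a, 3) = accepted[a].second;
  }
  return out;
}
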