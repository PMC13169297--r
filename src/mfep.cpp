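#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>

using namespace Rcpp;

// Minimax (lowest-maximum) path between two cells of a 2D grid graph with
// 8-connectivity: the bottleneck level is found by union-find over cells in
// ascending energy order, then a deterministic Dijkstra (cumulative energy,
// ties by cell index) picks one concrete path inside the sublevel set.

static int uf_find(std::vector<int> &p, int i) {
  while (p[i] != i) { p[i] = p[p[i]]; i = p[i]; }
  return i;
}

// [[Rcpp::export]]
List cpp_mfep(NumericMatrix F, bool per_row, bool per_col,
              int si, int sj, int ti, int tj) {
  const int n1 = F.nrow(), n2 = F.ncol(), N = n1 * n2;
  const int s = si + sj * n1, t = ti + tj * n1;
  if (si < 0 || si >= n1 || sj < 0 || sj >= n2 ||
      ti < 0 || ti >= n1 || tj < 0 || tj >= n2)
    stop("path endpoints outside grid");
  for (int k = 0; k < N; ++k)
    if (!R_finite(F[k])) stop("grid contains non-finite values (masked cells)");

  std::vector<int> order(N);
  for (int k = 0; k < N; ++k) order[k] = k;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (F[a] != F[b]) return F[a] < F[b];
    return a < b;
  });
  std::vector<int> rank(N);
  for (int k = 0; k < N; ++k) rank[order[k]] = k;

  std::vector<int> parent(N);
  for (int k = 0; k < N; ++k) parent[k] = k;
  std::vector<bool> done(N, false);

  auto neighbours = [&](int id, std::vector<int> &out) {
    out.clear();
    int i = id % n1, j = id / n1;
    for (int di = -1; di <= 1; ++di) for (int dj = -1; dj <= 1; ++dj) {
      if (di == 0 && dj == 0) continue;
      int ii = i + di, jj = j + dj;
      if (per_row) ii = (ii + n1) % n1;
      if (per_col) jj = (jj + n2) % n2;
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2) continue;
      out.push_back(ii + jj * n1);
    }
  };

  int bottleneck = -1, max_rank = -1;
  std::vector<int> nb;
  for (int k = 0; k < N; ++k) {
    int c = order[k];
    done[c] = true;
    neighbours(c, nb);
    for (int m : nb)
      if (done[m]) parent[uf_find(parent, m)] = uf_find(parent, c);
    if (done[s] && done[t] && uf_find(parent, s) == uf_find(parent, t)) {
      bottleneck = c;
      max_rank = k;
      break;
    }
  }
  if (bottleneck < 0) stop("endpoints not connected on the grid");

  // Dijkstra restricted to cells with rank <= max_rank
  double fmin = F[order[0]];
  std::vector<double> dist(N, R_PosInf);
  std::vector<int> prev(N, -1);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > q;
  dist[s] = 0.0;
  q.push(QE(0.0, s));
  while (!q.empty()) {
    QE e = q.top(); q.pop();
    int c = e.second;
    if (e.first > dist[c]) continue;
    if (c == t) break;
    neighbours(c, nb);
    std::sort(nb.begin(), nb.end());
    for (int m : nb) {
      if (rank[m] > max_rank) continue;
      double w = F[m] - fmin + 1e-12;
      if (dist[c] + w < dist[m]) {
        dist[m] = dist[c] + w;
        prev[m] = c;
        q.push(QE(dist[m], m));
      }
    }
  }
  if (!R_finite(dist[t])) stop("endpoints not connected below the bottleneck level");

  std::vector<int> path;
  for (int c = t; c != -1; c = prev[c]) path.push_back(c);
  std::reverse(path.begin(), path.end());

  int np = path.size();
  IntegerMatrix out(np, 2);
  for (int k = 0; k < np; ++k) {
    out(k, 0) = path[k] % n1 + 1;   // 1-based row (axis 1)
    out(k, 1) = path[k] / n1 + 1;   // 1-based col (axis 2)
  }
  return List::create(_["path"] = out,
                      _["bottleneck"] = IntegerVector::create(
                          bottleneck % n1 + 1, bottleneck / n1 + 1),
                      _["level"] = F[bottleneck]);
}
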