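#include <Rcpp.h>
#include <vector>
#include <functional>
#include <cmath>
using namespace Rcpp;

// Exact earth mover's distance between two discrete distributions via the
// transportation simplex (MODI / u-v method) with a spanning-tree basis.
// Supplies `a` (length n) and demands `b` (length m) must be balanced;
// `cost` is the n x m ground-distance matrix.

namespace {

struct Basis {
  std::vector<int> bi, bj;
  std::vector<double> flow;
};

// DFS path from row r0 to column c0 through basic cells, alternating
// row -> (basic cell) -> col -> (basic cell) -> row. Returns the indices of
// basic cells along the path, or empty if unreachable (should not happen in a
// spanning tree).
bool find_path(int n, int m, const Basis &B,
               const std::vector<std::vector<int>> &row_cells,
               const std::vector<std::vector<int>> &col_cells,
               int r0, int c0, std::vector<int> &path) {
  std::vector<int> prev_cell(n + m, -1);   // node -> basis cell used to reach it
  std::vector<int> prev_node(n + m, -1);
  std::vector<char> seen(n + m, 0);
  // nodes 0..n-1 rows, n..n+m-1 cols
  std::vector<int> stack;
  stack.push_back(r0);
  seen[r0] = 1;
  while (!stack.empty()) {
    int node = stack.back();
    stack.pop_back();
    if (node < n) {
      for (int k : row_cells[node]) {
        int cnode = n + B.bj[k];
        if (!seen[cnode]) {
          seen[cnode] = 1;
          prev_cell[cnode] = k;
          prev_node[cnode] = node;
          if (cnode == n + c0) { stack.clear(); break; }
          stack.push_back(cnode);
        }
      }
    } else {
      for (int k : col_cells[node - n]) {
        int rnode = B.bi[k];
        if (!seen[rnode]) {
          seen[rnode] = 1;
          prev_cell[rnode] = k;
          prev_node[rnode] = node;
          stack.push_back(rnode);
        }
      }
    }
  }
  if (!seen[n + c0]) return false;
  path.clear();
  int node = n + c0;
  while (node != r0) {
    path.push_back(prev_cell[node]);
    node = prev_node[node];
  }
  // path runs col-end -> row-start; reverse so it starts at r0
  std::reverse(path.begin(), path.end());
  return true;
}

} // namespace

// [[Rcpp::export]]
List emd_simplex_cpp(NumericVector a, NumericVector b, NumericMatrix cost) {
  const int n = a.size(), m = b.size();
  if (cost.nrow() != n || cost.ncol() != m)
    stop("cost matrix dimensions do not match mass vectors");

  double maxc = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      if (cost(i, j) > maxc) maxc = cost(i, j);
  const double tol = 1e-11 * std::max(1.0, maxc);

  // Row-minimum greedy initial feasible solution (cost-aware, far fewer
  // simplex iterations than the northwest corner), then zero-flow edges to
  // complete a spanning-tree basis of n + m - 1 cells.
  Basis B;
  B.bi.reserve(n + m);
  {
    std::vector<double> sa(a.begin(), a.end()), sb(b.begin(), b.end());
    std::vector<int> parent(n + m);
    for (int k = 0; k < n + m; ++k) parent[k] = k;
    std::function<int(int)> find = [&](int x) {
      while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
      return x;
    };
    auto add_cell = [&](int i, int j, double flow) {
      B.bi.push_back(i); B.bj.push_back(j); B.flow.push_back(flow);
      int ra = find(i), rb = find(n + j);
      if (ra != rb) parent[ra] = rb;
    };
    int open_cols = m;
    std::vector<char> col_open(m, 1);
    for (int i = 0; i < n; ++i) {
      while (sa[i] > 0 && open_cols > 0) {
        int jbest = -1; double cbest = R_PosInf;
        for (int j = 0; j < m; ++j) {
          if (col_open[j] && cost(i, j) < cbest) { cbest = cost(i, j); jbest = j; }
        }
        if (jbest < 0) break;
        double alloc = std::min(sa[i], sb[jbest]);
        add_cell(i, jbest, alloc);
        sa[i] -= alloc; sb[jbest] -= alloc;
        if (sb[jbest] <= 0) { col_open[jbest] = 0; --open_cols; }
        if (alloc <= 0) break;  // degenerate guard
        if (sa[i] <= 0) break;
      }
    }
    // the greedy edges form a forest; connect every component to row 0 with
    // zero-flow cells, giving exactly n + m - 1 spanning-tree edges
    for (int j = 0; j < m; ++j) {
      if (find(n + j) != find(0)) add_cell(0, j, 0.0);
    }
    for (int i = 1; i < n; ++i) {
      if (find(i) != find(0)) add_cell(i, 0, 0.0);
    }
  }
  if ((int)B.bi.size() != n + m - 1) stop("internal: invalid initial basis");

  std::vector<std::vector<int>> row_cells(n), col_cells(m);
  auto rebuild_adj = [&]() {
    for (int i = 0; i < n; ++i) row_cells[i].clear();
    for (int j = 0; j < m; ++j) col_cells[j].clear();
    for (size_t k = 0; k < B.bi.size(); ++k) {
      row_cells[B.bi[k]].push_back((int)k);
      col_cells[B.bj[k]].push_back((int)k);
    }
  };
  rebuild_adj();

  std::vector<double> u(n), v(m);
  std::vector<int> stack;
  const int max_iter = 200 * (n + m) + 1000;
  int iter = 0;
  bool optimal = false;

  auto update_potentials = [&]() {
    std::vector<char> udone(n, 0), vdone(m, 0);
    u[0] = 0.0; udone[0] = 1;
    stack.clear(); stack.push_back(0);
    while (!stack.empty()) {
      int node = stack.back(); stack.pop_back();
      if (node < n) {
        for (int k : row_cells[node]) {
          int j = B.bj[k];
          if (!vdone[j]) { v[j] = cost(node, j) - u[node]; vdone[j] = 1; stack.push_back(n + j); }
        }
      } else {
        int j = node - n;
        for (int k : col_cells[j]) {
          int i = B.bi[k];
          if (!udone[i]) { u[i] = cost(i, j) - v[j]; udone[i] = 1; stack.push_back(i); }
        }
      }
    }
  };

  auto pivot = [&](int ei, int ej) -> bool {
    std::vector<int> path;
    if (!find_path(n, m, B, row_cells, col_cells, ei, ej, path)) return false;
    // cells along the path alternate -,+,-,... (entering cell itself is +)
    double theta = R_PosInf;
    int leave = -1;
    for (size_t p = 0; p < path.size(); p += 2) {
      if (B.flow[path[p]] < theta) { theta = B.flow[path[p]]; leave = path[p]; }
    }
    for (size_t p = 0; p < path.size(); ++p) {
      if (p % 2 == 0) B.flow[path[p]] -= theta; else B.flow[path[p]] += theta;
    }
    B.bi[leave] = ei; B.bj[leave] = ej; B.flow[leave] = theta;
    rebuild_adj();
    update_potentials();
    return true;
  };

  // partial pricing: rotate through the rows in slabs, entering the most
  // negative reduced-cost cell found in the current slab; optimal when a
  // full sweep finds no negative cell
  const int slab = std::max(8, n / 64);
  int rp = 0;
  update_potentials();

  while (iter < max_iter) {
    int scanned = 0, ei = -1, ej = -1;
    double best = -tol;
    while (scanned < n) {
      const int i = rp;
      rp = (rp + 1) % n;
      ++scanned;
      const double ui = u[i];
      for (int j = 0; j < m; ++j) {
        double rc = cost(i, j) - ui - v[j];
        if (rc < best) { best = rc; ei = i; ej = j; }
      }
      if (ei >= 0 && scanned >= slab) break;
    }
    if (ei < 0) { optimal = true; break; }
    if (!pivot(ei, ej)) break;
    ++iter;
  }

  double total = 0.0;
  for (size_t k = 0; k < B.bi.size(); ++k)
    total += B.flow[k] * cost(B.bi[k], B.bj[k]);

  return List::create(_["cost"] = total,
                      _["iterations"] = iter,
                      _["optimal"] = optimal);
}
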