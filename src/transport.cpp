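#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact solver for the balanced transportation problem
//   min sum_ij C(i,j) P(i,j)  s.t.  P >= 0, row sums = a, col sums = b
// by the transportation simplex (u-v / MODI method) on a dense cost matrix.
//
// Degeneracy is handled by the classical perturbation: supplies receive
// distinct tiny increments absorbed by the last demand; the optimal basis
// of the perturbed problem is optimal for the original (reduced costs do
// not depend on the marginals), and the returned cost re-solves the flows
// on that basis tree with the *unperturbed* marginals, so the perturbation
// never leaks into the reported value.

namespace {

struct Basis {
  std::vector<int> bi, bj;          // basic cells
  std::vector<double> flow;
  std::vector<std::vector<int> > adj;  // node -> incident basic cells
  int m, n;
  Basis(int m_, int n_) : m(m_), n(n_) { adj.resize(m_ + n_); }
  void add(int i, int j, double f) {
    int id = (int)bi.size();
    bi.push_back(i); bj.push_back(j); flow.push_back(f);
    adj[i].push_back(id); adj[m + j].push_back(id);
  }
  void replace(int id, int i, int j) {  // swap leaving cell for entering
    drop_ref(bi[id], id); drop_ref(m + bj[id], id);
    bi[id] = i; bj[id] = j;
    adj[i].push_back(id); adj[m + j].push_back(id);
  }
  void drop_ref(int node, int id) {
    std::vector<int>& v = adj[node];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == id) { v[k] = v.back(); v.pop_back(); return; }
  }
  int other(int id, int node) const {
    return (node < m) ? m + bj[id] : bi[id];
  }
};

}  // namespace

// [[Rcpp::export]]
List transport_simplex_cpp(NumericVector a_, NumericVector b_,
                           NumericMatrix C, int max_iter = 0) {
  const int m = a_.size(), n = b_.size();
  if (C.nrow() != m || C.ncol() != n)
    stop("cost matrix dimensions do not match the marginals");
  std::vector<double> a(a_.begin(), a_.end()), b(b_.begin(), b_.end());
  double suma = 0, sumb = 0, cmax = 0;
  for (int i = 0; i < m; ++i) { if (a[i] < 0) stop("negative mass"); suma += a[i]; }
  for (int j = 0; j < n; ++j) { if (b[j] < 0) stop("negative mass"); sumb += b[j]; }
  if (std::fabs(suma - sumb) > 1e-9 * std::max(suma, sumb))
    stop("marginals must have equal total mass");
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      cmax = std::max(cmax, std::fabs(C(i, j)));

  // perturbed marginals (basis construction only)
  const double delta = suma * 1e-11 / (m + 1.0);
  std::vector<double> ap(a), bp(b);
  double extra = 0;
  for (int i = 0; i < m; ++i) { ap[i] += delta * (i + 1); extra += delta * (i + 1); }
  bp[n - 1] += extra;

  // north-west corner initial basis: exactly m + n - 1 cells, staircase tree
  Basis B(m, n);
  {
    std::vector<double> ar(ap), br(bp);
    int i = 0, j = 0;
    while (true) {
      double t = std::min(ar[i], br[j]);
      B.add(i, j, t);
      ar[i] -= t; br[j] -= t;
      if (i == m - 1 && j == n - 1) break;
      if (ar[i] <= br[j] && i < m - 1) ++i; else ++j;
    }
  }

  const int nb = m + n - 1;
  const double tol = 1e-10 * std::max(cmax, 1.0);
  if (max_iter <= 0) max_iter = 1000 * (m + n) + 100000;
  const int block = std::max(256, (int)std::sqrt((double)m * n));
  long price_start = 0;

  std::vector<double> u(m), v(n);
  std::vector<char> seen(m + n);
  std::vector<int> par_cell(m + n), order(m + n);
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // duals from the basis tree (BFS from row node 0)
    std::fill(seen.begin(), seen.end(), 0);
    u[0] = 0; seen[0] = 1;
    int head = 0, tail = 0;
    order[tail++] = 0;
    while (head < tail) {
      int node = order[head++];
      for (size_t k = 0; k < B.adj[node].size(); ++k) {
        int id = B.adj[node][k];
        int nb2 = B.other(id, node);
        if (seen[nb2]) continue;
        seen[nb2] = 1;
        if (nb2 >= m) v[nb2 - m] = C(B.bi[id], B.bj[id]) - u[B.bi[id]];
        else u[nb2] = C(B.bi[id], B.bj[id]) - v[B.bj[id]];
        order[tail++] = nb2;
      }
    }
    // entering cell: block pricing with a rolling start — scan fixed-size
    // blocks of cells and take the most negative reduced cost in the first
    // block that has one; full sweep without a hit proves optimality
    double best = -tol; int ei = -1, ej = -1;
    {
      const long total = (long)m * n;
      long p = price_start;
      long scanned = 0;
      while (scanned < total) {
        long stop = std::min((long)block, total - scanned);
        for (long k = 0; k < stop; ++k, ++p) {
          if (p >= total) p -= total;
          int i = (int)(p / n), j = (int)(p % n);
          double r = C(i, j) - u[i] - v[j];
          if (r < best) { best = r; ei = i; ej = j; }
        }
        scanned += stop;
        if (ei >= 0) { price_start = p % total; break; }
      }
    }
    if (ei < 0) break;  // optimal

    // tree path from row node ei to col node m + ej
    std::fill(seen.begin(), seen.end(), 0);
    std::fill(par_cell.begin(), par_cell.end(), -1);
    std::vector<int> par_node(m + n, -1);
    head = 0; tail = 0;
    order[tail++] = ei; seen[ei] = 1;
    int target = m + ej;
    while (head < tail && !seen[target]) {
      int node = order[head++];
      for (size_t k = 0; k < B.adj[node].size(); ++k) {
        int id = B.adj[node][k];
        int nb2 = B.other(id, node);
        if (seen[nb2]) continue;
        seen[nb2] = 1; par_cell[nb2] = id; par_node[nb2] = node;
        order[tail++] = nb2;
      }
    }
    if (!seen[target]) stop("internal error: basis is not a spanning tree");

    // walk back: cells along the path alternate -,+,-,... seen from (ei,ej)
    std::vector<int> path;
    for (int node = target; node != ei; node = par_node[node])
      path.push_back(par_cell[node]);
    // path is ordered target -> ei; reverse so it starts at ei
    std::reverse(path.begin(), path.end());
    double theta = std::numeric_limits<double>::infinity();
    int leave = -1;
    for (size_t k = 0; k < path.size(); k += 2) {  // odd positions get minus
      if (B.flow[path[k]] < theta) { theta = B.flow[path[k]]; leave = path[k]; }
    }
    for (size_t k = 0; k < path.size(); ++k)
      B.flow[path[k]] += (k % 2 == 0) ? -theta : theta;
    B.flow[leave] = 0.0;
    B.replace(leave, ei, ej);
    B.flow[leave] = theta;
  }
  if (iter >= max_iter)
    Rf_warning("transportation simplex hit the iteration cap; "
               "result may be sub-optimal");

  // exact flows on the final basis tree with unperturbed marginals
  std::vector<double> rem(m + n);
  for (int i = 0; i < m; ++i) rem[i] = a[i];
  for (int j = 0; j < n; ++j) rem[m + j] = b[j];
  std::vector<int> deg(m + n, 0);
  std::vector<char> cell_done(nb, 0), node_done(m + n, 0);
  for (int id = 0; id < nb; ++id) { ++deg[B.bi[id]]; ++deg[m + B.bj[id]]; }
  std::queue<int> leaves;
  for (int node = 0; node < m + n; ++node)
    if (deg[node] == 1) leaves.push(node);
  std::vector<double> exact_flow(nb, 0.0);
  int processed = 0;
  while (!leaves.empty()) {
    int node = leaves.front(); leaves.pop();
    if (node_done[node]) continue;
    int cell = -1;
    for (size_t k = 0; k < B.adj[node].size(); ++k)
      if (!cell_done[B.adj[node][k]]) { cell = B.adj[node][k]; break; }
    if (cell < 0) { node_done[node] = 1; continue; }
    exact_flow[cell] = rem[node];
    int o = B.other(cell, node);
    rem[o] -= rem[node];
    rem[node] = 0;
    cell_done[cell] = 1; node_done[node] = 1;
    ++processed;
    if (--deg[o] == 1) leaves.push(o);
  }
  if (processed != nb)
    stop("internal error: flow recovery did not exhaust the basis");

  double cost = 0;
  for (int id = 0; id < nb; ++id) {
    double f = exact_flow[id];
    if (f > 0) cost += f * C(B.bi[id], B.bj[id]);
  }
  return List::create(_["cost"] = cost, _["iterations"] = iter,
                      _["from"] = IntegerVector(B.bi.begin(), B.bi.end()),
                      _["to"] = IntegerVector(B.bj.begin(), B.bj.end()),
                      _["flow"] = NumericVector(exact_flow.begin(),
                                                exact_flow.end()));
}
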