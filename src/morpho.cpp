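#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Squared Euclidean distance transform of a binary volume with anisotropic
// voxel spacing, by separable lower-envelope passes (Felzenszwalb &
// Huttenlocher). Input: mask (foreground TRUE), dims, spacing in physical
// units. Output: for every foreground voxel, squared physical distance to
// the nearest background voxel center; 0 on background.

static void dt1d(std::vector<double>& f, double h, std::vector<int>& v,
                 std::vector<double>& z, std::vector<double>& d) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      // intersection (in physical x) of parabolas centred at qh and ph
      s = ((f[q] + h * h * q * q) - (f[p] + h * h * p * p)) /
          (2.0 * h * (q - p));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double x = h * q;
    while (z[k + 1] < x) ++k;
    double dx = x - h * v[k];
    d[q] = dx * dx + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dim");
  // sentinel "infinity" must stay small enough that BIG + h^2 q^2 remains
  // exactly representable, or the lower-envelope arithmetic degenerates
  const double BIG = 1e12;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along dim 1 (fastest-varying)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
      f.assign(out.begin() + base, out.begin() + base + n1);
      dt1d(f, spacing[0], v, z, d);
      for (int i = 0; i < n1; ++i) out[base + i] = f[i];
    }
  // pass along dim 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
      f.resize(n2);
      for (int j = 0; j < n2; ++j) f[j] = out[base + (R_xlen_t)j * n1];
      dt1d(f, spacing[1], v, z, d);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)j * n1] = f[j];
    }
  // pass along dim 3
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)j * n1 + i;
      f.resize(n3);
      for (int k = 0; k < n3; ++k) f[k] = out[base + (R_xlen_t)k * plane];
      dt1d(f, spacing[2], v, z, d);
      for (int k = 0; k < n3; ++k) out[base + (R_xlen_t)k * plane] = f[k];
    }
  return out;
}

// 26-connected component labelling of a binary volume; labels 1..ncomp in
// discovery order, 0 on background.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int k = (int)(p / ((R_xlen_t)n1 * n2));
      int rem = (int)(p % ((R_xlen_t)n1 * n2));
      int j = rem / n1, i = rem % n1;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 ||
                kk >= n3)
              continue;
            R_xlen_t q =
                (R_xlen_t)kk * n1 * n2 + (R_xlen_t)jj * n1 + ii;
            if (mask[q] && !lab[q]) {
              lab[q] = cur;
              stack.push_back(q);
            }
          }
    }
  }
  return lab;
}

// Dijkstra over foreground voxels (26-neighbourhood, physical edge lengths).
// node_cost: optional per-voxel multiplicative cost (length n or 0); an edge
// u-v costs step_length * (node_cost[u] + node_cost[v]) / 2. start is a
// 1-based linear index. Returns distances (Inf where unreachable) and
// 1-based parent indices (NA at start/unreached).
// [[Rcpp::export]]
List dijkstra_cpp(LogicalVector mask, IntegerVector dim,
                  NumericVector spacing, double start,
                  NumericVector node_cost) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dim");
  const bool use_cost = node_cost.size() == n;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector dist(n, INF);
  IntegerVector parent(n, NA_INTEGER);
  R_xlen_t s = (R_xlen_t)start - 1;
  if (s < 0 || s >= n || !mask[s]) stop("start voxel is not in the mask");

  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  dist[s] = 0.0;
  pq.push(Node(0.0, s));
  double step[3][3][3];
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di)
        step[di + 1][dj + 1][dk + 1] =
            std::sqrt(di * di * spacing[0] * spacing[0] +
                      dj * dj * spacing[1] * spacing[1] +
                      dk * dk * spacing[2] * spacing[2]);
  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    R_xlen_t p = top.second;
    if (top.first > dist[p]) continue;
    int k = (int)(p / ((R_xlen_t)n1 * n2));
    int rem = (int)(p % ((R_xlen_t)n1 * n2));
    int j = rem / n1, i = rem % n1;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 ||
              kk >= n3)
            continue;
          R_xlen_t q = (R_xlen_t)kk * n1 * n2 + (R_xlen_t)jj * n1 + ii;
          if (!mask[q]) continue;
          double w = step[di + 1][dj + 1][dk + 1];
          if (use_cost) w *= 0.5 * (node_cost[p] + node_cost[q]);
          double nd = dist[p] + w;
          if (nd < dist[q]) {
            dist[q] = nd;
            parent[q] = (int)(p + 1);
            pq.push(Node(nd, q));
          }
        }
  }
  return List::create(_["dist"] = dist, _["parent"] = parent);
}
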