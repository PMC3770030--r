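#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Exact double sum of Eq-style source energy:
// E(i,j) = sum_{(i0,j0) in src} exp(-dist((i,j),(i0,j0)) / sigma) * g(i0,j0)
// [[Rcpp::export]]
NumericMatrix source_energy_cpp(NumericMatrix g, LogicalMatrix src,
                                double sigma) {
  const int nr = g.nrow(), nc = g.ncol();
  std::vector<int> si, sj;
  std::vector<double> sg;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (src(i, j)) {
        si.push_back(i);
        sj.push_back(j);
        sg.push_back(g(i, j));
      }
  const int ns = (int)si.size();
  NumericMatrix out(nr, nc);
  const double inv_sigma = 1.0 / sigma;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = 0; k < ns; ++k) {
        const double di = (double)(i - si[k]);
        const double dj = (double)(j - sj[k]);
        acc += std::exp(-std::sqrt(di * di + dj * dj) * inv_sigma) * sg[k];
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// First-order fast marching on a 4-connected unit grid: solves |grad T| = 1/F
// with front speed F = energy, T = 0 at seeds. Pixels with F = 0 are hard
// barriers (T = +Inf) unless seeded. Godunov upwind update with lazy-deletion
// binary heap.
// [[Rcpp::export]]
NumericMatrix fast_march_cpp(NumericMatrix energy, IntegerMatrix seeds) {
  const int nr = energy.nrow(), nc = energy.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix T(nr, nc);
  std::vector<char> frozen((size_t)nr * nc, 0);
  std::fill(T.begin(), T.end(), INF);

  typedef std::pair<double, int> Node; // (tentative T, linear index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > heap;

  for (int k = 0; k < seeds.nrow(); ++k) {
    const int i = seeds(k, 0) - 1, j = seeds(k, 1) - 1;
    if (i < 0 || i >= nr || j < 0 || j >= nc)
      stop("seed outside the grid");
    const int idx = i + j * nr;
    T[idx] = 0.0;
    heap.push(Node(0.0, idx));
  }

  // exact initialization of the seed neighborhoods: the upwind stencil is
  // least accurate at the point source, so the 8 neighbors of each seed get
  // the locally exact arrival time (offset length over local speed)
  for (int k = 0; k < seeds.nrow(); ++k) {
    const int i = seeds(k, 0) - 1, j = seeds(k, 1) - 1;
    for (int di2 = -1; di2 <= 1; ++di2) {
      for (int dj2 = -1; dj2 <= 1; ++dj2) {
        if (di2 == 0 && dj2 == 0) continue;
        const int ni = i + di2, nj = j + dj2;
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        const double F = energy(ni, nj);
        if (F <= 0.0) continue;
        const double t = std::sqrt((double)(di2 * di2 + dj2 * dj2)) / F;
        const int nidx = ni + nj * nr;
        if (t < T[nidx]) {
          T[nidx] = t;
          heap.push(Node(t, nidx));
        }
      }
    }
  }

  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};

  while (!heap.empty()) {
    const Node nd = heap.top();
    heap.pop();
    const int idx = nd.second;
    if (frozen[idx]) continue;
    frozen[idx] = 1;
    const int i = idx % nr, j = idx / nr;

    for (int q = 0; q < 4; ++q) {
      const int ni = i + di[q], nj = j + dj[q];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      const int nidx = ni + nj * nr;
      if (frozen[nidx]) continue;
      const double F = energy(ni, nj);
      if (F <= 0.0) continue; // unreachable barrier
      const double rhs = 1.0 / F;
      // upwind values along each axis
      double a = INF, b = INF;
      if (ni > 0)      a = std::min(a, T[nidx - 1]);
      if (ni < nr - 1) a = std::min(a, T[nidx + 1]);
      if (nj > 0)      b = std::min(b, T[nidx - nr]);
      if (nj < nc - 1) b = std::min(b, T[nidx + nr]);
      const double lo = std::min(a, b), hi = std::max(a, b);
      if (lo == INF) continue;
      double t;
      if (hi - lo < rhs && hi != INF) {
        const double disc = 2.0 * rhs * rhs - (a - b) * (a - b);
        t = 0.5 * (a + b + std::sqrt(disc));
      } else {
        t = lo + rhs;
      }
      if (t < T[nidx]) {
        T[nidx] = t;
        heap.push(Node(t, nidx));
      }
    }
  }
  return T;
}
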