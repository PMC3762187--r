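#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------
// Transiogram model evaluation.
// anchors: increasing lag distances, anchors[0] == 0 (identity matrix).
// tvals:   K row-stochastic n x n matrices, laid out dim (n, n, K).
// Beyond the last anchor the model returns the marginal sill.
static inline double t_eval(int i, int j, double h,
                            const NumericVector &anchors,
                            const NumericVector &tvals,
                            const NumericVector &marginals, int n) {
  const int K = anchors.size();
  if (h > anchors[K - 1]) return marginals[j];
  // binary search for the bracketing interval [k, k+1]
  int lo = 0, hi = K - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (anchors[mid] <= h) lo = mid; else hi = mid;
  }
  const double a0 = anchors[lo], a1 = anchors[hi];
  const double w = (a1 > a0) ? (h - a0) / (a1 - a0) : 0.0;
  const double v0 = tvals[i + n * j + n * n * lo];
  const double v1 = tvals[i + n * j + n * n * hi];
  return (1.0 - w) * v0 + w * v1;
}

// ---------------------------------------------------------------------
// Quadrant sector of an offset (dx, dy) in map orientation (y up).
// Sector boundaries at 45/135/225/315 degrees; a point exactly on a
// boundary belongs to the counter-clockwise sector.
// Returns 0 = E, 1 = N, 2 = W, 3 = S.
static inline int quadrant_of(int dx, int dy) {
  if (dx > 0 && dy >= -dx && dy < dx) return 0;          // E: [-45, 45)
  if (dy > 0 && dx > -dy && dx <= dy) return 1;          // N: [45, 135)
  if (dx < 0 && dy <= -dx && dy > dx) return 2;          // W: [135, 225)
  return 3;                                              // S: [225, 315)
}

struct NeighborSet {
  int cls[4];
  int d2[4];
  int row[4];
  int col[4];
  bool used[4];
  int m;      // number of occupied quadrants
  int first;  // quadrant index of the designated first neighbor
};

// Ring search over the informed grid (value >= 0 means informed class,
// -1 means uninformed). Nearest informed cell per quadrant, Euclidean
// distance ties broken by smallest (row, col) lexicographic order.
static void find_neighbors_grid(const IntegerMatrix &g, int r0, int c0,
                                double radius_cells, NeighborSet &ns) {
  const int nr = g.nrow(), nc = g.ncol();
  const double r2max = radius_cells * radius_cells + 1e-9;
  const int kmax = (int)std::floor(radius_cells + 1e-9);
  for (int q = 0; q < 4; ++q) { ns.used[q] = false; ns.d2[q] = INT_MAX; }

  for (int k = 1; k <= kmax; ++k) {
    // stop when no later ring (min distance k) can beat or tie any best
    bool done = true;
    for (int q = 0; q < 4; ++q)
      if (!(ns.used[q] && ns.d2[q] < k * k)) { done = false; break; }
    if (done) break;

    const int rlo = std::max(0, r0 - k), rhi = std::min(nr - 1, r0 + k);
    const int clo = std::max(0, c0 - k), chi = std::min(nc - 1, c0 + k);
    for (int r = rlo; r <= rhi; ++r) {
      const bool edge_row = (r == r0 - k) || (r == r0 + k);
      const int cstep = edge_row ? 1 : (chi - clo > 0 ? chi - clo : 1);
      for (int c = clo; c <= chi; c += cstep) {
        if (!edge_row && c != c0 - k && c != c0 + k) continue;
        const int v = g(r, c);
        if (v < 0) continue;
        const int dr = r - r0, dc = c - c0;
        const int d2 = dr * dr + dc * dc;
        if ((double)d2 > r2max) continue;
        const int q = quadrant_of(dc, -dr);
        const bool better =
          !ns.used[q] || d2 < ns.d2[q] ||
          (d2 == ns.d2[q] &&
           (r < ns.row[q] || (r == ns.row[q] && c < ns.col[q])));
        if (better) {
          ns.used[q] = true; ns.d2[q] = d2;
          ns.row[q] = r; ns.col[q] = c; ns.cls[q] = v;
        }
      }
    }
  }

  ns.m = 0; ns.first = -1;
  int bd2 = INT_MAX, brow = INT_MAX, bcol = INT_MAX;
  for (int q = 0; q < 4; ++q) {
    if (!ns.used[q]) continue;
    ++ns.m;
    if (ns.d2[q] < bd2 ||
        (ns.d2[q] == bd2 &&
         (ns.row[q] < brow || (ns.row[q] == brow && ns.col[q] < bcol)))) {
      bd2 = ns.d2[q]; brow = ns.row[q]; bcol = ns.col[q]; ns.first = q;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix find_neighbors_cpp(IntegerMatrix informed, int r0, int c0,
                                 double radius_cells) {
  NeighborSet ns;
  find_neighbors_grid(informed, r0, c0, radius_cells, ns);
  IntegerMatrix out(ns.m, 6);
  int i = 0;
  for (int q = 0; q < 4; ++q) {
    if (!ns.used[q]) continue;
    out(i, 0) = ns.row[q];
    out(i, 1) = ns.col[q];
    out(i, 2) = ns.cls[q];
    out(i, 3) = q;
    out(i, 4) = ns.d2[q];
    out(i, 5) = (q == ns.first) ? 1 : 0;
    ++i;
  }
  colnames(out) = CharacterVector::create("row", "col", "class", "quadrant",
                                          "d2", "first");
  return out;
}

// ---------------------------------------------------------------------
// Local conditional distribution of the simplified MCRF / colocated
// Co-MCRF model. The designated first neighbor contributes the
// transposed-direction term p_{i1,i0}(h10); every other neighbor g the
// term p_{i0,ig}(h0g); each auxiliary colocation multiplies by its CTPM
// likelihood b_{i0, r0}. Zero-numerator fallback chain: (1) CTPM
// likelihood times marginals, (2) marginals.
// Returns the fallback level used (0 = none) via `fallback`.
static void local_distribution(const int *cls, const double *lag, int m,
                               int first,
                               const NumericVector &anchors,
                               const NumericVector &tvals,
                               const NumericVector &marginals, int n,
                               const std::vector<const double *> &ctpm,
                               const std::vector<int> &ctpm_nrow,
                               const std::vector<int> &aux_code,
                               double *p, int &fallback) {
  fallback = 0;
  double s = 0.0;
  for (int f = 0; f < n; ++f) {
    double num;
    if (m == 0) {
      num = marginals[f];
    } else {
      num = t_eval(cls[first], f, lag[first], anchors, tvals, marginals, n);
      for (int g = 0; g < m; ++g) {
        if (g == first) continue;
        num *= t_eval(f, cls[g], lag[g], anchors, tvals, marginals, n);
      }
    }
    for (size_t l = 0; l < ctpm.size(); ++l) {
      if (aux_code[l] >= 0)
        num *= ctpm[l][f + ctpm_nrow[l] * aux_code[l]];
    }
    p[f] = num;
    s += num;
  }
  if (s <= 0.0) {               // fallback 1: CTPM likelihood x marginals
    fallback = 1;
    s = 0.0;
    for (int f = 0; f < n; ++f) {
      double num = marginals[f];
      for (size_t l = 0; l < ctpm.size(); ++l) {
        if (aux_code[l] >= 0)
          num *= ctpm[l][f + ctpm_nrow[l] * aux_code[l]];
      }
      p[f] = num;
      s += num;
    }
  }
  if (s <= 0.0) {               // fallback 2: marginals
    fallback = 2;
    s = 0.0;
    for (int f = 0; f < n; ++f) { p[f] = marginals[f]; s += p[f]; }
  }
  if (s <= 0.0) {               // fallback 3: uniform (defensive)
    fallback = 3;
    for (int f = 0; f < n; ++f) p[f] = 1.0 / n;
    s = 1.0;
  }
  for (int f = 0; f < n; ++f) p[f] /= s;
}

// [[Rcpp::export]]
List local_dist_cpp(IntegerVector classes, NumericVector lags, int first,
                    NumericVector anchors, NumericVector tvals,
                    NumericVector marginals,
                    List ctpms, IntegerVector aux_codes) {
  const int n = marginals.size();
  const int m = classes.size();
  std::vector<const double *> cp;
  std::vector<int> cn, ac;
  std::vector<NumericMatrix> keep;
  for (int l = 0; l < ctpms.size(); ++l) {
    NumericMatrix b = ctpms[l];
    keep.push_back(b);
    cp.push_back(REAL(b));
    cn.push_back(b.nrow());
    ac.push_back(aux_codes[l]);
  }
  NumericVector p(n);
  int fb = 0;
  std::vector<int> cls(classes.begin(), classes.end());
  std::vector<double> lag(lags.begin(), lags.end());
  local_distribution(m ? cls.data() : NULL, m ? lag.data() : NULL, m, first,
                     anchors, tvals, marginals, n, cp, cn, ac,
                     REAL(p), fb);
  return List::create(_["p"] = p, _["fallback"] = fb);
}

// ---------------------------------------------------------------------
// Random-path sequential (co)simulation. `init` holds fixed sample cells
// as class codes and -1 for cells to simulate; `path` gives the 0-based
// (row, col) visit order of the -1 cells. Each visited cell draws its
// class by inverse CDF over codebook order using one uniform from R's
// RNG, then joins the informed set. Auxiliary grids use -1 for nodata
// (their CTPM term is skipped there).
// [[Rcpp::export]]
List mcrf_simulate_cpp(IntegerMatrix init, IntegerMatrix path,
                       NumericVector anchors, NumericVector tvals,
                       NumericVector marginals, double radius_cells,
                       double cell_size, List aux_grids, List ctpms) {
  const int n = marginals.size();
  IntegerMatrix g = clone(init);
  std::vector<const double *> cp;
  std::vector<int> cn;
  std::vector<NumericMatrix> keepm;
  std::vector<IntegerMatrix> keepa;
  for (int l = 0; l < ctpms.size(); ++l) {
    NumericMatrix b = ctpms[l];
    keepm.push_back(b);
    cp.push_back(REAL(b));
    cn.push_back(b.nrow());
    IntegerMatrix a = aux_grids[l];
    keepa.push_back(a);
  }
  std::vector<int> ac(ctpms.size(), -1);
  std::vector<double> p(n);
  int cls[4];
  double lag[4];
  int n_fb1 = 0, n_fb2 = 0;
  NeighborSet ns;
  RNGScope scope;

  for (int t = 0; t < path.nrow(); ++t) {
    const int r0 = path(t, 0), c0 = path(t, 1);
    find_neighbors_grid(g, r0, c0, radius_cells, ns);
    int m = 0, first = -1;
    for (int q = 0; q < 4; ++q) {
      if (!ns.used[q]) continue;
      cls[m] = ns.cls[q];
      lag[m] = cell_size * std::sqrt((double)ns.d2[q]);
      if (q == ns.first) first = m;
      ++m;
    }
    for (size_t l = 0; l < cp.size(); ++l) ac[l] = keepa[l](r0, c0);
    int fb = 0;
    local_distribution(cls, lag, m, first, anchors, tvals, marginals, n,
                       cp, cn, ac, p.data(), fb);
    if (fb == 1) ++n_fb1; else if (fb >= 2) ++n_fb2;
    const double u = unif_rand();
    double cum = 0.0;
    int draw = n - 1;
    for (int f = 0; f < n; ++f) {
      cum += p[f];
      if (u < cum) { draw = f; break; }
    }
    g(r0, c0) = draw;
  }
  return List::create(_["grid"] = g, _["n_fallback_ctpm"] = n_fb1,
                      _["n_fallback_marginal"] = n_fb2);
}

// ---------------------------------------------------------------------
// Pairwise transition counting for experimental transiograms.
// Points must be pre-sorted by x. Both orderings of every pair within
// max_lag are counted (omnidirectional); bin index is floor(d / bin_width)
// clamped so that d == max_lag falls in the last bin.
// Returns counts dim (n, n, n_bins), per-bin pair count and distance sum.
// [[Rcpp::export]]
List transio_count_cpp(NumericVector x, NumericVector y, IntegerVector cls,
                       int n_classes, double bin_width, double max_lag) {
  const int np = x.size();
  const int n_bins = (int)std::floor(max_lag / bin_width + 1e-12) + 1;
  NumericVector counts(n_classes * n_classes * n_bins);
  NumericVector dist_sum(n_bins);
  NumericVector n_pairs(n_bins);
  const double ml2 = max_lag * max_lag + 1e-12;
  for (int i = 0; i < np; ++i) {
    for (int j = i + 1; j < np; ++j) {
      const double dx = x[j] - x[i];
      if (dx > max_lag) break;
      const double dy = y[j] - y[i];
      const double d2 = dx * dx + dy * dy;
      if (d2 > ml2) continue;
      const double d = std::sqrt(d2);
      int b = (int)std::floor(d / bin_width + 1e-12);
      if (b >= n_bins) b = n_bins - 1;
      const int ci = cls[i], cj = cls[j];
      counts[ci + n_classes * cj + n_classes * n_classes * b] += 1.0;
      counts[cj + n_classes * ci + n_classes * n_classes * b] += 1.0;
      dist_sum[b] += 2.0 * d;
      n_pairs[b] += 2.0;
    }
  }
  counts.attr("dim") = IntegerVector::create(n_classes, n_classes, n_bins);
  return List::create(_["counts"] = counts, _["dist_sum"] = dist_sum,
                      _["n_pairs"] = n_pairs);
}
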