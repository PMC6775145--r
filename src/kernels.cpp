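#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Sample-entropy template counts (Richman & Moorman): B = matching pairs at
// length m, A = at length m+1, Chebyshev distance, self-matches excluded,
// both counted over the N - m template starting positions.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;          // number of templates with an (m+1)-th point
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// Natural visibility graph adjacency. Node b is visible from a (a < b) iff
// the slope from a to b strictly exceeds the slope from a to every
// intermediate point: (y_c - y_a)/(t_c - t_a) < (y_b - y_a)/(t_b - t_a).
static std::vector< std::vector<int> > nvg_adjacency(const NumericVector& t,
                                                     const NumericVector& y) {
  int n = t.size();
  std::vector< std::vector<int> > adj(n);
  for (int a = 0; a < n - 1; ++a) {
    double maxslope = -std::numeric_limits<double>::infinity();
    for (int b = a + 1; b < n; ++b) {
      double s = (y[b] - y[a]) / (t[b] - t[a]);
      // strict visibility: an intermediate point on the line blocks the edge
      if (s > maxslope) { adj[a].push_back(b); adj[b].push_back(a); }
      maxslope = std::max(maxslope, s);
    }
  }
  return adj;
}

// Edge list of the natural visibility graph (1-based node indices, a < b).
// [[Rcpp::export]]
IntegerMatrix nvg_edges_cpp(NumericVector t, NumericVector y) {
  std::vector< std::vector<int> > adj = nvg_adjacency(t, y);
  int n = t.size();
  std::vector<int> ea, eb;
  for (int a = 0; a < n; ++a)
    for (size_t k = 0; k < adj[a].size(); ++k)
      if (adj[a][k] > a) { ea.push_back(a + 1); eb.push_back(adj[a][k] + 1); }
  IntegerMatrix out(ea.size(), 2);
  for (size_t i = 0; i < ea.size(); ++i) { out(i, 0) = ea[i]; out(i, 1) = eb[i]; }
  return out;
}

// Degrees, local clustering coefficients and degree assortativity of the NVG.
// [[Rcpp::export]]
List nvg_stats_cpp(NumericVector t, NumericVector y) {
  std::vector< std::vector<int> > adj = nvg_adjacency(t, y);
  int n = t.size();
  IntegerVector degree(n);
  NumericVector clust(n);
  for (int i = 0; i < n; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    degree[i] = adj[i].size();
  }
  for (int i = 0; i < n; ++i) {
    int d = degree[i];
    if (d < 2) { clust[i] = 0.0; continue; }
    long links = 0;
    for (int p = 0; p < d - 1; ++p)
      for (int q = p + 1; q < d; ++q) {
        int u = adj[i][p], v = adj[i][q];
        if (std::binary_search(adj[u].begin(), adj[u].end(), v)) ++links;
      }
    clust[i] = 2.0 * links / (double(d) * (d - 1));
  }
  // assortativity: Pearson correlation of endpoint degrees over directed edges
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0; long m2 = 0;
  for (int i = 0; i < n; ++i)
    for (size_t k = 0; k < adj[i].size(); ++k) {
      double dx = degree[i], dy = degree[adj[i][k]];
      sx += dx; sy += dy; sxx += dx * dx; syy += dy * dy; sxy += dx * dy;
      ++m2;
    }
  double assort = NA_REAL;
  if (m2 > 0) {
    double mx = sx / m2, my = sy / m2;
    double vx = sxx / m2 - mx * mx, vy = syy / m2 - my * my;
    double cv = sxy / m2 - mx * my;
    if (vx > 0 && vy > 0) assort = cv / std::sqrt(vx * vy);
  }
  return List::create(_["degree"] = degree, _["clustering"] = clust,
                      _["assortativity"] = assort);
}

// Joint template counts for m = 1 and m = 2 in one diagonal sweep:
// returns (A1, B1, A2, B2) with the same Richman-Moorman index restriction
// as sampen_counts_cpp (templates drawn from the first n - m positions).
// Along each diagonal d = j - i, runs of consecutive positions p with
// |x[p] - x[p+d]| <= r yield closed-form match counts per template length.
// [[Rcpp::export]]
NumericVector sampen12_counts_cpp(NumericVector x, double r) {
  int n = x.size();
  double A1 = 0, B1 = 0, A2 = 0, B2 = 0;
  for (int d = 1; d <= n - 2; ++d) {
    int plen = n - d;           // positions 0 .. plen-1 on this diagonal
    int p = 0;
    while (p < plen) {
      if (std::fabs(x[p] - x[p + d]) > r) { ++p; continue; }
      int a = p;
      while (p < plen && std::fabs(x[p] - x[p + d]) <= r) ++p;
      int b = p - 1;            // inclusive run of matches [a, b]
      // m = 1: starts s in [a, min(b, n-2-d)] (i <= n-2, j <= n-2)
      long c = (long)std::min(b, n - 2 - d) - a + 1;
      if (c > 0) B1 += c;
      // A1: length-2 match, same start range
      c = (long)std::min(b - 1, n - 2 - d) - a + 1;
      if (c > 0) A1 += c;
      // m = 2: starts s in [a, min(b-1, n-3-d)]
      c = (long)std::min(b - 1, n - 3 - d) - a + 1;
      if (c > 0) B2 += c;
      c = (long)std::min(b - 2, n - 3 - d) - a + 1;
      if (c > 0) A2 += c;
    }
  }
  return NumericVector::create(A1, B1, A2, B2);
}

// DFA fluctuation function: integrate the mean-centred series, then for each
// box size remove a per-box least-squares line and return the RMS residual.
// [[Rcpp::export]]
NumericVector dfa_profile_cpp(NumericVector x, IntegerVector scales) {
  // integrated profile with its leading zero (n + 1 points): together with
  // the both-end box tiling below this makes F(s) exactly invariant under
  // time reversal of x
  int nx = x.size();
  int n = nx + 1;
  std::vector<double> y(n);
  double mu = 0;
  for (int i = 0; i < nx; ++i) mu += x[i];
  mu /= nx;
  double acc = 0;
  y[0] = 0.0;
  for (int i = 0; i < nx; ++i) { acc += x[i] - mu; y[i + 1] = acc; }
  NumericVector out(scales.size());
  for (int si = 0; si < scales.size(); ++si) {
    int s = scales[si];
    int nbox = n / s;
    double sxx = 0;
    for (int k = 0; k < s; ++k) {
      double d = k - (s - 1) / 2.0;
      sxx += d * d;
    }
    // boxes tiled from both ends so the tail is covered too (and the
    // fluctuation function is exactly invariant under time reversal)
    double ssr = 0;
    for (int pass = 0; pass < 2; ++pass) {
      for (int b = 0; b < nbox; ++b) {
        const double* yb = pass == 0 ? &y[b * s] : &y[n - (b + 1) * s];
        double sy = 0, sxy = 0;
        for (int k = 0; k < s; ++k) {
          double d = k - (s - 1) / 2.0;
          sy += yb[k]; sxy += d * yb[k];
        }
        double ym = sy / s, beta = sxy / sxx;
        for (int k = 0; k < s; ++k) {
          double d = k - (s - 1) / 2.0;
          double r = yb[k] - ym - beta * d;
          ssr += r * r;
        }
      }
    }
    out[si] = std::sqrt(ssr / (2.0 * nbox * s));
  }
  return out;
}
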