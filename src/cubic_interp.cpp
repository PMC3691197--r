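// Piecewise-cubic scattered-data interpolation over a Delaunay triangulation.
//
// Per-triangle cubic Bezier patches: vertex values are interpolated exactly,
// edge control points come from vertex gradients (so the restriction to each
// edge is the cubic Hermite determined by the shared endpoint data, making the
// surface continuous across triangles), and the interior control point is the
// quadratic-precision choice b111 = 1/4 * sum(edge ctrl) - 1/6 * sum(vertex
// ctrl). Vertex gradients are estimated by weighted least-squares quadratic
// fits over Delaunay neighbours, so the interpolant reproduces quadratic
// fields to rounding error.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Weighted LS fit of z - z_v ~ [dx, dy, dx^2, dx*dy, dy^2] around each vertex.
// Falls back to a linear fit when the neighbourhood is too small or the
// quadratic system is ill-conditioned (e.g. hull vertices with few neighbours).
// [[Rcpp::export]]
NumericMatrix cpp_vertex_gradients(NumericMatrix pts, NumericVector z,
                                   IntegerMatrix tri, int degree = 2) {
  const int n = pts.nrow(), m = tri.nrow();
  std::vector< std::vector<int> > adj(n);
  for (int t = 0; t < m; ++t) {
    int a = tri(t, 0) - 1, b = tri(t, 1) - 1, c = tri(t, 2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int v = 0; v < n; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }

  NumericMatrix grad(n, 2);
  for (int v = 0; v < n; ++v) {
    std::vector<int> nb = adj[v];
    if ((int)nb.size() < 5) {           // widen to the 2-ring
      std::vector<int> ext = nb;
      for (size_t i = 0; i < nb.size(); ++i)
        for (size_t j = 0; j < adj[nb[i]].size(); ++j) ext.push_back(adj[nb[i]][j]);
      std::sort(ext.begin(), ext.end());
      ext.erase(std::unique(ext.begin(), ext.end()), ext.end());
      ext.erase(std::remove(ext.begin(), ext.end(), v), ext.end());
      nb = ext;
    }
    const int k = nb.size();
    if (k == 0) { grad(v, 0) = 0.0; grad(v, 1) = 0.0; continue; }

    arma::mat A(k, 5);
    arma::vec b(k), w(k);
    for (int i = 0; i < k; ++i) {
      double dx = pts(nb[i], 0) - pts(v, 0);
      double dy = pts(nb[i], 1) - pts(v, 1);
      double d = std::sqrt(dx * dx + dy * dy);
      double wi = d > 0 ? 1.0 / d : 0.0;
      A(i, 0) = dx; A(i, 1) = dy; A(i, 2) = dx * dx; A(i, 3) = dx * dy; A(i, 4) = dy * dy;
      b(i) = z[nb[i]] - z[v];
      w(i) = wi;
    }
    A.each_col() %= w;
    b %= w;

    arma::vec sol;
    bool ok = false;
    if (degree >= 2 && k >= 5) {
      ok = arma::solve(sol, A, b, arma::solve_opts::no_approx);
      if (ok && !sol.is_finite()) ok = false;
    }
    if (!ok) {                          // local plane fit
      arma::mat A2 = A.cols(0, 1);
      arma::vec s2 = arma::pinv(A2) * b;
      grad(v, 0) = s2(0); grad(v, 1) = s2(1);
    } else {
      grad(v, 0) = sol(0); grad(v, 1) = sol(1);
    }
  }
  return grad;
}

// Evaluate the patchwork at query points; NA outside the triangulation.
// [[Rcpp::export]]
NumericVector cpp_eval_cubic(NumericMatrix pts, NumericVector z, NumericMatrix grad,
                             IntegerMatrix tri, NumericVector qx, NumericVector qy) {
  const int m = tri.nrow(), nq = qx.size();
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < pts.nrow(); ++i) {
    xmin = std::min(xmin, pts(i, 0)); xmax = std::max(xmax, pts(i, 0));
    ymin = std::min(ymin, pts(i, 1)); ymax = std::max(ymax, pts(i, 1));
  }
  const double spanx = std::max(xmax - xmin, 1e-300);
  const double spany = std::max(ymax - ymin, 1e-300);
  const int G = std::max(1, (int)std::sqrt((double)m / 2.0));
  std::vector< std::vector<int> > bucket(G * G);
  for (int t = 0; t < m; ++t) {
    double tx0 = R_PosInf, tx1 = R_NegInf, ty0 = R_PosInf, ty1 = R_NegInf;
    for (int j = 0; j < 3; ++j) {
      int v = tri(t, j) - 1;
      tx0 = std::min(tx0, pts(v, 0)); tx1 = std::max(tx1, pts(v, 0));
      ty0 = std::min(ty0, pts(v, 1)); ty1 = std::max(ty1, pts(v, 1));
    }
    int i0 = std::max(0, std::min(G - 1, (int)((tx0 - xmin) / spanx * G)));
    int i1 = std::max(0, std::min(G - 1, (int)((tx1 - xmin) / spanx * G)));
    int j0 = std::max(0, std::min(G - 1, (int)((ty0 - ymin) / spany * G)));
    int j1 = std::max(0, std::min(G - 1, (int)((ty1 - ymin) / spany * G)));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j) bucket[i * G + j].push_back(t);
  }

  NumericVector out(nq, NA_REAL);
  const double tol = -1e-9;
  for (int q = 0; q < nq; ++q) {
    double x = qx[q], y = qy[q];
    if (x < xmin || x > xmax || y < ymin || y > ymax) continue;
    int bi = std::max(0, std::min(G - 1, (int)((x - xmin) / spanx * G)));
    int bj = std::max(0, std::min(G - 1, (int)((y - ymin) / spany * G)));
    const std::vector<int> &cand = bucket[bi * G + bj];
    for (size_t c = 0; c < cand.size(); ++c) {
      int t = cand[c];
      int v0 = tri(t, 0) - 1, v1 = tri(t, 1) - 1, v2 = tri(t, 2) - 1;
      double x0 = pts(v0, 0), y0 = pts(v0, 1);
      double x1 = pts(v1, 0), y1 = pts(v1, 1);
      double x2 = pts(v2, 0), y2 = pts(v2, 1);
      double det = (y1 - y2) * (x0 - x2) + (x2 - x1) * (y0 - y2);
      if (std::fabs(det) < 1e-300) continue;
      double l0 = ((y1 - y2) * (x - x2) + (x2 - x1) * (y - y2)) / det;
      double l1 = ((y2 - y0) * (x - x2) + (x0 - x2) * (y - y2)) / det;
      double l2 = 1.0 - l0 - l1;
      if (l0 < tol || l1 < tol || l2 < tol) continue;

      double f0 = z[v0], f1 = z[v1], f2 = z[v2];
      double e01 = f0 + (grad(v0, 0) * (x1 - x0) + grad(v0, 1) * (y1 - y0)) / 3.0;
      double e02 = f0 + (grad(v0, 0) * (x2 - x0) + grad(v0, 1) * (y2 - y0)) / 3.0;
      double e10 = f1 + (grad(v1, 0) * (x0 - x1) + grad(v1, 1) * (y0 - y1)) / 3.0;
      double e12 = f1 + (grad(v1, 0) * (x2 - x1) + grad(v1, 1) * (y2 - y1)) / 3.0;
      double e20 = f2 + (grad(v2, 0) * (x0 - x2) + grad(v2, 1) * (y0 - y2)) / 3.0;
      double e21 = f2 + (grad(v2, 0) * (x1 - x2) + grad(v2, 1) * (y1 - y2)) / 3.0;
      double b111 = 0.25 * (e01 + e02 + e10 + e12 + e20 + e21) -
                    (f0 + f1 + f2) / 6.0;
      out[q] = f0 * l0 * l0 * l0 + f1 * l1 * l1 * l1 + f2 * l2 * l2 * l2 +
               3.0 * (e01 * l0 * l0 * l1 + e02 * l0 * l0 * l2 +
                      e10 * l1 * l1 * l0 + e12 * l1 * l1 * l2 +
                      e20 * l2 * l2 * l0 + e21 * l2 * l2 * l1) +
               6.0 * b111 * l0 * l1 * l2;
      break;
    }
  }
  return out;
}
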