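#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming alignment of two square-root-velocity curves sampled
// on a uniform grid. Finds a piecewise-linear non-decreasing warping
// gamma: [0,1] -> [0,1] (gamma(0)=0, gamma(1)=1) on the grid that minimises
//   int || q1(t) - q2(gamma(t)) * sqrt(gamma'(t)) ||^2 dt,
// restricted to local slopes a/b with 1 <= a,b <= slope_max.
// q1, q2 are n x 2 matrices; returns the optimal cost and the warped grid.

// [[Rcpp::export]]
List srvf_dp_align(NumericMatrix q1, NumericMatrix q2, int slope_max = 3) {
  const int n = q1.nrow();
  if (q2.nrow() != n) stop("grids must match");
  const double INF = R_PosInf;
  NumericMatrix E(n, n);
  IntegerMatrix Pi(n, n), Pj(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) E(i, j) = INF;
  E(0, 0) = 0.0;

  const double dt = 1.0 / (n - 1);

  for (int i = 1; i < n; ++i) {
    for (int j = 1; j < n; ++j) {
      double best = INF;
      int bi = -1, bj = -1;
      for (int a = 1; a <= slope_max; ++a) {
        for (int b = 1; b <= slope_max; ++b) {
          int ip = i - a, jp = j - b;
          if (ip < 0 || jp < 0) continue;
          if (E(ip, jp) == INF) continue;
          // segment from (ip,jp) to (i,j): slope s = b/a in gamma,
          // integrate squared residual along the a steps in t
          double s = double(b) / double(a);
          double sq = std::sqrt(s);
          double seg = 0.0;
          for (int k = 1; k <= a; ++k) {
            int ti = ip + k;
            double gj = jp + s * k;             // fractional q2 index
            int j0 = (int)std::floor(gj);
            double w = gj - j0;
            if (j0 >= n - 1) { j0 = n - 2; w = 1.0; }
            double q2x = (1 - w) * q2(j0, 0) + w * q2(j0 + 1, 0);
            double q2y = (1 - w) * q2(j0, 1) + w * q2(j0 + 1, 1);
            double rx = q1(ti, 0) - sq * q2x;
            double ry = q1(ti, 1) - sq * q2y;
            seg += (rx * rx + ry * ry) * dt;
          }
          double tot = E(ip, jp) + seg;
          if (tot < best) { best = tot; bi = ip; bj = jp; }
        }
      }
      E(i, j) = best;
      Pi(i, j) = bi;
      Pj(i, j) = bj;
    }
  }

  // backtrack gamma on the grid
  NumericVector gamma(n);
  {
    int i = n - 1, j = n - 1;
    std::vector<int> is, js;
    while (i > 0 || j > 0) {
      is.push_back(i); js.push_back(j);
      int pi = Pi(i, j), pj = Pj(i, j);
      if (pi < 0) break; // unreachable corner (should not happen)
      i = pi; j = pj;
    }
    is.push_back(0); js.push_back(0);
    std::reverse(is.begin(), is.end());
    std::reverse(js.begin(), js.end());
    // piecewise-linear interpolation of j as a function of i
    for (size_t k = 0; k + 1 < is.size(); ++k) {
      int i0 = is[k], i1 = is[k + 1];
      double j0 = js[k], j1 = js[k + 1];
      for (int t = i0; t <= i1; ++t) {
        double w = (i1 == i0) ? 0.0 : double(t - i0) / double(i1 - i0);
        gamma[t] = ((1 - w) * j0 + w * j1) * dt;
      }
    }
    gamma[n - 1] = 1.0;
  }

  return List::create(Named("cost") = E(n - 1, n - 1),
                      Named("gamma") = gamma);
}
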