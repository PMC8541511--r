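// Primal-dual hybrid gradient inner loop for the relaxed Chan-Vese
// segmentation. Arrays are column-major sx x sy x t; TV couples pixels
// within a frame only (spatial forward differences, replicate boundary).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".pdhg_core")]]
List pdhg_core(NumericVector gradG, int sx, int sy, int nt,
               double lam1, double tau, double sigma,
               int n_iters, bool iso, IntegerVector trace_iters) {
  const R_xlen_t n = (R_xlen_t)sx * sy * nt;
  std::vector<double> b(n, 0.0), bbar(n, 0.0), px(n, 0.0), py(n, 0.0);
  NumericVector trace(trace_iters.size());
  int ti = 0;
  const R_xlen_t fstride = (R_xlen_t)sx * sy;

  for (int it = 1; it <= n_iters; ++it) {
    // dual ascent + projection
    for (int f = 0; f < nt; ++f) {
      const R_xlen_t off = f * fstride;
      for (int j = 0; j < sy; ++j) {
        const R_xlen_t cj = off + (R_xlen_t)j * sx;
        for (int i = 0; i < sx; ++i) {
          const R_xlen_t v = cj + i;
          const double gx = (i < sx - 1) ? bbar[v + 1] - bbar[v] : 0.0;
          const double gy = (j < sy - 1) ? bbar[v + sx] - bbar[v] : 0.0;
          double pxv = px[v] + sigma * gx;
          double pyv = py[v] + sigma * gy;
          if (iso) {
            const double nrm2 = pxv * pxv + pyv * pyv;
            if (nrm2 > lam1 * lam1) {
              const double s = lam1 / std::sqrt(nrm2);
              pxv *= s;
              pyv *= s;
            }
          } else {
            if (pxv > lam1) pxv = lam1; else if (pxv < -lam1) pxv = -lam1;
            if (pyv > lam1) pyv = lam1; else if (pyv < -lam1) pyv = -lam1;
          }
          px[v] = pxv;
          py[v] = pyv;
        }
      }
    }
    // primal descent (D^T p), clip to [0,1], extrapolate
    for (int f = 0; f < nt; ++f) {
      const R_xlen_t off = f * fstride;
      for (int j = 0; j < sy; ++j) {
        const R_xlen_t cj = off + (R_xlen_t)j * sx;
        for (int i = 0; i < sx; ++i) {
          const R_xlen_t v = cj + i;
          double div = -px[v] - py[v];
          if (i > 0) div += px[v - 1];
          if (j > 0) div += py[v - sx];
          double bn = b[v] - tau * (div + gradG[v]);
          if (bn < 0.0) bn = 0.0; else if (bn > 1.0) bn = 1.0;
          bbar[v] = 2.0 * bn - b[v];
          b[v] = bn;
        }
      }
    }
    if (ti < trace_iters.size() && it == trace_iters[ti]) {
      double e = 0.0;
      for (int f = 0; f < nt; ++f) {
        const R_xlen_t off = f * fstride;
        for (int j = 0; j < sy; ++j) {
          const R_xlen_t cj = off + (R_xlen_t)j * sx;
          for (int i = 0; i < sx; ++i) {
            const R_xlen_t v = cj + i;
            e += gradG[v] * b[v];
            const double gx = (i < sx - 1) ? b[v + 1] - b[v] : 0.0;
            const double gy = (j < sy - 1) ? b[v + sx] - b[v] : 0.0;
            e += lam1 * (iso ? std::sqrt(gx * gx + gy * gy)
                             : std::abs(gx) + std::abs(gy));
          }
        }
      }
      trace[ti++] = e;
    }
  }
  NumericVector bout(b.begin(), b.end());
  return List::create(_["b"] = bout, _["trace"] = trace);
}
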