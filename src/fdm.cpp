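#include <Rcpp.h>
using namespace Rcpp;

// Successive over-relaxation solve of div(sigma grad phi) = 0 on a regular
// voxel lattice with harmonic-mean face conductivities. Dirichlet nodes:
// `dirichlet_idx` (0-based linear, column-major) held at 1, and the outer
// grid boundary held at 0 (the return/ground). The constant face area/
// spacing factor cancels and is omitted.
// [[Rcpp::export]]
List fdm_sor(NumericVector sigma, IntegerVector dims,
             IntegerVector dirichlet_idx, double tol, int max_sweeps,
             double omega) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> phi(n, 0.0);
  std::vector<char> fixed(n, 0);

  // outer boundary grounded
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 ||
            k == nz - 1)
          fixed[(R_xlen_t)i + nx * (j + (R_xlen_t)ny * k)] = 1;
  for (int m = 0; m < dirichlet_idx.size(); ++m) {
    R_xlen_t id = dirichlet_idx[m];
    phi[id] = 1.0;
    fixed[id] = 1;
  }

  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  auto hm = [](double a, double b) {
    double s = a + b;
    return s > 0 ? 2.0 * a * b / s : 0.0;
  };

  double res0 = -1.0, rel = NA_REAL;
  int sweep = 0;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    double res2 = 0.0;
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j) {
        R_xlen_t base = nx * (j + (R_xlen_t)ny * k);
        for (int i = 1; i < nx - 1; ++i) {
          R_xlen_t id = base + i;
          if (fixed[id]) continue;
          double s0 = sigma[id];
          double cxm = hm(s0, sigma[id - sx]), cxp = hm(s0, sigma[id + sx]);
          double cym = hm(s0, sigma[id - sy]), cyp = hm(s0, sigma[id + sy]);
          double czm = hm(s0, sigma[id - sz]), czp = hm(s0, sigma[id + sz]);
          double csum = cxm + cxp + cym + cyp + czm + czp;
          if (csum <= 0) continue;
          double num = cxm * phi[id - sx] + cxp * phi[id + sx] +
                       cym * phi[id - sy] + cyp * phi[id + sy] +
                       czm * phi[id - sz] + czp * phi[id + sz];
          double r = num - csum * phi[id];
          res2 += r * r;
          phi[id] += omega * r / csum;
        }
      }
    double res = std::sqrt(res2);
    if (res0 < 0) res0 = res > 0 ? res : 1.0;
    rel = res / res0;
    if (rel <= tol) break;
  }

  NumericVector out(n);
  std::copy(phi.begin(), phi.end(), out.begin());
  return List::create(_["phi"] = out, _["sweeps"] = sweep + 1,
                      _["rel_residual"] = rel,
                      _["converged"] = (rel <= tol));
}
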