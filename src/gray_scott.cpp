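#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Explicit-Euler integration of the Gray-Scott system
//   du/dt = Du lap(u) - u v^2 + f (1 - u)
//   dv/dt = Dv lap(v) + u v^2 - (f + k) v
// 5-point Laplacian; Dv may vary per pixel (foveated mosaics).
// Boundary: periodic (torus) or zero-flux (reflect).
// Divergence is checked every `check_every` steps; the step index at which a
// non-finite value first appeared (to within the check stride) is reported.

// [[Rcpp::export(name = ".gs_advance")]]
List gs_advance(NumericMatrix u0, NumericMatrix v0, double Du, NumericMatrix Dv,
                double f, double k, double dt, int n_steps, bool periodic,
                int check_every, int t0) {
  const int nr = u0.nrow(), nc = u0.ncol();
  const bool dv_scalar = (Dv.nrow() == 1 && Dv.ncol() == 1);
  const double dv0 = Dv(0, 0);
  const double fk = f + k;

  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> un(nr * nc), vn(nr * nc);
  const double *dvp = REAL(Dv);

  // neighbour index maps for the boundary condition
  std::vector<int> up(nr), dn(nr), lf(nc), rt(nc);
  for (int i = 0; i < nr; ++i) {
    up[i] = i == 0 ? (periodic ? nr - 1 : 1) : i - 1;
    dn[i] = i == nr - 1 ? (periodic ? 0 : nr - 2) : i + 1;
  }
  for (int j = 0; j < nc; ++j) {
    lf[j] = j == 0 ? (periodic ? nc - 1 : 1) : j - 1;
    rt[j] = j == nc - 1 ? (periodic ? 0 : nc - 2) : j + 1;
  }

  for (int s = 0; s < n_steps; ++s) {
    const double *pu = u.data(), *pv = v.data();
    double *qu = un.data(), *qv = vn.data();
    for (int j = 0; j < nc; ++j) {
      const double *cu = pu + (size_t)j * nr, *cv = pv + (size_t)j * nr;
      const double *luu = pu + (size_t)lf[j] * nr, *ruu = pu + (size_t)rt[j] * nr;
      const double *lvv = pv + (size_t)lf[j] * nr, *rvv = pv + (size_t)rt[j] * nr;
      const double *dvc = dv_scalar ? nullptr : dvp + (size_t)j * nr;
      double *ou = qu + (size_t)j * nr, *ov = qv + (size_t)j * nr;
      for (int i = 0; i < nr; ++i) {
        const double uc = cu[i], vc = cv[i];
        const double lap_u = cu[up[i]] + cu[dn[i]] + luu[i] + ruu[i] - 4.0 * uc;
        const double lap_v = cv[up[i]] + cv[dn[i]] + lvv[i] + rvv[i] - 4.0 * vc;
        const double uvv = uc * vc * vc;
        const double dv = dv_scalar ? dv0 : dvc[i];
        ou[i] = uc + dt * (Du * lap_u - uvv + f * (1.0 - uc));
        ov[i] = vc + dt * (dv * lap_v + uvv - fk * vc);
      }
    }
    u.swap(un);
    v.swap(vn);
    if ((s + 1) % check_every == 0 || s == n_steps - 1) {
      bool bad = false;
      for (size_t q = 0; q < u.size(); ++q)
        if (!std::isfinite(u[q]) || !std::isfinite(v[q])) { bad = true; break; }
      if (bad)
        stop("unstable coefficients: non-finite concentrations at step %d",
             t0 + s + 1);
    }
    if ((s + 1) % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix uo(nr, nc), vo(nr, nc);
  std::copy(u.begin(), u.end(), uo.begin());
  std::copy(v.begin(), v.end(), vo.begin());
  return List::create(_["u"] = uo, _["v"] = vo, _["t"] = t0 + n_steps);
}
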