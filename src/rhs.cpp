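// Compiled right-hand side of the aggregation PDE system.
//
// Mirrors the R reference implementation (worm_rhs/chemical_rhs): flux-form
// fourth-order periodic finite differences. The stiff integrator calls this
// kernel thousands of times per run (including Jacobian estimation by
// finite differences), so it is the one hot path kept in C++. Fields are
// flat column-major nx x ny arrays (x fastest); ny == 1 gives the 1D model.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline int wrap(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// [[Rcpp::export]]
NumericVector ks_rhs_cpp(NumericVector y, List pars, int nx, int ny,
                         double hx, double hy) {
  const int np = nx * ny;
  const bool rep = as<bool>(pars["repellent"]);
  const int nf = rep ? 3 : 2;
  if (y.size() != nf * np) stop("state vector has wrong length");

  const double sigma = as<double>(pars["sigma"]);
  const double rho_max = as<double>(pars["rho_max"]);
  const double cushion = as<double>(pars["cushion"]);
  const double scale = as<double>(pars["scale"]);
  const double beta_a = as<double>(pars["beta_a"]);
  const double alpha_a = as<double>(pars["alpha_a"]);
  const double gamma_a = as<double>(pars["gamma_a"]);
  const double D_a = as<double>(pars["D_a"]);
  const double s_a = as<double>(pars["s_a"]);
  const double beta_r = rep ? as<double>(pars["beta_r"]) : 0.0;
  const double alpha_r = rep ? as<double>(pars["alpha_r"]) : 1.0;
  const double gamma_r = rep ? as<double>(pars["gamma_r"]) : 0.0;
  const double D_r = rep ? as<double>(pars["D_r"]) : 0.0;
  const double s_r = rep ? as<double>(pars["s_r"]) : 0.0;

  const double* rho = y.begin();
  const double* Ua = y.begin() + np;
  const double* Ur = rep ? y.begin() + 2 * np : nullptr;

  // Total movement potential; arguments clamped at zero so Jacobian
  // probing with slightly negative trial values stays finite.
  std::vector<double> V(np);
  for (int q = 0; q < np; ++q) {
    double rc = rho[q] > 0.0 ? rho[q] : 0.0;
    double ua = Ua[q] > 0.0 ? Ua[q] : 0.0;
    double v = -beta_a * std::log(alpha_a + ua) +
               0.5 * sigma * scale * (1.0 + std::tanh((rc - rho_max) / cushion));
    if (rep) {
      double ur = Ur[q] > 0.0 ? Ur[q] : 0.0;
      v -= beta_r * std::log(alpha_r + ur);
    }
    V[q] = v;
  }

  NumericVector dy(nf * np);
  double* drho = dy.begin();
  double* dUa = dy.begin() + np;
  double* dUr = rep ? dy.begin() + 2 * np : nullptr;

  for (int q = 0; q < np; ++q) {
    dUa[q] = -gamma_a * Ua[q] + s_a * rho[q];
    if (rep) dUr[q] = -gamma_r * Ur[q] + s_r * rho[q];
  }

  // face buffers along one axis: worm flux, signal face gradients
  std::vector<double> fw(np), fa(np), fr(rep ? np : 0);

  // x direction
  for (int j = 0; j < ny; ++j) {
    const int base = j * nx;
    for (int i = 0; i < nx; ++i) {
      const int q0 = base + i;
      const int qp1 = base + wrap(i + 1, nx);
      const int qp2 = base + wrap(i + 2, nx);
      const int qm1 = base + wrap(i - 1, nx);
      const double c = 1.0 / (24.0 * hx);
      const double gV = (27.0 * (V[qp1] - V[q0]) - (V[qp2] - V[qm1])) * c;
      const double gR = (27.0 * (rho[qp1] - rho[q0]) - (rho[qp2] - rho[qm1])) * c;
      const double rf =
          (9.0 * (rho[q0] + rho[qp1]) - (rho[qm1] + rho[qp2])) / 16.0;
      fw[q0] = rf * gV + sigma * gR;
      fa[q0] = (27.0 * (Ua[qp1] - Ua[q0]) - (Ua[qp2] - Ua[qm1])) * c;
      if (rep)
        fr[q0] = (27.0 * (Ur[qp1] - Ur[q0]) - (Ur[qp2] - Ur[qm1])) * c;
    }
    for (int i = 0; i < nx; ++i) {
      const int q0 = base + i;
      const int qm1 = base + wrap(i - 1, nx);
      const int qp1 = base + wrap(i + 1, nx);
      const int qm2 = base + wrap(i - 2, nx);
      const double c = 1.0 / (24.0 * hx);
      drho[q0] += (27.0 * (fw[q0] - fw[qm1]) - (fw[qp1] - fw[qm2])) * c;
      dUa[q0] += D_a * (27.0 * (fa[q0] - fa[qm1]) - (fa[qp1] - fa[qm2])) * c;
      if (rep)
        dUr[q0] += D_r * (27.0 * (fr[q0] - fr[qm1]) - (fr[qp1] - fr[qm2])) * c;
    }
  }

  // y direction (absent for 1D fields)
  if (ny > 1) {
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) {
        const int q0 = j * nx + i;
        const int qp1 = wrap(j + 1, ny) * nx + i;
        const int qp2 = wrap(j + 2, ny) * nx + i;
        const int qm1 = wrap(j - 1, ny) * nx + i;
        const double c = 1.0 / (24.0 * hy);
        const double gV = (27.0 * (V[qp1] - V[q0]) - (V[qp2] - V[qm1])) * c;
        const double gR =
            (27.0 * (rho[qp1] - rho[q0]) - (rho[qp2] - rho[qm1])) * c;
        const double rf =
            (9.0 * (rho[q0] + rho[qp1]) - (rho[qm1] + rho[qp2])) / 16.0;
        fw[q0] = rf * gV + sigma * gR;
        fa[q0] = (27.0 * (Ua[qp1] - Ua[q0]) - (Ua[qp2] - Ua[qm1])) * c;
        if (rep)
          fr[q0] = (27.0 * (Ur[qp1] - Ur[q0]) - (Ur[qp2] - Ur[qm1])) * c;
      }
      for (int j = 0; j < ny; ++j) {
        const int q0 = j * nx + i;
        const int qm1 = wrap(j - 1, ny) * nx + i;
        const int qp1 = wrap(j + 1, ny) * nx + i;
        const int qm2 = wrap(j - 2, ny) * nx + i;
        const double c = 1.0 / (24.0 * hy);
        drho[q0] += (27.0 * (fw[q0] - fw[qm1]) - (fw[qp1] - fw[qm2])) * c;
        dUa[q0] += D_a * (27.0 * (fa[q0] - fa[qm1]) - (fa[qp1] - fa[qm2])) * c;
        if (rep)
          dUr[q0] += D_r * (27.0 * (fr[q0] - fr[qm1]) - (fr[qp1] - fr[qm2])) * c;
      }
    }
  }

  return dy;
}
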