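// 2-D TMz FDTD kernel on the Yee grid with CPML absorbing boundaries.
//
// Field layout (nx x ny cells, dx = dy):
//   Ez(i, j)       i = 0..nx-1, j = 0..ny-1   (cell corners)
//   Hx(i, j+1/2)   nx x (ny-1)
//   Hy(i+1/2, j)   (nx-1) x ny
// Lossy-medium Ez update with the standard (1 +- sigma*dt/2eps) coefficients.
// CPML after Roden & Gedney: polynomial-graded sigma, linear-graded alpha,
// kappa = 1; psi accumulators updated only inside the PML slabs.
// pml_cells = 0 degenerates to a PEC box (outermost Ez ring is always 0).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double C0   = 299792458.0;
static const double MU0  = 4.0e-7 * M_PI;
static const double EPS0 = 1.0 / (MU0 * C0 * C0);
static const double ETA0 = 376.730313668;

struct PmlProfile {
  // b, c at every 1-D position (integer for E, half-integer for H);
  // b = 1, c = 0 outside the PML slabs so psi stays zero there.
  std::vector<double> be, ce, bh, ch;
};

static PmlProfile make_profile(int n, int npml, double dt, double m,
                               double r0, double alpha_max, double dx) {
  PmlProfile p;
  p.be.assign(n, 1.0);  p.ce.assign(n, 0.0);
  p.bh.assign(n - 1, 1.0); p.ch.assign(n - 1, 0.0);
  if (npml <= 0) return p;
  const double L = npml * dx;
  const double smax = -(m + 1.0) * std::log(r0) / (2.0 * ETA0 * L);
  auto grade = [&](double depth_frac, double& b, double& c) {
    if (depth_frac <= 0.0) return;
    double rho = std::min(depth_frac, 1.0);
    double sig = smax * std::pow(rho, m);
    double alp = alpha_max * (1.0 - rho);
    b = std::exp(-(sig / EPS0 + alp / EPS0) * dt);
    c = (sig + alp > 0.0) ? sig * (b - 1.0) / (sig + alp) : 0.0;
  };
  for (int i = 0; i < n; ++i) {
    double dl = (npml - i) / (double)npml;            // depth from left inner edge
    double dr = (i - (n - 1 - npml)) / (double)npml;  // depth from right inner edge
    grade(dl, p.be[i], p.ce[i]);
    grade(dr, p.be[i], p.ce[i]);
  }
  for (int i = 0; i < n - 1; ++i) {
    double pos = i + 0.5;
    double dl = (npml - pos) / (double)npml;
    double dr = (pos - (n - 1 - npml)) / (double)npml;
    grade(dl, p.bh[i], p.ch[i]);
    grade(dr, p.bh[i], p.ch[i]);
  }
  return p;
}

// [[Rcpp::export(name = ".fdtd_run_cpp")]]
List fdtd_run_cpp(NumericMatrix eps_r, NumericMatrix sigma,
                  double dx, double dt, int nsteps,
                  IntegerVector src_i, IntegerVector src_j, NumericMatrix src_wf,
                  IntegerVector rx_i, IntegerVector rx_j,
                  int pml_cells, double pml_m, double pml_r0, double pml_alpha,
                  bool record_energy,
                  Nullable<NumericVector> step_weights = R_NilValue,
                  Nullable<LogicalMatrix> energy_mask = R_NilValue) {
  const int nx = eps_r.nrow(), ny = eps_r.ncol();
  if (sigma.nrow() != nx || sigma.ncol() != ny)
    stop("eps_r and sigma maps must have identical shape");
  const double courant = C0 * dt / dx;
  if (courant > 1.0 / std::sqrt(2.0) + 1e-12)
    stop("timestep violates the 2-D Courant bound dt <= dx/(c*sqrt(2)): c*dt/dx = %f", courant);
  const int nsrc = src_i.size(), nrx = rx_i.size();
  if (src_wf.ncol() != nsrc || src_wf.nrow() != nsteps)
    stop("src_wf must be nsteps x nsrc");
  for (int s = 0; s < nsrc; ++s)
    if (src_i[s] < 1 || src_i[s] >= nx - 1 || src_j[s] < 1 || src_j[s] >= ny - 1)
      stop("source cell outside interior");
  for (int r = 0; r < nrx; ++r)
    if (rx_i[r] < 0 || rx_i[r] >= nx || rx_j[r] < 0 || rx_j[r] >= ny)
      stop("receiver cell outside grid");

  std::vector<double> Ez((size_t)nx * ny, 0.0);
  std::vector<double> Hx((size_t)nx * (ny - 1), 0.0);
  std::vector<double> Hy((size_t)(nx - 1) * ny, 0.0);
  // psi accumulators (full-size allocation, strip-limited updates)
  std::vector<double> pEzx((size_t)nx * ny, 0.0), pEzy((size_t)nx * ny, 0.0);
  std::vector<double> pHyx((size_t)(nx - 1) * ny, 0.0), pHxy((size_t)nx * (ny - 1), 0.0);

  // column-major like R: index (i, j) -> i + j*nrow
  auto EZ = [&](int i, int j) -> double& { return Ez[(size_t)i + (size_t)j * nx]; };
  auto HX = [&](int i, int j) -> double& { return Hx[(size_t)i + (size_t)j * nx]; };
  auto HY = [&](int i, int j) -> double& { return Hy[(size_t)i + (size_t)j * (nx - 1)]; };

  // precomputed Ez update coefficients
  std::vector<double> Ca((size_t)nx * ny), Cb((size_t)nx * ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double eps = eps_r(i, j) * EPS0;
      double a = sigma(i, j) * dt / (2.0 * eps);
      Ca[(size_t)i + (size_t)j * nx] = (1.0 - a) / (1.0 + a);
      Cb[(size_t)i + (size_t)j * nx] = (dt / eps) / (1.0 + a);
    }

  const PmlProfile px = make_profile(nx, pml_cells, dt, pml_m, pml_r0, pml_alpha, dx);
  const PmlProfile py = make_profile(ny, pml_cells, dt, pml_m, pml_r0, pml_alpha, dx);
  const int np = std::max(pml_cells, 0);
  const double ch_mu = dt / (MU0 * dx);
  const double inv_dx = 1.0 / dx;

  NumericMatrix traces(nsteps, nrx);
  NumericMatrix energy(record_energy ? nx : 1, record_energy ? ny : 1);
  NumericVector step_energy(record_energy ? nsteps : 0);
  std::vector<double> wts(nsteps, 1.0);
  if (step_weights.isNotNull()) {
    NumericVector w(step_weights);
    if (w.size() != nsteps) stop("step_weights must have length nsteps");
    for (int n = 0; n < nsteps; ++n) wts[n] = w[n];
  }
  std::vector<char> emask;
  if (energy_mask.isNotNull()) {
    LogicalMatrix mm(energy_mask);
    if (mm.nrow() != nx || mm.ncol() != ny) stop("energy_mask shape mismatch");
    emask.resize((size_t)nx * ny);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        emask[(size_t)i + (size_t)j * nx] = mm(i, j) ? 1 : 0;
  }

  for (int n = 0; n < nsteps; ++n) {
    // --- H updates ---
    for (int j = 0; j < ny - 1; ++j) {
      const bool pml_j = (j < np) || (j >= ny - 1 - np);
      double* ez0 = &Ez[(size_t)j * nx];
      double* ez1 = &Ez[(size_t)(j + 1) * nx];
      double* hx = &Hx[(size_t)j * nx];
      if (pml_j) {
        const double b = py.bh[j], c = py.ch[j];
        double* ps = &pHxy[(size_t)j * nx];
        for (int i = 0; i < nx; ++i) {
          double dEzdy = (ez1[i] - ez0[i]) * inv_dx;
          ps[i] = b * ps[i] + c * dEzdy;
          hx[i] -= ch_mu * dx * (dEzdy + ps[i]);
        }
      } else {
        for (int i = 0; i < nx; ++i)
          hx[i] -= ch_mu * (ez1[i] - ez0[i]);
      }
    }
    for (int j = 0; j < ny; ++j) {
      double* ez = &Ez[(size_t)j * nx];
      double* hy = &Hy[(size_t)j * (nx - 1)];
      double* ps = &pHyx[(size_t)j * (nx - 1)];
      for (int i = 0; i < nx - 1; ++i) {
        double dEzdx = (ez[i + 1] - ez[i]) * inv_dx;
        if (px.ch[i] != 0.0 || px.bh[i] != 1.0) {
          ps[i] = px.bh[i] * ps[i] + px.ch[i] * dEzdx;
          hy[i] += ch_mu * dx * (dEzdx + ps[i]);
        } else {
          hy[i] += ch_mu * dx * dEzdx;
        }
      }
    }
    // --- Ez update (interior; boundary ring stays 0 = PEC backing) ---
    for (int j = 1; j < ny - 1; ++j) {
      const bool pml_j = (j <= np) || (j >= ny - 1 - np);
      double* ez = &Ez[(size_t)j * nx];
      double* hxj = &Hx[(size_t)j * nx];
      double* hxm = &Hx[(size_t)(j - 1) * nx];
      double* hyj = &Hy[(size_t)j * (nx - 1)];
      double* ca = &Ca[(size_t)j * nx];
      double* cb = &Cb[(size_t)j * nx];
      double* psx = &pEzx[(size_t)j * nx];
      double* psy = &pEzy[(size_t)j * nx];
      const double bey = py.be[j], cey = py.ce[j];
      for (int i = 1; i < nx - 1; ++i) {
        double dHydx = (hyj[i] - hyj[i - 1]) * inv_dx;
        double dHxdy = (hxj[i] - hxm[i]) * inv_dx;
        const bool pml_i = (i <= np) || (i >= nx - 1 - np);
        if (pml_i) {
          psx[i] = px.be[i] * psx[i] + px.ce[i] * dHydx;
          dHydx += psx[i];
        }
        if (pml_j) {
          psy[i] = bey * psy[i] + cey * dHxdy;
          dHxdy += psy[i];
        }
        ez[i] = ca[i] * ez[i] + cb[i] * (dHydx - dHxdy);
      }
    }
    // --- soft sources ---
    for (int s = 0; s < nsrc; ++s)
      EZ(src_i[s], src_j[s]) += src_wf(n, s);
    // --- record ---
    for (int r = 0; r < nrx; ++r)
      traces(n, r) = EZ(rx_i[r], rx_j[r]);
    if (record_energy) {
      const double w = wts[n];
      double se = 0.0;
      const bool masked = !emask.empty();
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double v = EZ(i, j);
          double v2 = v * v;
          energy(i, j) += w * v2;
          if (!masked || emask[(size_t)i + (size_t)j * nx]) se += v2;
        }
      step_energy[n] = se;
    }
    if ((n & 255) == 255) {
      double probe = EZ(nx / 2, ny / 2);
      if (!std::isfinite(probe) || std::fabs(probe) > 1e30)
        stop("FDTD solution diverged at step %d; check the Courant bound dt <= dx/(c*sqrt(2))", n);
      Rcpp::checkUserInterrupt();
    }
  }

  List out = List::create(_["traces"] = traces);
  if (record_energy) {
    out["energy"] = energy;
    out["step_energy"] = step_energy;
  }
  return out;
}
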