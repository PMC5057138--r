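// Transport kernels: first-order upwind (donor-cell) advection step and the
// continuity-based vertical-velocity diagnosis, both on the staggered
// C-grid. Index conventions match the R side: column-major arrays, layer
// k = 0 at the bottom, u on x-faces [nx+1, ny, nz], v on y-faces
// [nx, ny+1, nz], w on interfaces [nx, ny, nz+1].

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List upwind_step_cpp(NumericVector C_, NumericVector u_, NumericVector v_,
                     NumericVector wf_, NumericVector Hzu_, NumericVector Hzv_,
                     NumericVector Hz_, int nx, int ny, int nz,
                     double dx, double dy, double dt) {
  NumericVector div_(nx * ny * nz);         // net outward flux per cell
  NumericVector dep_(nx * ny);              // deposited mass per column
  NumericVector Cnew_(nx * ny * nz);
  const double *C = C_.begin(), *u = u_.begin(), *v = v_.begin(),
    *wf = wf_.begin(), *Hzu = Hzu_.begin(), *Hzv = Hzv_.begin(),
    *Hz = Hz_.begin();
  double *div = div_.begin(), *dep = dep_.begin(), *Cnew = Cnew_.begin();
  double boundary_mass = 0.0;
  double cmax_x = 0.0, cmax_y = 0.0, cmax_z = 0.0;
  const double area = dx * dy;

  // x-faces: face f = i + (nx+1)*(j + ny*k), cells c = i + nx*(j + ny*k)
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const int bf = (nx + 1) * (j + ny * k);
      const int bc = nx * (j + ny * k);
      for (int i = 0; i <= nx; ++i) {
        const double uf = u[bf + i];
        if (uf == 0.0) continue;
        const int il = (i > 0 ? i - 1 : 0), ir = (i < nx ? i : nx - 1);
        const double cdon = uf > 0.0 ? C[bc + il] : C[bc + ir];
        const double F = uf * Hzu[bf + i] * dy * cdon;
        const double cr = std::fabs(uf) * dt / dx;
        if (cr > cmax_x) cmax_x = cr;
        if (i > 0)  div[bc + i - 1] += F;
        if (i < nx) div[bc + i] -= F;
        if (i == 0)  boundary_mass -= F * dt;
        if (i == nx) boundary_mass += F * dt;
      }
    }
  }
  // y-faces: face f = i + nx*(j + (ny+1)*k)
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j <= ny; ++j) {
      const int bf = nx * (j + (ny + 1) * k);
      const int bl = nx * ((j > 0 ? j - 1 : 0) + ny * k);
      const int br = nx * ((j < ny ? j : ny - 1) + ny * k);
      const int bd = nx * (j + ny * k);        // own-row cell base (j < ny)
      for (int i = 0; i < nx; ++i) {
        const double vf = v[bf + i];
        if (vf == 0.0) continue;
        const double cdon = vf > 0.0 ? C[bl + i] : C[br + i];
        const double F = vf * Hzv[bf + i] * dx * cdon;
        const double cr = std::fabs(vf) * dt / dy;
        if (cr > cmax_y) cmax_y = cr;
        if (j > 0)  div[bl + i] += F;          // bl is cell j-1 when j > 0
        if (j < ny) div[bd + i] -= F;
        if (j == 0)  boundary_mass -= F * dt;
        if (j == ny) boundary_mass += F * dt;
      }
    }
  }
  // vertical faces; the top interface (kf = nz) carries no flux
  const int nxy = nx * ny;
  for (int kf = 0; kf < nz; ++kf) {
    const int bw = nxy * kf;
    const int bdn = nxy * (kf > 0 ? kf - 1 : 0); // donor below for upward flow
    for (int ij = 0; ij < nxy; ++ij) {
      const double w = wf[bw + ij];
      if (w == 0.0) continue;
      const double cdon = w > 0.0 ? C[bdn + ij] : C[bw + ij];
      const double F = w * area * cdon;
      const double hz_min = (kf > 0)
        ? std::min(Hz[bdn + ij], Hz[bw + ij]) : Hz[ij];
      const double cr = std::fabs(w) * dt / hz_min;
      if (cr > cmax_z) cmax_z = cr;
      if (kf > 0) div[bdn + ij] += F;
      div[bw + ij] -= F;
      if (kf == 0) dep[ij] -= F * dt;          // settling out at the seabed
    }
  }

  const int ncell = nx * ny * nz;
  for (int n = 0; n < ncell; ++n)
    Cnew[n] = C[n] - dt * div[n] / (Hz[n] * area);

  return List::create(_["conc"] = Cnew_, _["deposition_mass"] = dep_,
                      _["boundary_mass"] = boundary_mass,
                      _["courant"] = NumericVector::create(cmax_x, cmax_y,
                                                           cmax_z));
}

// [[Rcpp::export]]
NumericVector diagnose_w_cpp(NumericVector u_, NumericVector v_,
                             NumericVector Hzu_, NumericVector Hzv_,
                             int nx, int ny, int nz, double dx, double dy) {
  NumericVector w_(nx * ny * (nz + 1));
  const double *u = u_.begin(), *v = v_.begin(),
    *Hzu = Hzu_.begin(), *Hzv = Hzv_.begin();
  double *w = w_.begin();
  const double area = dx * dy;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const int ij = i + nx * j;
      double flux = 0.0;                       // w = 0 at the seabed
      for (int k = 0; k < nz; ++k) {
        const int fw = i + (nx + 1) * (j + ny * k);
        const int fs = i + nx * (j + (ny + 1) * k);
        const double out =
          u[fw + 1] * Hzu[fw + 1] * dy - u[fw] * Hzu[fw] * dy +
          v[fs + nx] * Hzv[fs + nx] * dx - v[fs] * Hzv[fs] * dx;
        flux -= out;
        w[ij + nx * ny * (k + 1)] = flux / area;
      }
    }
  }
  return w_;
}
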