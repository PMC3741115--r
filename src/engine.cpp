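#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Explicit-Euler reaction-diffusion driver on a 3-D voxel grid.
//
// Per step s (1..n_steps):
//   1. inject quantal events scheduled for step s (ev_ptr is a CSR offset
//      vector into ev_voxel, 0-based linear voxel indices, column-major);
//   2. C <- C + (D*dt/dx^2) * (sum of 6 neighbours - 6C) - dt*k_s*C.
// Uptake uses the post-injection, pre-diffusion concentration, so the mass
// ledger sum(dt*k*C) accounts exactly for what the scheme removes.
//
// boundary: 0 = periodic wrap, 1 = reflecting (zero-flux: ghost = edge voxel).
// Scalar traces are recorded every step; probe-group means every
// record_every steps; the running field average over [avg_from, avg_to].
// [[Rcpp::export(name = ".rd_run_cpp")]]
List rd_run_cpp(NumericVector conc, IntegerVector dim,
                double D, NumericVector k_steps, double dt, double dx,
                IntegerVector ev_ptr, IntegerVector ev_voxel, double inc,
                IntegerVector snap_steps, int boundary,
                int avg_from, int avg_to,
                IntegerVector probe_ptr, IntegerVector probe_voxel,
                int record_every) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (conc.size() != n) stop("field length does not match grid dimensions");
  const int n_steps = k_steps.size();
  const double r = D * dt / (dx * dx);

  std::vector<double> a(conc.begin(), conc.end()), b(n);

  // neighbour index tables per axis
  std::vector<int> xm(nx), xp(nx), ym(ny), yp(ny), zm(nz), zp(nz);
  for (int i = 0; i < nx; ++i) { xm[i] = i - 1; xp[i] = i + 1; }
  for (int i = 0; i < ny; ++i) { ym[i] = i - 1; yp[i] = i + 1; }
  for (int i = 0; i < nz; ++i) { zm[i] = i - 1; zp[i] = i + 1; }
  if (boundary == 0) {            // periodic
    xm[0] = nx - 1; xp[nx - 1] = 0;
    ym[0] = ny - 1; yp[ny - 1] = 0;
    zm[0] = nz - 1; zp[nz - 1] = 0;
  } else {                        // reflecting: zero-flux ghost = self
    xm[0] = 0; xp[nx - 1] = nx - 1;
    ym[0] = 0; yp[ny - 1] = ny - 1;
    zm[0] = 0; zp[nz - 1] = nz - 1;
  }

  NumericVector mean_tr(n_steps), inj_tr(n_steps), upt_tr(n_steps);
  List snapshots(snap_steps.size());
  int next_snap = 0;

  const int n_probes = probe_ptr.size() > 0 ? probe_ptr.size() - 1 : 0;
  int n_rec = (record_every > 0 && n_probes > 0) ? n_steps / record_every : 0;
  NumericMatrix probe_tr(n_rec, n_probes);
  IntegerVector probe_steps(n_rec);
  int rec_row = 0;

  std::vector<double> avg;
  long avg_count = 0;
  if (avg_from > 0 && avg_to >= avg_from) avg.assign(n, 0.0);

  for (int s = 1; s <= n_steps; ++s) {
    const double k = k_steps[s - 1];
    const double dtk = dt * k;

    int e0 = ev_ptr[s - 1], e1 = ev_ptr[s];
    for (int j = e0; j < e1; ++j) a[ev_voxel[j]] += inc;
    inj_tr[s - 1] = (double)(e1 - e0) * inc;

    double upt = 0.0, tot = 0.0;
    for (int z = 0; z < nz; ++z) {
      const R_xlen_t z0 = (R_xlen_t)z * nx * ny;
      const R_xlen_t zmo = (R_xlen_t)zm[z] * nx * ny;
      const R_xlen_t zpo = (R_xlen_t)zp[z] * nx * ny;
      for (int y = 0; y < ny; ++y) {
        const R_xlen_t y0 = z0 + (R_xlen_t)y * nx;
        const R_xlen_t ymo = z0 + (R_xlen_t)ym[y] * nx;
        const R_xlen_t ypo = z0 + (R_xlen_t)yp[y] * nx;
        const R_xlen_t zym = zmo + (R_xlen_t)y * nx;
        const R_xlen_t zyp = zpo + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; ++x) {
          const double c = a[y0 + x];
          const double nn = a[y0 + xm[x]] + a[y0 + xp[x]] +
                            a[ymo + x] + a[ypo + x] +
                            a[zym + x] + a[zyp + x];
          const double v = c + r * (nn - 6.0 * c) - dtk * c;
          b[y0 + x] = v;
          upt += c;
          tot += v;
        }
      }
    }
    upt_tr[s - 1] = upt * dtk;
    mean_tr[s - 1] = tot / (double)n;
    std::swap(a, b);

    if (!avg.empty() && s >= avg_from && s <= avg_to) {
      for (R_xlen_t i = 0; i < n; ++i) avg[i] += a[i];
      ++avg_count;
    }
    if (n_rec > 0 && s % record_every == 0 && rec_row < n_rec) {
      for (int pgi = 0; pgi < n_probes; ++pgi) {
        double acc = 0.0;
        for (int j = probe_ptr[pgi]; j < probe_ptr[pgi + 1]; ++j)
          acc += a[probe_voxel[j]];
        int cnt = probe_ptr[pgi + 1] - probe_ptr[pgi];
        probe_tr(rec_row, pgi) = cnt > 0 ? acc / cnt : NA_REAL;
      }
      probe_steps[rec_row] = s;
      ++rec_row;
    }
    while (next_snap < snap_steps.size() && snap_steps[next_snap] == s) {
      NumericVector sn(a.begin(), a.end());
      sn.attr("dim") = dim;
      snapshots[next_snap] = sn;
      ++next_snap;
    }
  }

  NumericVector fin(a.begin(), a.end());
  fin.attr("dim") = dim;

  List out = List::create(
    _["final"] = fin,
    _["mean_nM"] = mean_tr,
    _["injected_nM_voxel"] = inj_tr,
    _["uptaken_nM_voxel"] = upt_tr,
    _["snapshots"] = snapshots,
    _["probe_means"] = probe_tr,
    _["probe_steps"] = probe_steps);

  if (!avg.empty() && avg_count > 0) {
    NumericVector av(avg.begin(), avg.end());
    for (R_xlen_t i = 0; i < n; ++i) av[i] /= (double)avg_count;
    av.attr("dim") = dim;
    out["average"] = av;
  } else {
    out["average"] = R_NilValue;
  }
  return out;
}
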