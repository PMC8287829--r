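#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Operator-split explicit monodomain stepper on a regular voxel grid with a
// two-variable phenomenological ionic model (fast inward / slow outward
// currents gated by a single recovery variable).
//
// Layout: element (ix, iy, iz) at linear index ix + nx*(iy + ny*iz), 0-based.
// gx[i] is the face conductance (already divided by h^2, units 1/ms) between
// element i and its +x neighbour; the last x-slab entries must be 0, likewise
// gy/gz. No-flux boundaries fall out of the face formulation.
//
// Extracellular potentials: at every output instant the intracellular source
// density s = div(sigma_i grad Vm) is evaluated with its own face conductances
// (sx, sy, sz) and projected onto electrode weight columns W (n x n_elec):
// phi_e = -W^t s. W carries the Green's-function geometry and the amplitude
// calibration constant.

static inline void face_accumulate(const std::vector<double>& u,
                                   const double* gx, const double* gy,
                                   const double* gz, int nx, int ny, int nz,
                                   std::vector<double>& lap) {
  const int n = nx * ny * nz;
  std::fill(lap.begin(), lap.end(), 0.0);
  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      const int base = nx * (iy + ny * iz);
      for (int ix = 0; ix < nx - 1; ++ix) {
        const int i = base + ix;
        const double f = gx[i] * (u[i + 1] - u[i]);
        lap[i] += f;
        lap[i + 1] -= f;
      }
    }
  }
  const int sy = nx;
  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny - 1; ++iy) {
      const int base = nx * (iy + ny * iz);
      for (int ix = 0; ix < nx; ++ix) {
        const int i = base + ix;
        const double f = gy[i] * (u[i + sy] - u[i]);
        lap[i] += f;
        lap[i + sy] -= f;
      }
    }
  }
  const int sz = nx * ny;
  for (int i = 0; i < n - sz; ++i) {
    const double f = gz[i] * (u[i + sz] - u[i]);
    lap[i] += f;
    lap[i + sz] -= f;
  }
}

// [[Rcpp::export(name = ".md_run")]]
List md_run(int nx, int ny, int nz,
            NumericVector gx, NumericVector gy, NumericVector gz,
            NumericVector sx, NumericVector sy, NumericVector sz,
            NumericVector stim_mask, NumericVector pulse_starts,
            double pulse_dur, double stim_amp,
            double dt, int n_steps, int out_every,
            double tau_in, double tau_out, double tau_open, double tau_close,
            double u_gate, double v_amp,
            NumericVector u0, NumericVector h0,
            NumericMatrix W, IntegerVector probes,
            bool record_field, int field_every) {
  const int n = nx * ny * nz;
  if (u0.size() != n || h0.size() != n)
    stop("state vectors do not match grid size");
  const int n_elec = W.ncol();
  if (n_elec > 0 && W.nrow() != n) stop("weight matrix does not match grid");
  const int n_out = n_steps / out_every;
  const int n_probe = probes.size();

  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> h(h0.begin(), h0.end());
  std::vector<double> lap(n), src(n);

  NumericMatrix egm(n_out, std::max(n_elec, 0));
  NumericMatrix probe_vm(n_out, std::max(n_probe, 0));
  int n_field = 0;
  if (record_field && field_every > 0) n_field = n_steps / field_every;
  NumericMatrix field(record_field ? n : 0, record_field ? n_field : 0);

  // stimulated elements only (mask is typically sparse)
  std::vector<int> stim_idx;
  for (int i = 0; i < n; ++i)
    if (stim_mask[i] != 0.0) stim_idx.push_back(i);

  bool blowup = false;
  int out_row = 0, field_col = 0;
  const int n_pulse = pulse_starts.size();

  for (int step = 0; step < n_steps && !blowup; ++step) {
    const double t = step * dt;
    face_accumulate(u, gx.begin(), gy.begin(), gz.begin(), nx, ny, nz, lap);

    bool stim_on = false;
    for (int p = 0; p < n_pulse; ++p)
      if (t >= pulse_starts[p] && t < pulse_starts[p] + pulse_dur) {
        stim_on = true;
        break;
      }

    for (int i = 0; i < n; ++i) {
      const double ui = u[i];
      const double j_in = h[i] * ui * ui * (1.0 - ui) / tau_in;
      const double j_out = -ui / tau_out;
      double un = ui + dt * (lap[i] + j_in + j_out);
      // flush the exponential tail of repolarization to zero so resting
      // tissue never drifts into denormal arithmetic
      u[i] = (std::fabs(un) < 1e-12) ? 0.0 : un;
      h[i] += dt * ((ui < u_gate) ? (1.0 - h[i]) / tau_open : -h[i] / tau_close);
    }
    if (stim_on)
      for (size_t k = 0; k < stim_idx.size(); ++k) {
        const int i = stim_idx[k];
        u[i] += dt * stim_amp * stim_mask[i];
      }

    if ((step + 1) % out_every == 0) {
      if (n_elec > 0) {
        face_accumulate(u, sx.begin(), sy.begin(), sz.begin(), nx, ny, nz, src);
        for (int e = 0; e < n_elec; ++e) {
          const double* w = &W(0, e);
          double acc = 0.0;
          for (int i = 0; i < n; ++i) acc += w[i] * src[i];
          egm(out_row, e) = -v_amp * acc;
        }
      }
      for (int p = 0; p < n_probe; ++p) probe_vm(out_row, p) = u[probes[p]];
      ++out_row;
    }
    if (record_field && field_every > 0 && (step + 1) % field_every == 0 &&
        field_col < n_field) {
      for (int i = 0; i < n; ++i) field(i, field_col) = u[i];
      ++field_col;
    }
    if ((step & 255) == 0) {
      double umax = 0.0;
      for (int i = 0; i < n; ++i)
        if (std::fabs(u[i]) > umax) umax = std::fabs(u[i]);
      if (umax > 3.0 || !std::isfinite(umax)) blowup = true;
    }
  }

  return List::create(_["egm"] = egm, _["probe_vm"] = probe_vm,
                      _["u"] = NumericVector(u.begin(), u.end()),
                      _["h"] = NumericVector(h.begin(), h.end()),
                      _["field"] = field, _["blowup"] = blowup,
                      _["steps_done"] = out_row * out_every);
}

// Brute-force sample entropy counts for short windows: returns (B, A), the
// numbers of length-m and length-(m+1) template matches under the Chebyshev
// metric, self-matches excluded.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  long double B = 0, A = 0;
  const int nm = n - m;
  for (int i = 0; i < nm; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        const double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
      }
      if (d <= r) {
        ++B;
        if (std::max(d, std::fabs(x[i + m] - x[j + m])) <= r) ++A;
      }
    }
  }
  return NumericVector::create((double)B, (double)A);
}
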