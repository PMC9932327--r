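// Cable-equation integrator on a branched compartment tree.
//
// Two schemes share the gate/calcium machinery:
//   explicit: forward Euler for v, exponential integrator for gates
//   implicit: backward Euler for v (ionic conductances linearized at the
//             freshly updated gates), solved by Hines elimination on the
//             tree; same gate update
//
// Units at this interface: v mV, t ms, capacitance uF, conductances uA/mV
// (i.e. mS, already multiplied by membrane area where relevant), external
// pulse amplitudes nA, calcium uM, current densities uA/cm^2.
//
// Gate kinetics arrive as lookup tables over a uniform voltage grid
// (x_inf and tau per gate table, tau pre-scaled by any perturbation factor
// f); calcium-dependent gates additionally carry analytic Hill coefficients
// applied multiplicatively to the tabulated voltage part.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct GateTables {
  const double* xinf;   // n_v entries per table, column-major
  const double* edt;    // exp(-dt/tau), same layout
  int n_v;
  double v_min, v_step;

  inline void lookup(int table, double v, double& xi, double& ed) const {
    double u = (v - v_min) / v_step;
    if (u <= 0) {
      xi = xinf[table * n_v];
      ed = edt[table * n_v];
      return;
    }
    if (u >= n_v - 1) {
      xi = xinf[table * n_v + n_v - 1];
      ed = edt[table * n_v + n_v - 1];
      return;
    }
    int i = static_cast<int>(u);
    double w = u - i;
    const double* xc = xinf + table * n_v + i;
    const double* tc = edt + table * n_v + i;
    xi = xc[0] + w * (xc[1] - xc[0]);
    ed = tc[0] + w * (tc[1] - tc[0]);
  }
};

inline double hill(double ca, double kd, double n) {
  double can = std::pow(ca > 0 ? ca : 0.0, n);
  return can / (can + std::pow(kd, n));
}

}  // namespace

// Argument groups: tree topology (parent is 0-based, -1 at root, parents
// precede children) and per-compartment geometry (area cm^2, cap uF, g_ax
// uA/mV to parent); flattened channel and gate instances; gate lookup
// tables; calcium-pool constants; timed pulses plus a constant
// per-compartment current (nA); run control; initial state.
// [[Rcpp::export(name = ".sim_core")]]
List sim_core(IntegerVector parent, NumericVector area, NumericVector cap,
              NumericVector g_ax,
              IntegerVector ch_comp, NumericVector ch_gbar, NumericVector ch_erev,
              LogicalVector ch_ca,
              IntegerVector gi_chan, IntegerVector gi_table, IntegerVector gi_exp,
              NumericMatrix tab_xinf, NumericMatrix tab_tau,
              double v_min, double v_step,
              IntegerVector tab_cadep, NumericVector tab_kd, NumericVector tab_n,
              double ca_rest, double tau_ca, double phi,
              IntegerVector pulse_comp, NumericVector pulse_t0, NumericVector pulse_w,
              double pulse_width, int pulse_mode, double tau_i,
              NumericVector ext_const,
              double dt, int n_steps, double t_start, int method,
              IntegerVector record_idx, int record_stride,
              NumericVector v0, NumericVector gates0, NumericVector ca0) {
  const int n = parent.size();
  const int n_ch = ch_comp.size();
  const int n_gi = gi_chan.size();
  const int n_tab = tab_xinf.ncol();
  const int n_pulse = pulse_comp.size();

  // precompute exp(-dt/tau) per table entry: dt is fixed across the run
  std::vector<double> tab_edt(static_cast<size_t>(tab_tau.nrow()) * n_tab);
  for (size_t i = 0; i < tab_edt.size(); ++i) tab_edt[i] = std::exp(-dt / REAL(tab_tau)[i]);
  GateTables gt{REAL(tab_xinf), tab_edt.data(), tab_xinf.nrow(), v_min, v_step};

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> gates(gates0.begin(), gates0.end());
  std::vector<double> ca(ca0.begin(), ca0.end());
  std::vector<double> i_ion(n), g_ion(n), e_g_ion(n), i_ca_dens(n), i_ax(n), i_ext(n);
  std::vector<double> open(n_ch);

  // Hines workspace
  std::vector<double> diag(n), rhs(n), offd(n);

  const double edt_ca = std::exp(-dt / tau_ca);
  const double nA_to_uA = 1e-3;

  const int n_rec = record_idx.size();
  const int n_samp = n_steps / record_stride + 1;
  NumericMatrix rec_v(n_samp, n_rec);
  NumericVector rec_t(n_samp);
  int samp = 0;
  // record initial sample
  rec_t[samp] = t_start;
  for (int r = 0; r < n_rec; ++r) rec_v(samp, r) = v[record_idx[r]];
  ++samp;

  for (int step = 0; step < n_steps; ++step) {
    const double t = t_start + step * dt;

    // --- gates: exponential integrator at current v (and ca) ---
    for (int i = 0; i < n_gi; ++i) {
      const int c = ch_comp[gi_chan[i]];
      const int tb = gi_table[i];
      double xi, ed;
      gt.lookup(tb, v[c], xi, ed);
      if (tab_cadep[tb]) xi *= hill(ca[c], tab_kd[tb], tab_n[tb]);
      double x = xi + (gates[i] - xi) * ed;
      gates[i] = x < 0 ? 0 : (x > 1 ? 1 : x);
    }

    // --- ionic currents (with fresh gates, current v) ---
    std::fill(i_ion.begin(), i_ion.end(), 0.0);
    std::fill(g_ion.begin(), g_ion.end(), 0.0);
    std::fill(e_g_ion.begin(), e_g_ion.end(), 0.0);
    std::fill(i_ca_dens.begin(), i_ca_dens.end(), 0.0);
    std::fill(open.begin(), open.end(), 1.0);
    for (int i = 0; i < n_gi; ++i) {
      double x = gates[i];
      int e = gi_exp[i];
      double p = 1.0;
      while (e-- > 0) p *= x;
      open[gi_chan[i]] *= p;
    }
    for (int k = 0; k < n_ch; ++k) {
      const int c = ch_comp[k];
      const double g = ch_gbar[k] * open[k];       // uA/mV
      const double cur = g * (v[c] - ch_erev[k]);  // uA, outward positive
      i_ion[c] += cur;
      g_ion[c] += g;
      e_g_ion[c] += g * ch_erev[k];
      if (ch_ca[k]) i_ca_dens[c] += cur / area[c];
    }

    // --- calcium shell (exponential integrator, fixed current over dt) ---
    for (int c = 0; c < n; ++c) {
      const double target = ca_rest - phi * i_ca_dens[c] * tau_ca;
      double x = target + (ca[c] - target) * edt_ca;
      ca[c] = x > 0 ? x : 0.0;
    }

    // --- external currents ---
    for (int c = 0; c < n; ++c) i_ext[c] = ext_const[c] * nA_to_uA;
    for (int p = 0; p < n_pulse; ++p) {
      const double rel = t - pulse_t0[p];
      if (rel >= 0 && rel < pulse_width) {
        double amp = pulse_w[p];
        if (pulse_mode == 1) amp *= 1.0 - std::exp(-rel / tau_i);
        i_ext[pulse_comp[p]] += amp * nA_to_uA;
      }
    }

    if (method == 0) {
      // --- explicit: forward Euler on v ---
      std::fill(i_ax.begin(), i_ax.end(), 0.0);
      for (int c = 1; c < n; ++c) {
        const int p = parent[c];
        const double cur = g_ax[c] * (v[p] - v[c]);  // into c
        i_ax[c] += cur;
        i_ax[p] -= cur;
      }
      for (int c = 0; c < n; ++c) {
        v[c] += dt * (i_ax[c] + i_ext[c] - i_ion[c]) / cap[c];
        if (!std::isfinite(v[c])) {
          stop("integration produced a non-finite voltage at t = %f ms (compartment %d)",
               t, c + 1);
        }
      }
    } else {
      // --- implicit: backward Euler, Hines solve over the tree ---
      for (int c = 0; c < n; ++c) {
        diag[c] = cap[c] / dt + g_ion[c];
        rhs[c] = cap[c] / dt * v[c] + e_g_ion[c] + i_ext[c];
        offd[c] = -g_ax[c];
      }
      for (int c = 1; c < n; ++c) {
        diag[c] += g_ax[c];
        diag[parent[c]] += g_ax[c];
      }
      // backward elimination: children (high index) into parents
      for (int c = n - 1; c >= 1; --c) {
        const int p = parent[c];
        const double f = offd[c] / diag[c];
        diag[p] -= f * offd[c];
        rhs[p] -= f * rhs[c];
      }
      v[0] = rhs[0] / diag[0];
      for (int c = 1; c < n; ++c) {
        v[c] = (rhs[c] - offd[c] * v[parent[c]]) / diag[c];
        if (!std::isfinite(v[c])) {
          stop("integration produced a non-finite voltage at t = %f ms (compartment %d)",
               t, c + 1);
        }
      }
    }

    if ((step + 1) % record_stride == 0 && samp < n_samp) {
      rec_t[samp] = t_start + (step + 1) * dt;
      for (int r = 0; r < n_rec; ++r) rec_v(samp, r) = v[record_idx[r]];
      ++samp;
    }
  }

  return List::create(
      _["times"] = rec_t, _["v_rec"] = rec_v,
      _["v"] = NumericVector(v.begin(), v.end()),
      _["gates"] = NumericVector(gates.begin(), gates.end()),
      _["ca"] = NumericVector(ca.begin(), ca.end()),
      _["t_end"] = t_start + n_steps * dt);
}
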