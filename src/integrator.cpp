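// Forward integration of the coupled neuronal / Windkessel-balloon /
// oxygen-to-tissue model driven by a train of rectangular pulses.
//
// The stimulus u(t) is piecewise constant, so integration proceeds with a
// classical RK4 scheme between consecutive pulse edges (exact breakpoints);
// on every sub-interval the right-hand side is smooth and the scheme keeps
// its full order.  State per region: x_e, x_i, s, g, v, q, w, m, og where
// g is the branch flow conductance (single region: f = g, df/dt = s).  For
// two regions sharing a supply artery with resistance fraction RA > 0 an
// extra state f_A (shared-artery flow, inertance L_A) closes the circuit:
//   P_n = f_A / (g_1 + g_2),   f_j = P_n * g_j,
//   L_A df_A/dt = P_a - R_abs f_A - P_n,   P_a = 2 R_abs + 1,
//   R_abs = 0.5 RA / (1 - RA).
// Conservation f_1 + f_2 = f_A holds identically.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Pars {
  int nr;                 // number of regions (1 or 2)
  bool coupled;           // nr == 2 && RA > 0
  // neural, per region
  double taue[2], taui[2], ce[2], cei[2], cie[2], ae[2], ai[2];
  // vascular / metabolic, shared
  double eps, tau_s, tau_f, tau0, alpha, tvisc, RA, LA, V0, k1, k2, k3;
  double kappa, E0, tau_m, tau_m2, tau_g, tau_g2;
  double Rabs, Pa;
};

const int NPR = 9;  // states per region

inline void deriv(const double* x, double* dx, double u, const Pars& P,
                  double* fbr) {
  double fA = 0.0, Pn = 0.0;
  if (P.coupled) {
    fA = x[P.nr * NPR];
    double G = x[3] + x[NPR + 3];
    Pn = fA / G;
  }
  for (int j = 0; j < P.nr; ++j) {
    const double* xr = x + j * NPR;
    double* dr = dx + j * NPR;
    double xe = xr[0], xi = xr[1], s = xr[2], g = xr[3], v = xr[4],
           q = xr[5], w = xr[6], m = xr[7], og = xr[8];
    double f = P.coupled ? Pn * g : g;
    fbr[j] = f;
    double n = xe;
    dr[0] = (-xe + P.ce[j] * xe - P.cie[j] * xi + P.ae[j] * u) / P.taue[j];
    dr[1] = (-xi + P.cei[j] * xe + P.ai[j] * u) / P.taui[j];
    dr[2] = P.eps * n - s / P.tau_s - (f - 1.0) / P.tau_f;
    dr[3] = s;
    double fv = std::pow(v, 1.0 / P.alpha);
    double dv = (f - fv) / (P.tau0 + P.tvisc);
    dr[4] = dv;
    double fout = fv + P.tvisc * dv;
    dr[5] = (m - fout * q / v) / P.tau0;
    dr[6] = P.kappa * n - w / P.tau_m - (m - 1.0) / P.tau_m2;
    dr[7] = w;
    double E = 1.0 - std::pow(1.0 - P.E0, 1.0 / f);
    dr[8] = (f * E / P.E0 - m) / P.tau_g - (og - 1.0) / P.tau_g2;
  }
  if (P.coupled)
    dx[P.nr * NPR] = (P.Pa - P.Rabs * fA - Pn) / P.LA;
}

inline void rk4_step(std::vector<double>& x, double u, double h,
                     const Pars& P, int nx) {
  std::vector<double> k1(nx), k2(nx), k3(nx), k4(nx), xt(nx);
  double fbr[2];
  deriv(x.data(), k1.data(), u, P, fbr);
  for (int i = 0; i < nx; ++i) xt[i] = x[i] + 0.5 * h * k1[i];
  deriv(xt.data(), k2.data(), u, P, fbr);
  for (int i = 0; i < nx; ++i) xt[i] = x[i] + 0.5 * h * k2[i];
  deriv(xt.data(), k3.data(), u, P, fbr);
  for (int i = 0; i < nx; ++i) xt[i] = x[i] + h * k3[i];
  deriv(xt.data(), k4.data(), u, P, fbr);
  for (int i = 0; i < nx; ++i)
    x[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

double getnum(const List& l, const char* nm) {
  return as<double>(l[nm]);
}

}  // namespace

// [[Rcpp::export(name = ".integrate_model")]]
NumericMatrix integrate_model(List pars, NumericVector onsets,
                              NumericVector amps, double pulse_width,
                              double t_end, double dt, double dt_out) {
  Pars P;
  P.nr = as<int>(pars["nregions"]);
  if (P.nr < 1 || P.nr > 2) stop("nregions must be 1 or 2");
  NumericMatrix neu = pars["neural"];  // 7 x nr: taue taui ce cei cie ae ai
  if (neu.nrow() != 7 || neu.ncol() != P.nr)
    stop("neural parameter matrix must be 7 x nregions");
  for (int j = 0; j < P.nr; ++j) {
    P.taue[j] = neu(0, j); P.taui[j] = neu(1, j); P.ce[j] = neu(2, j);
    P.cei[j] = neu(3, j);  P.cie[j] = neu(4, j);  P.ae[j] = neu(5, j);
    P.ai[j] = neu(6, j);
  }
  P.eps = getnum(pars, "epsilon"); P.tau_s = getnum(pars, "tau_s");
  P.tau_f = getnum(pars, "tau_f"); P.tau0 = getnum(pars, "tau_0");
  P.alpha = getnum(pars, "alpha"); P.tvisc = getnum(pars, "tau_visc");
  P.RA = getnum(pars, "R_A");      P.LA = getnum(pars, "L_A");
  P.V0 = getnum(pars, "V0");       P.k1 = getnum(pars, "k1");
  P.k2 = getnum(pars, "k2");       P.k3 = getnum(pars, "k3");
  P.kappa = getnum(pars, "kappa"); P.E0 = getnum(pars, "E0");
  P.tau_m = getnum(pars, "tau_m"); P.tau_m2 = getnum(pars, "tau_m2");
  P.tau_g = getnum(pars, "tau_g");
  P.tau_g2 = getnum(pars, "tau_g2");
  P.coupled = (P.nr == 2 && P.RA > 0.0);
  P.Rabs = P.coupled ? 0.5 * P.RA / (1.0 - P.RA) : 0.0;
  P.Pa = 2.0 * P.Rabs + 1.0;

  int nx = P.nr * NPR + (P.coupled ? 1 : 0);
  std::vector<double> x(nx, 0.0);
  for (int j = 0; j < P.nr; ++j) {
    x[j * NPR + 3] = 1.0;  // g
    x[j * NPR + 4] = 1.0;  // v
    x[j * NPR + 5] = 1.0;  // q
    x[j * NPR + 7] = 1.0;  // m
    x[j * NPR + 8] = 1.0;  // og
  }
  if (P.coupled) x[P.nr * NPR] = 2.0;  // f_A baseline

  // breakpoints: output grid plus pulse edges
  int n_out = (int)std::floor(t_end / dt_out + 1e-9) + 1;
  std::vector<double> bp;
  bp.reserve(n_out + 2 * onsets.size());
  for (int i = 0; i < n_out; ++i) bp.push_back(i * dt_out);
  for (int k = 0; k < onsets.size(); ++k) {
    double a = onsets[k], b = onsets[k] + pulse_width;
    if (a > 0 && a < t_end) bp.push_back(a);
    if (b > 0 && b < t_end) bp.push_back(b);
  }
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end(),
                       [](double a, double b) { return std::fabs(a - b) < 1e-9; }),
           bp.end());

  int ncol = 1 + P.nr * 10 + (P.nr == 2 ? 1 : 0);
  NumericMatrix out(n_out, ncol);
  double fbr[2];
  std::vector<double> dtmp(nx);

  int oi = 0;
  auto record = [&](double t) {
    out(oi, 0) = t;
    deriv(x.data(), dtmp.data(), 0.0, P, fbr);  // recover branch flows
    for (int j = 0; j < P.nr; ++j) {
      const double* xr = x.data() + j * NPR;
      double f = fbr[j], v = xr[4], q = xr[5];
      double E = 1.0 - std::pow(1.0 - P.E0, 1.0 / f);
      double y = P.V0 * (P.k1 * (1.0 - q) + P.k2 * (1.0 - q / v) +
                         P.k3 * (1.0 - v));
      int c = 1 + j * 10;
      out(oi, c + 0) = xr[0]; out(oi, c + 1) = xr[1]; out(oi, c + 2) = xr[2];
      out(oi, c + 3) = f;     out(oi, c + 4) = v;     out(oi, c + 5) = q;
      out(oi, c + 6) = xr[7]; out(oi, c + 7) = xr[8]; out(oi, c + 8) = E;
      out(oi, c + 9) = y;
    }
    if (P.nr == 2)
      out(oi, ncol - 1) = P.coupled ? x[P.nr * NPR] : (x[3] + x[NPR + 3]);
    ++oi;
  };

  record(0.0);
  for (size_t k = 0; k + 1 < bp.size(); ++k) {
    double ta = bp[k], tb = bp[k + 1];
    double tm = 0.5 * (ta + tb);
    double u = 0.0;
    for (int e = 0; e < onsets.size(); ++e)
      if (tm >= onsets[e] && tm < onsets[e] + pulse_width) u += amps[e];
    int nst = std::max(1, (int)std::ceil((tb - ta) / dt - 1e-9));
    double h = (tb - ta) / nst;
    for (int st = 0; st < nst; ++st) rk4_step(x, u, h, P, nx);
    // blow-up guard
    for (int j = 0; j < P.nr; ++j) {
      const double* xr = x.data() + j * NPR;
      const char* nm[5] = {"f", "v", "q", "m", "g_O2"};
      double vals[5] = {P.coupled ? (x[P.nr * NPR] * xr[3] / (x[3] + x[NPR + 3]))
                                  : xr[3],
                        xr[4], xr[5], xr[7], xr[8]};
      for (int c = 0; c < 5; ++c)
        if (!std::isfinite(vals[c]) || vals[c] <= 0.0)
          stop("integration failed: state '%s' (region %d) non-positive or "
               "non-finite at t = %.3f s", nm[c], j + 1, tb);
      for (int c = 0; c < NPR; ++c)
        if (!std::isfinite(xr[c]))
          stop("integration failed: non-finite state (region %d) at t = %.3f s",
               j + 1, tb);
    }
    if (std::fabs(tb - oi * dt_out) < 1e-9 && oi < n_out) record(tb);
  }
  while (oi < n_out) record(oi * dt_out);  // guard (should not trigger)
  return out;
}
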