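// Hot loops: Cash-Karp integration of the Hodgkin-Huxley equations,
// teacher-forced surrogate stepping, reservoir state collection and
// closed-loop prediction.  All routines are deterministic; randomness
// lives on the R side (graph construction, protocol generation).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Gate { double vh, dv, tau0, eps, dvt; };
struct HHPar { double C, gNa, gK, gL, ENa, EK, EL; Gate g[3]; };

// parameter packing order (see pack_neuron_params() on the R side):
// C, gNa, gK, gL, ENa, EK, EL, then for each of m, h, n:
// v_half, dv, tau0, eps_tau, dvt
static HHPar unpack(const NumericVector& p) {
  HHPar P;
  P.C = p[0]; P.gNa = p[1]; P.gK = p[2]; P.gL = p[3];
  P.ENa = p[4]; P.EK = p[5]; P.EL = p[6];
  for (int k = 0; k < 3; ++k) {
    int o = 7 + 5 * k;
    P.g[k].vh = p[o]; P.g[k].dv = p[o + 1]; P.g[k].tau0 = p[o + 2];
    P.g[k].eps = p[o + 3]; P.g[k].dvt = p[o + 4];
  }
  return P;
}

// dV/dt = [gNa m^3 h (ENa - V) + gK n^4 (EK - V) + gL (EL - V) + I] / C
// dchi/dt = (chi_inf(V) - chi) / tau_chi(V)
static inline void hh_deriv(const HHPar& P, const double* y, double I,
                            double* dy) {
  const double V = y[0];
  double xinf[3], tau[3];
  for (int k = 0; k < 3; ++k) {
    const double a = V - P.g[k].vh;
    xinf[k] = 0.5 * (1.0 + std::tanh(a / P.g[k].dv));
    const double th = std::tanh(a / P.g[k].dvt);
    tau[k] = P.g[k].tau0 + P.g[k].eps * (1.0 - th * th);
  }
  const double m = y[1], h = y[2], n = y[3];
  dy[0] = (P.gNa * m * m * m * h * (P.ENa - V) +
           P.gK * n * n * n * n * (P.EK - V) +
           P.gL * (P.EL - V) + I) / P.C;
  dy[1] = (xinf[0] - m) / tau[0];
  dy[2] = (xinf[1] - h) / tau[1];
  dy[3] = (xinf[2] - n) / tau[2];
}

// Cash-Karp embedded 4(5) pair coefficients
static const double b21 = 0.2,
  b31 = 3.0 / 40.0, b32 = 9.0 / 40.0,
  b41 = 0.3, b42 = -0.9, b43 = 1.2,
  b51 = -11.0 / 54.0, b52 = 2.5, b53 = -70.0 / 27.0, b54 = 35.0 / 27.0,
  b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0, b63 = 575.0 / 13824.0,
  b64 = 44275.0 / 110592.0, b65 = 253.0 / 4096.0,
  c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
  c6 = 512.0 / 1771.0,
  dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
  dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0, dc6 = c6 - 0.25;

static inline void ck_step(const HHPar& P, const double* y, double I,
                           double h, double* yout, double* yerr) {
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], yt[4];
  hh_deriv(P, y, I, k1);
  for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * b21 * k1[i];
  hh_deriv(P, yt, I, k2);
  for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
  hh_deriv(P, yt, I, k3);
  for (int i = 0; i < 4; ++i)
    yt[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
  hh_deriv(P, yt, I, k4);
  for (int i = 0; i < 4; ++i)
    yt[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
  hh_deriv(P, yt, I, k5);
  for (int i = 0; i < 4; ++i)
    yt[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                        b64 * k4[i] + b65 * k5[i]);
  hh_deriv(P, yt, I, k6);
  for (int i = 0; i < 4; ++i) {
    yout[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
    yerr[i] = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] +
                   dc5 * k5[i] + dc6 * k6[i]);
  }
}

struct StepCtl {
  double rtol, atol, hmin, hmax;
  int status;   // 0 ok, 1 step-size underflow, 2 non-finite state
  long clamps;
};

static inline void clamp_gates(double* y, long& clamps) {
  for (int i = 1; i < 4; ++i) {
    if (y[i] < 0.0) { y[i] = 0.0; ++clamps; }
    else if (y[i] > 1.0) { y[i] = 1.0; ++clamps; }
  }
}

// advance state y over one sampling interval [0, span] with I held constant
// (zero-order hold).  h carries the step-size estimate across intervals.
static void integrate_span(const HHPar& P, double* y, double I, double span,
                           double& h, StepCtl& ctl) {
  double t = 0.0, ynew[4], yerr[4];
  const double safety = 0.9;
  while (t < span) {
    if (h > ctl.hmax) h = ctl.hmax;
    double hh = (t + h > span) ? (span - t) : h;
    ck_step(P, y, I, hh, ynew, yerr);
    bool finite = true;
    double errnorm = 0.0;
    for (int i = 0; i < 4; ++i) {
      if (!std::isfinite(ynew[i])) { finite = false; break; }
      double sc = ctl.atol + ctl.rtol * std::max(std::fabs(y[i]),
                                                 std::fabs(ynew[i]));
      double e = std::fabs(yerr[i]) / sc;
      if (e > errnorm) errnorm = e;
    }
    if (!finite) {
      h = hh * 0.1;
      if (h < ctl.hmin) { ctl.status = 2; return; }
      continue;
    }
    if (errnorm <= 1.0) {
      t += hh;
      for (int i = 0; i < 4; ++i) y[i] = ynew[i];
      clamp_gates(y, ctl.clamps);
      double fac = (errnorm > 0.0)
        ? std::min(5.0, safety * std::pow(errnorm, -0.2)) : 5.0;
      h = hh * fac;
      if (h > ctl.hmax) h = ctl.hmax;
    } else {
      h = hh * std::max(0.1, safety * std::pow(errnorm, -0.25));
      if (h < ctl.hmin) {
        ctl.status = std::max(ctl.status, 1);
        h = ctl.hmin;             // keep moving; caller decides what to do
        t += hh;                  // accept the rejected step to avoid stalling
        for (int i = 0; i < 4; ++i) y[i] = ynew[i];
        clamp_gates(y, ctl.clamps);
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_integrate(NumericVector y0, NumericVector params, NumericVector I,
                   double dt, double rtol, double atol) {
  const HHPar P = unpack(params);
  const int n = I.size();
  NumericMatrix out(n, 4);
  double y[4] = { y0[0], y0[1], y0[2], y0[3] };
  StepCtl ctl{rtol, atol, dt * 1e-6, dt, 0, 0};
  for (int j = 0; j < 4; ++j) out(0, j) = y[j];
  double h = dt;
  for (int k = 0; k + 1 < n; ++k) {
    integrate_span(P, y, I[k], dt, h, ctl);
    if (ctl.status == 2) {
      for (int kk = k + 1; kk < n; ++kk)
        for (int j = 0; j < 4; ++j) out(kk, j) = NA_REAL;
      return List::create(_["trajectory"] = out, _["status"] = ctl.status,
                          _["clamps"] = (double)ctl.clamps);
    }
    for (int j = 0; j < 4; ++j) out(k + 1, j) = y[j];
  }
  return List::create(_["trajectory"] = out, _["status"] = ctl.status,
                      _["clamps"] = (double)ctl.clamps);
}

// teacher-forced surrogate run: at each sample the model voltage is
// overwritten by the observed/fed-back voltage, the gates persist, and the
// model is integrated one sampling interval forward.
// Returns the (n-1) x 4 matrix of states x(t + dt) for t = 0..n-2.
// [[Rcpp::export]]
List cpp_surrogate_teacher(NumericVector params, NumericVector vmem,
                           NumericVector I, double dt, double rtol,
                           double atol, NumericVector state0) {
  const HHPar P = unpack(params);
  const int n = vmem.size();
  NumericMatrix out(n > 0 ? n - 1 : 0, 4);
  double y[4] = { state0[0], state0[1], state0[2], state0[3] };
  StepCtl ctl{rtol, atol, dt * 1e-6, dt, 0, 0};
  double h = dt;
  for (int t = 0; t + 1 < n; ++t) {
    y[0] = vmem[t];
    integrate_span(P, y, I[t], dt, h, ctl);
    if (ctl.status == 2) break;
    for (int j = 0; j < 4; ++j) out(t, j) = y[j];
  }
  return List::create(_["states"] = out, _["status"] = ctl.status,
                      _["clamps"] = (double)ctl.clamps);
}

// sparse symmetric matvec acc = A r, A in CSC (dgCMatrix slots)
static inline void spmv(const IntegerVector& Ap, const IntegerVector& Ai,
                        const NumericVector& Ax, const std::vector<double>& r,
                        std::vector<double>& acc) {
  const int n = (int)r.size();
  for (int i = 0; i < n; ++i) acc[i] = 0.0;
  for (int j = 0; j < n; ++j) {
    const double xj = r[j];
    if (xj == 0.0) continue;
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) acc[Ai[k]] += Ax[k] * xj;
  }
}

// teacher-forced reservoir run r(t+dt) = tanh(A r(t) + W_in v_in(t)) from
// r(0) = 0.  vin is n_channels x T; nodeCh maps node -> 0-based channel.
// Returns N_R x T matrix of states r(dt)..r(T dt).
// [[Rcpp::export]]
NumericMatrix cpp_collect_states(IntegerVector Ap, IntegerVector Ai,
                                 NumericVector Ax, IntegerVector nodeCh,
                                 NumericMatrix vin) {
  const int N = nodeCh.size();
  const int T = vin.ncol();
  NumericMatrix out(N, T);
  std::vector<double> r(N, 0.0), acc(N, 0.0);
  for (int t = 0; t < T; ++t) {
    spmv(Ap, Ai, Ax, r, acc);
    for (int i = 0; i < N; ++i) {
      r[i] = std::tanh(acc[i] + vin(nodeCh[i], t));
      out(i, t) = r[i];
    }
  }
  return out;
}

// Closed-loop prediction for the stand-alone reservoir (stateScope = 0) and
// all six hybrid variants.  The readout voltage replaces the observed
// voltage on the feedback channel and, when a surrogate is embedded
// (stateScope 1 = V only, 4 = V,m,h,n), in the surrogate teacher step.
// a/b: composed affine readout in raw units over (r, model outputs).
// Saturation or non-finite readouts are flagged, never thrown.
// [[Rcpp::export]]
List cpp_predict(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                 IntegerVector nodeCh, NumericVector r0, NumericVector a,
                 double b, NumericVector Iraw, NumericVector Iscaled,
                 int stateScope, bool injIn, bool injOut,
                 NumericVector params, NumericVector surr0, double vfb0,
                 double dt, double rtol, double atol,
                 double sVc, double sVs, double sigma) {
  const int N = nodeCh.size();
  const int H = Iraw.size();
  const double VCLIP = 150.0;
  NumericVector V(H);
  NumericMatrix gates(stateScope > 0 ? H : 0, 3);
  std::vector<double> r(N), acc(N);
  for (int i = 0; i < N; ++i) r[i] = r0[i];
  HHPar P;
  double y[4] = {0, 0, 0, 0};
  if (stateScope > 0) {
    P = unpack(params);
    for (int j = 0; j < 4; ++j) y[j] = surr0[j];
  }
  StepCtl ctl{rtol, atol, dt * 1e-6, dt, 0, 0};
  double h = dt;
  const int nModelIn = injIn ? (stateScope == 4 ? 4 : (stateScope == 1 ? 1 : 0)) : 0;
  double vch[6];
  double vfb = vfb0, vfb_c = std::max(-VCLIP, std::min(VCLIP, vfb0));
  bool saturated = false, nonfinite = false;
  for (int t = 0; t < H; ++t) {
    if (std::isfinite(vfb)) {
      vfb_c = std::max(-VCLIP, std::min(VCLIP, vfb));
      if (std::fabs(vfb) > VCLIP) saturated = true;
    } else {
      nonfinite = true; saturated = true;   // keep previous vfb_c
    }
    if (stateScope > 0) {
      y[0] = vfb_c;
      integrate_span(P, y, Iraw[t], dt, h, ctl);
      if (ctl.status == 2) {                // surrogate blew up: reset gates
        nonfinite = true;
        for (int j = 1; j < 4; ++j)
          if (!std::isfinite(y[j])) y[j] = 0.5;
        if (!std::isfinite(y[0])) y[0] = vfb_c;
        ctl.status = 1;
      }
    }
    vch[0] = Iscaled[t];
    vch[1] = sigma * (vfb_c - sVc) / sVs;
    // model channels enter raw: V in mV (tanh-saturating), gates in [0, 1]
    if (nModelIn >= 1) vch[2] = y[0];
    if (nModelIn == 4)
      for (int j = 1; j < 4; ++j) vch[2 + j] = y[j];
    spmv(Ap, Ai, Ax, r, acc);
    for (int i = 0; i < N; ++i) r[i] = std::tanh(acc[i] + vch[nodeCh[i]]);
    double vhat = b;
    for (int i = 0; i < N; ++i) vhat += a[i] * r[i];
    if (injOut) {
      vhat += a[N] * y[0];
      if (stateScope == 4)
        for (int j = 1; j < 4; ++j) vhat += a[N + j] * y[j];
    }
    V[t] = vhat;
    if (stateScope > 0)
      for (int j = 0; j < 3; ++j) gates(t, j) = y[j + 1];
    if (!std::isfinite(vhat) || std::fabs(vhat) > VCLIP) saturated = true;
    vfb = vhat;
  }
  NumericVector rEnd(N);
  for (int i = 0; i < N; ++i) rEnd[i] = r[i];
  return List::create(_["V"] = V, _["gates"] = gates,
                      _["saturated"] = saturated,
                      _["nonfinite"] = nonfinite,
                      _["status"] = ctl.status,
                      _["clamps"] = (double)ctl.clamps,
                      _["r_final"] = rEnd);
}
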