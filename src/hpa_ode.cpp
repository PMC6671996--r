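#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State layout (14 variables):
//  0..2  light_TCsynth_1..3     photic synthesis transfer chain
//  3..5  light_TCdeg_1..3       photic degradation transfer chain
//  6     light_effect
//  7..13 CRH, ACTH, CORT, GR_mRNA, GR, DR, DRN
//
// Parameter layout (26, fixed order; see R/parameters.R):
//  0 k_p1   1 K_p1   2 k_p2    3 K_p2     4 k_p3
//  5 V_d1   6 K_d1   7 V_d2    8 K_d2     9 V_d3   10 K_d3
// 11 k_syn_GRm  12 IC50_GRm  13 k_deg
// 14 k_syn_GR   15 k_deg_GR
// 16 k_on  17 k_T  18 k_re  19 r_f
// 20 k_t   21 k_us 22 K_M_us 23 n  24 k_deg_us 25 k_eff
//
// Forcing within a segment is constant: L (light signal, already
// amplitude-scaled), Ld (drive of the degradation chain), s (multiplier on
// k_p1, used for acute stress pulses).

static const int NS = 14;

static inline void hpa_rhs(const double *y, const double *p,
                           double L, double Ld, double s, double *dy) {
  const double kt = p[20];
  dy[0] = kt * (L - y[0]);
  dy[1] = kt * (y[0] - y[1]);
  dy[2] = kt * (y[1] - y[2]);
  dy[3] = kt * (Ld - y[3]);
  dy[4] = kt * (y[3] - y[4]);
  dy[5] = kt * (y[4] - y[5]);

  const double x = y[2] > 0.0 ? y[2] : 0.0;   // guard fractional power
  const double xn = std::pow(x, p[23]);
  const double Kn = std::pow(p[22], p[23]);
  dy[6] = p[21] * xn / (Kn + xn) - p[24] * y[6] * (1.0 + p[25] * y[5]);

  const double DRN = y[13];
  const double lf = 1.0 + y[6] / (1.0 + y[6]);
  dy[7] = s * p[0] * p[1] / (p[1] + DRN) - p[5] * y[7] * lf / (p[6] + y[7]);
  dy[8] = p[2] * p[3] * y[7] / (p[3] + DRN) - p[7] * y[8] / (p[8] + y[8]);
  dy[9] = p[4] * y[8] - p[9] * y[9] / (p[10] + y[9]);
  dy[10] = p[11] * (1.0 - DRN / (p[12] + DRN)) - p[13] * y[10];
  dy[11] = p[14] * y[10] + p[19] * p[18] * DRN - p[16] * y[9] * y[11] -
           p[15] * y[11];
  dy[12] = p[16] * y[9] * y[11] - p[17] * y[12];
  dy[13] = p[17] * y[12] - p[19] * p[18] * DRN;
}

// Analytic Jacobian, J[i + NS*j] = d f_i / d y_j (column-major).
static inline void hpa_jac(const double *y, const double *p,
                           double L, double Ld, double s, double *J) {
  (void)L; (void)Ld;
  for (int i = 0; i < NS * NS; ++i) J[i] = 0.0;
  const double kt = p[20];
#define JAC(i, j) J[(i) + NS * (j)]
  JAC(0, 0) = -kt;
  JAC(1, 0) = kt;  JAC(1, 1) = -kt;
  JAC(2, 1) = kt;  JAC(2, 2) = -kt;
  JAC(3, 3) = -kt;
  JAC(4, 3) = kt;  JAC(4, 4) = -kt;
  JAC(5, 4) = kt;  JAC(5, 5) = -kt;

  const double x = y[2] > 0.0 ? y[2] : 0.0;
  const double n = p[23];
  const double Kn = std::pow(p[22], n);
  const double xn = std::pow(x, n);
  const double den = Kn + xn;
  JAC(6, 2) = x > 0.0 ? p[21] * n * Kn * std::pow(x, n - 1.0) / (den * den)
                      : 0.0;
  JAC(6, 5) = -p[24] * p[25] * y[6];
  JAC(6, 6) = -p[24] * (1.0 + p[25] * y[5]);

  const double DRN = y[13];
  const double lf = 1.0 + y[6] / (1.0 + y[6]);
  const double dlf = 1.0 / ((1.0 + y[6]) * (1.0 + y[6]));
  JAC(7, 6) = -p[5] * y[7] * dlf / (p[6] + y[7]);
  JAC(7, 7) = -p[5] * lf * p[6] / ((p[6] + y[7]) * (p[6] + y[7]));
  JAC(7, 13) = -s * p[0] * p[1] / ((p[1] + DRN) * (p[1] + DRN));

  JAC(8, 7) = p[2] * p[3] / (p[3] + DRN);
  JAC(8, 8) = -p[7] * p[8] / ((p[8] + y[8]) * (p[8] + y[8]));
  JAC(8, 13) = -p[2] * p[3] * y[7] / ((p[3] + DRN) * (p[3] + DRN));

  JAC(9, 8) = p[4];
  JAC(9, 9) = -p[9] * p[10] / ((p[10] + y[9]) * (p[10] + y[9]));

  JAC(10, 10) = -p[13];
  JAC(10, 13) = -p[11] * p[12] / ((p[12] + DRN) * (p[12] + DRN));

  JAC(11, 9) = -p[16] * y[11];
  JAC(11, 10) = p[14];
  JAC(11, 11) = -p[16] * y[9] - p[15];
  JAC(11, 13) = p[19] * p[18];

  JAC(12, 9) = p[16] * y[11];
  JAC(12, 11) = p[16] * y[9];
  JAC(12, 12) = -p[17];

  JAC(13, 12) = p[17];
  JAC(13, 13) = -p[19] * p[18];
#undef JAC
}

// Augmented rhs: y (14) followed by the variational matrix Phi (14x14,
// column-major); dPhi = J(y) Phi.
static inline void hpa_rhs_var(const double *y, const double *p,
                               double L, double Ld, double s, double *dy) {
  double J[NS * NS];
  hpa_rhs(y, p, L, Ld, s, dy);
  hpa_jac(y, p, L, Ld, s, J);
  const double *Phi = y + NS;
  double *dPhi = dy + NS;
  for (int c = 0; c < NS; ++c)
    for (int i = 0; i < NS; ++i) {
      double acc = 0.0;
      for (int k = 0; k < NS; ++k) acc += J[i + NS * k] * Phi[k + NS * c];
      dPhi[i + NS * c] = acc;
    }
}

// ---------------------------------------------------------------------------
// Dormand-Prince 5(4) adaptive integrator over piecewise-constant forcing.
// Steps never cross segment boundaries, so the square-wave light input is
// handled exactly (the integrator restarts at every switching time).
// ---------------------------------------------------------------------------

struct DP45 {
  const double *p;
  int nvar;
  bool variational;
  double rtol, atol, hmax;
  long nrej = 0, nacc = 0;

  void f(const double *y, double L, double Ld, double s, double *dy) const {
    if (variational) hpa_rhs_var(y, p, L, Ld, s, dy);
    else             hpa_rhs(y, p, L, Ld, s, dy);
  }

  // Integrate y from t0 to t1 under constant forcing (L, Ld, s).
  void span(double t0, double t1, double *y, double L, double Ld, double s,
            double &h) {
    static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                        c5 = 8.0 / 9;
    static const double a21 = 1.0 / 5;
    static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
    static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
    static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                        a53 = 64448.0 / 6561, a54 = -212.0 / 729;
    static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                        a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                        a65 = -5103.0 / 18656;
    static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                        b5 = -2187.0 / 6784, b6 = 11.0 / 84;
    static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                        e3 = 500.0 / 1113 - 7571.0 / 16695,
                        e4 = 125.0 / 192 - 393.0 / 640,
                        e5 = -2187.0 / 6784 + 92097.0 / 339200,
                        e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

    std::vector<double> k1(nvar), k2(nvar), k3(nvar), k4(nvar), k5(nvar),
        k6(nvar), k7(nvar), yt(nvar), ynew(nvar);
    double t = t0;
    if (h <= 0.0) h = std::min(hmax, (t1 - t0));
    int guard = 0;
    while (t < t1 - 1e-12) {
      if (++guard > 2000000) stop("integrator step limit exceeded");
      h = std::min(h, t1 - t);
      f(y, L, Ld, s, k1.data());
      for (int i = 0; i < nvar; ++i) yt[i] = y[i] + h * a21 * k1[i];
      f(yt.data(), L, Ld, s, k2.data());
      for (int i = 0; i < nvar; ++i)
        yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
      f(yt.data(), L, Ld, s, k3.data());
      for (int i = 0; i < nvar; ++i)
        yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      f(yt.data(), L, Ld, s, k4.data());
      for (int i = 0; i < nvar; ++i)
        yt[i] = y[i] +
                h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
      f(yt.data(), L, Ld, s, k5.data());
      for (int i = 0; i < nvar; ++i)
        yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
      f(yt.data(), L, Ld, s, k6.data());
      for (int i = 0; i < nvar; ++i)
        ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                              b5 * k5[i] + b6 * k6[i]);
      f(ynew.data(), L, Ld, s, k7.data());

      double err = 0.0;
      for (int i = 0; i < nvar; ++i) {
        double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                         e6 * k6[i] + e7 * k7[i]);
        double sc = atol + rtol * std::max(std::fabs(y[i]),
                                           std::fabs(ynew[i]));
        double r = ei / sc;
        err += r * r;
      }
      err = std::sqrt(err / nvar);
      if (!std::isfinite(err)) {
        h *= 0.25;
        ++nrej;
        if (h < 1e-12) stop("non-finite state during integration");
        continue;
      }
      if (err <= 1.0) {
        t += h;
        std::copy(ynew.begin(), ynew.end(), y);
        ++nacc;
        double fac = 0.9 * std::pow(err > 1e-14 ? err : 1e-14, -0.2);
        h = std::min(hmax, h * std::min(5.0, std::max(0.2, fac)));
      } else {
        ++nrej;
        double fac = 0.9 * std::pow(err, -0.2);
        h *= std::min(1.0, std::max(0.1, fac));
        if (h < 1e-12) stop("step size underflow");
      }
    }
  }
};

// Shared driver: walks output times across forcing segments.
static NumericMatrix drive(const double *p, std::vector<double> &y, int nvar,
                           bool variational, NumericVector seg_start,
                           NumericVector seg_L, NumericVector seg_Ld,
                           NumericVector seg_s, double t_end,
                           NumericVector out_times, double rtol, double atol,
                           double hmax) {
  const int m = seg_start.size(), k = out_times.size();
  DP45 solver{p, nvar, variational, rtol, atol, hmax};
  NumericMatrix out(k, nvar);
  double t = seg_start[0];
  double h = -1.0;
  int io = 0;
  // skip output times before start
  while (io < k && out_times[io] < t - 1e-9) {
    for (int j = 0; j < nvar; ++j) out(io, j) = NA_REAL;
    ++io;
  }
  for (int sgi = 0; sgi < m; ++sgi) {
    double s0 = seg_start[sgi];
    double s1 = (sgi + 1 < m) ? seg_start[sgi + 1] : t_end;
    if (s1 > t_end) s1 = t_end;
    if (s1 <= s0) continue;
    double L = seg_L[sgi], Ld = seg_Ld[sgi], sc = seg_s[sgi];
    h = -1.0;  // restart step size at each discontinuity
    while (io < k && out_times[io] <= s1 + 1e-9) {
      double target = std::min(out_times[io], s1);
      if (target > t) solver.span(t, target, y.data(), L, Ld, sc, h);
      t = std::max(t, target);
      if (std::fabs(out_times[io] - t) <= 1e-9) {
        for (int j = 0; j < nvar; ++j) out(io, j) = y[j];
        ++io;
      } else break;
    }
    if (t < s1) {
      solver.span(t, s1, y.data(), L, Ld, sc, h);
      t = s1;
    }
    if (t >= t_end - 1e-12) break;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_hpa_integrate(NumericVector params, NumericVector y0,
                                NumericVector seg_start, NumericVector seg_L,
                                NumericVector seg_Ld, NumericVector seg_s,
                                double t_end, NumericVector out_times,
                                double rtol, double atol, double hmax) {
  if (params.size() != 26) stop("expected 26 parameters");
  if (y0.size() != NS) stop("expected 14 state variables");
  for (int i = 0; i < params.size(); ++i)
    if (!std::isfinite(params[i])) stop("non-finite parameter");
  for (int i = 0; i < y0.size(); ++i)
    if (!std::isfinite(y0[i])) stop("non-finite initial state");
  std::vector<double> y(y0.begin(), y0.end());
  return drive(REAL(params), y, NS, false, seg_start, seg_L, seg_Ld, seg_s,
               t_end, out_times, rtol, atol, hmax);
}

// Integrates state + variational matrix from t0 over [t0, t0 + period]
// and returns the final state and the monodromy matrix.
// [[Rcpp::export]]
List cpp_hpa_monodromy(NumericVector params, NumericVector y0,
                       NumericVector seg_start, NumericVector seg_L,
                       NumericVector seg_Ld, NumericVector seg_s,
                       double t_end, double rtol, double atol, double hmax) {
  if (params.size() != 26) stop("expected 26 parameters");
  if (y0.size() != NS) stop("expected 14 state variables");
  const int nvar = NS + NS * NS;
  std::vector<double> y(nvar, 0.0);
  for (int i = 0; i < NS; ++i) y[i] = y0[i];
  for (int i = 0; i < NS; ++i) y[NS + i + NS * i] = 1.0;
  NumericVector out_times = NumericVector::create(t_end);
  NumericMatrix out = drive(REAL(params), y, nvar, true, seg_start, seg_L,
                            seg_Ld, seg_s, t_end, out_times, rtol, atol,
                            hmax);
  NumericVector yf(NS);
  NumericMatrix Phi(NS, NS);
  for (int i = 0; i < NS; ++i) yf[i] = out(0, i);
  for (int c = 0; c < NS; ++c)
    for (int i = 0; i < NS; ++i) Phi(i, c) = out(0, NS + i + NS * c);
  return List::create(_["state"] = yf, _["monodromy"] = Phi);
}

// Single rhs / Jacobian evaluations (used to validate against the R
// reference implementation and the finite-difference Jacobian).
// [[Rcpp::export]]
NumericVector cpp_hpa_rhs(NumericVector params, NumericVector y, double L,
                          double Ld, double s) {
  if (params.size() != 26 || y.size() != NS) stop("bad dimensions");
  NumericVector dy(NS);
  hpa_rhs(REAL(y), REAL(params), L, Ld, s, REAL(dy));
  return dy;
}

// [[Rcpp::export]]
NumericMatrix cpp_hpa_jacobian(NumericVector params, NumericVector y,
                               double L, double Ld, double s) {
  if (params.size() != 26 || y.size() != NS) stop("bad dimensions");
  NumericMatrix J(NS, NS);
  hpa_jac(REAL(y), REAL(params), L, Ld, s, REAL(J));
  return J;
}
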