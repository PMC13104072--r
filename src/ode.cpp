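#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State order matches hdo_species() in R:
//   0 GLUCOSE, 1 BUTYRYL_COA, 2 BUTANAL, 3 BUTYRATE, 4 HDO
// With with_flux, two auxiliary states are appended:
//   5 cumulative production of butyryl-CoA (integral of the inflow rate)
//   6 cumulative consumption of butyryl-CoA (integral of the outflow rates)
// so the flux integrals share the trajectory's error control.
//
// Parameter layout (all variants share it; unused entries are 0):
//   p[0] k_in    first-order glucose -> butyryl-CoA constant (Ka1 or Kb1), 1/h
//   p[1] k_drain first-order butyryl-CoA -> butyrate constant (Ka2), 1/h
//   p[2] k_lin   first-order butyryl-CoA -> butanal constant (Km1/Km2), 1/h
//   p[3] vmax    substrate-inhibition Vmax, mM/h
//   p[4] km      substrate-inhibition Km, mM
//   p[5] ki      substrate-inhibition Ki, mM
//   p[6] ka3     first-order butanal -> HDO constant (Ka3), 1/h
// inhib selects the butyryl-CoA -> butanal rate law.

#define NMAX 7

static inline void pathway_rhs(const double *y, double *dy, const double *p,
                               const bool inhib, const int nn) {
  // clamp tiny integrator-induced negatives for rate evaluation only
  const double G = y[0] > 0.0 ? y[0] : 0.0;
  const double B = y[1] > 0.0 ? y[1] : 0.0;
  const double A = y[2] > 0.0 ? y[2] : 0.0;
  const double vin = p[0] * G;
  const double conv =
      inhib ? p[3] * B / (p[4] + B + B * B / p[5]) : p[2] * B;
  const double drain = p[1] * B;
  const double vout = p[6] * A;
  dy[0] = -vin;
  dy[1] = vin - conv - drain;
  dy[2] = conv - vout;
  dy[3] = drain;
  dy[4] = vout;
  if (nn > 5) {
    dy[5] = vin;          // cumulative production
    dy[6] = conv + drain; // cumulative consumption
  }
}

// Jacobian of the RHS. Only the (G, B, A) columns are ever nonzero and the
// matrix is lower triangular (the auxiliary flux rows depend on G and B
// only), so the Rosenbrock stage systems solve by forward substitution.
static inline void pathway_jac(const double *y, double J[NMAX][NMAX],
                               const double *p, const bool inhib,
                               const int nn) {
  const double B = y[1] > 0.0 ? y[1] : 0.0;
  double s; // d(conv)/dB
  if (inhib) {
    const double den = p[4] + B + B * B / p[5];
    s = p[3] * (p[4] - B * B / p[5]) / (den * den);
  } else {
    s = p[2];
  }
  for (int i = 0; i < nn; ++i)
    for (int j = 0; j < nn; ++j) J[i][j] = 0.0;
  J[0][0] = -p[0];
  J[1][0] = p[0];
  J[1][1] = -s - p[1];
  J[2][1] = s;
  J[2][2] = -p[6];
  J[3][1] = p[1];
  J[4][2] = p[6];
  if (nn > 5) {
    J[5][0] = p[0];
    J[6][1] = s + p[1];
  }
}

// solve (I - gh*J) x = b by forward substitution (J lower triangular)
static inline void ros_solve(const double J[NMAX][NMAX], const double gh,
                             const double *b, double *x, const int nn) {
  for (int i = 0; i < nn; ++i) {
    double s = b[i];
    for (int j = 0; j < i; ++j) s += gh * J[i][j] * x[j];
    x[i] = s / (1.0 - gh * J[i][i]);
  }
}

static inline void clamp_or_stop(double *y, const double neg_tol,
                                 const double t, const int nn) {
  // auxiliary flux states (indices >= 5) are monotone by construction and
  // receive the same treatment
  for (int i = 0; i < nn; ++i) {
    if (y[i] < 0.0) {
      if (y[i] < -neg_tol)
        stop("integration produced a negative concentration "
             "(%g mM for component %d at t = %g h) beyond tolerance",
             y[i], i + 1, t);
      y[i] = 0.0;
    }
  }
}

// Dormand-Prince 5(4) with FSAL and standard step control. Output is
// produced by stepping exactly onto each requested time.
// [[Rcpp::export(name = ".ode_solve_cpp")]]
NumericMatrix ode_solve_cpp(NumericVector y0, NumericVector times,
                            NumericVector p, bool inhib, double rtol,
                            double atol, double neg_tol, double max_steps,
                            bool with_flux = false) {
  const int nn = with_flux ? 7 : 5;
  const int nt = times.size();
  if (y0.size() != 5) stop("state vector must have 5 components");
  NumericMatrix out(nt, nn);

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

  double y[NMAX], yn[NMAX], ytmp[NMAX];
  double k1[NMAX], k2[NMAX], k3[NMAX], k4[NMAX], k5[NMAX], k6[NMAX],
      k7[NMAX];
  const double *pp = REAL(p);
  for (int i = 0; i < nn; ++i) y[i] = i < 5 ? y0[i] : 0.0;
  double t = times[0];
  for (int i = 0; i < nn; ++i) out(0, i) = y[i];

  pathway_rhs(y, k1, pp, inhib, nn);
  double h = 1e-4;
  double steps = 0.0;

  for (int it = 1; it < nt; ++it) {
    const double tend = times[it];
    while (t < tend) {
      if (++steps > max_steps)
        stop("integrator step budget exhausted (step-size collapse?); "
             "last good time t = %g h", t);
      if (h > tend - t) h = tend - t;

      for (int i = 0; i < nn; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
      pathway_rhs(ytmp, k2, pp, inhib, nn);
      for (int i = 0; i < nn; ++i)
        ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
      pathway_rhs(ytmp, k3, pp, inhib, nn);
      for (int i = 0; i < nn; ++i)
        ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      pathway_rhs(ytmp, k4, pp, inhib, nn);
      for (int i = 0; i < nn; ++i)
        ytmp[i] = y[i] +
                  h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
      pathway_rhs(ytmp, k5, pp, inhib, nn);
      for (int i = 0; i < nn; ++i)
        ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                              a64 * k4[i] + a65 * k5[i]);
      pathway_rhs(ytmp, k6, pp, inhib, nn);
      for (int i = 0; i < nn; ++i)
        yn[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
      pathway_rhs(yn, k7, pp, inhib, nn);

      double errsq = 0.0;
      for (int i = 0; i < nn; ++i) {
        const double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                                e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
        const double ya = std::fabs(y[i]), yb = std::fabs(yn[i]);
        const double sc = atol + rtol * (ya > yb ? ya : yb);
        const double r = err / sc;
        errsq += r * r;
      }
      const double errnorm = std::sqrt(errsq / nn);

      if (errnorm <= 1.0) {
        t += h;
        clamp_or_stop(yn, neg_tol, t, nn);
        for (int i = 0; i < nn; ++i) y[i] = yn[i];
        // FSAL; refreshed because clamping may have fired
        pathway_rhs(y, k1, pp, inhib, nn);
      }
      double fac = 0.9 * std::pow(errnorm > 1e-10 ? errnorm : 1e-10, -0.2);
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      if (h < 1e-14) stop("step size underflow at t = %g h", t);
    }
    for (int i = 0; i < nn; ++i) out(it, i) = y[i];
  }
  return out;
}

// L-stable two-stage Rosenbrock method (order 2, gamma = 1 - 1/sqrt(2)),
// with the linearised-implicit-Euler stage as embedded first-order
// estimate. Suited to the substrate-inhibition variants, whose fast mode
// (slope ~ Vmax/Km when butyryl-CoA << Km) stability-limits explicit
// methods. Stage systems are lower triangular (see pathway_jac).
// [[Rcpp::export(name = ".ode_solve_ros_cpp")]]
NumericMatrix ode_solve_ros_cpp(NumericVector y0, NumericVector times,
                                NumericVector p, bool inhib, double rtol,
                                double atol, double neg_tol,
                                double max_steps, bool with_flux = false) {
  const int nn = with_flux ? 7 : 5;
  const int nt = times.size();
  if (y0.size() != 5) stop("state vector must have 5 components");
  NumericMatrix out(nt, nn);
  const double gamma = 1.0 - 1.0 / std::sqrt(2.0);

  double y[NMAX], yn[NMAX], ytmp[NMAX], f0[NMAX], f1[NMAX], k1[NMAX],
      k2[NMAX];
  double J[NMAX][NMAX];
  const double *pp = REAL(p);
  for (int i = 0; i < nn; ++i) y[i] = i < 5 ? y0[i] : 0.0;
  double t = times[0];
  for (int i = 0; i < nn; ++i) out(0, i) = y[i];

  double h = 1e-4;
  double steps = 0.0;
  for (int it = 1; it < nt; ++it) {
    const double tend = times[it];
    while (t < tend) {
      if (++steps > max_steps)
        stop("integrator step budget exhausted (step-size collapse?); "
             "last good time t = %g h", t);
      if (h > tend - t) h = tend - t;
      const double gh = gamma * h;

      pathway_rhs(y, f0, pp, inhib, nn);
      pathway_jac(y, J, pp, inhib, nn);
      ros_solve(J, gh, f0, k1, nn);
      for (int i = 0; i < nn; ++i) ytmp[i] = y[i] + h * k1[i];
      pathway_rhs(ytmp, f1, pp, inhib, nn);
      for (int i = 0; i < nn; ++i) ytmp[i] = f1[i] - 2.0 * k1[i];
      ros_solve(J, gh, ytmp, k2, nn);
      for (int i = 0; i < nn; ++i)
        yn[i] = y[i] + 0.5 * h * (3.0 * k1[i] + k2[i]);

      double errsq = 0.0;
      for (int i = 0; i < nn; ++i) {
        const double err = 0.5 * h * (k1[i] + k2[i]);
        const double ya = std::fabs(y[i]), yb = std::fabs(yn[i]);
        const double sc = atol + rtol * (ya > yb ? ya : yb);
        const double r = err / sc;
        errsq += r * r;
      }
      const double errnorm = std::sqrt(errsq / nn);

      if (errnorm <= 1.0) {
        t += h;
        clamp_or_stop(yn, neg_tol, t, nn);
        for (int i = 0; i < nn; ++i) y[i] = yn[i];
      }
      double fac = 0.9 * std::pow(errnorm > 1e-10 ? errnorm : 1e-10,
                                  -1.0 / 3.0);
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      if (h < 1e-14) stop("step size underflow at t = %g h", t);
    }
    for (int i = 0; i < nn; ++i) out(it, i) = y[i];
  }
  return out;
}
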