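#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// One-compartment amount A (mg) with parallel first-order and
// Michaelis-Menten elimination and zero-order input:
//   dA/dt = rate_in - (CL/V)*A - Vmax * (A/V) / (Km + A/V)
// CL may change at each dosing occasion (interoccasion variability).

namespace {

struct PkPars {
  double ke;      // CL/V, 1/day (current occasion)
  double vmax;    // mg/day
  double km;      // mg/L
  double v;       // L
  double rate_in; // mg/day (active infusion rate)
};

inline double rhs(double A, const PkPars &p) {
  double a = A > 0.0 ? A : 0.0;
  double c = a / p.v;
  return p.rate_in - p.ke * a - p.vmax * c / (p.km + c);
}

// Dormand-Prince 5(4) step: returns 5th-order solution, err estimate via
// embedded 4th-order.
inline void dp45(double A, double h, const PkPars &p, double &A5, double &err) {
  const double k1 = rhs(A, p);
  const double k2 = rhs(A + h * (1.0 / 5.0) * k1, p);
  const double k3 = rhs(A + h * (3.0 / 40.0 * k1 + 9.0 / 40.0 * k2), p);
  const double k4 = rhs(A + h * (44.0 / 45.0 * k1 - 56.0 / 15.0 * k2 + 32.0 / 9.0 * k3), p);
  const double k5 = rhs(A + h * (19372.0 / 6561.0 * k1 - 25360.0 / 2187.0 * k2 +
                                 64448.0 / 6561.0 * k3 - 212.0 / 729.0 * k4), p);
  const double k6 = rhs(A + h * (9017.0 / 3168.0 * k1 - 355.0 / 33.0 * k2 +
                                 46732.0 / 5247.0 * k3 + 49.0 / 176.0 * k4 -
                                 5103.0 / 18656.0 * k5), p);
  A5 = A + h * (35.0 / 384.0 * k1 + 500.0 / 1113.0 * k3 + 125.0 / 192.0 * k4 -
                2187.0 / 6784.0 * k5 + 11.0 / 84.0 * k6);
  const double k7 = rhs(A5, p);
  // embedded 4th-order coefficients
  const double A4 = A + h * (5179.0 / 57600.0 * k1 + 7571.0 / 16695.0 * k3 +
                             393.0 / 640.0 * k4 - 92097.0 / 339200.0 * k5 +
                             187.0 / 2100.0 * k6 + 1.0 / 40.0 * k7);
  err = std::fabs(A5 - A4);
}

// Integrate A from t0 to t1 with fixed parameters, adaptive step.
double integrate_span(double A, double t0, double t1, const PkPars &p,
                      double rtol, double atol) {
  if (t1 <= t0) return A;
  double t = t0;
  double h = (t1 - t0);
  if (h > 0.5) h = 0.5; // initial guess, days
  int iter = 0;
  const int max_iter = 20000000;
  while (t < t1) {
    if (++iter > max_iter)
      stop("ODE solver failed to converge: step budget exhausted at t = %f", t);
    if (t + h > t1) h = t1 - t;
    double A5, err;
    dp45(A, h, p, A5, err);
    double sc = atol + rtol * std::max(std::fabs(A), std::fabs(A5));
    if (err <= sc || h < 1e-12) {
      t += h;
      A = A5 > 0.0 ? A5 : 0.0; // drug amount cannot be negative
      double fac = err > 0.0 ? 0.9 * std::pow(sc / err, 0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(sc / err, 0.2);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
    }
    if (!std::isfinite(A))
      stop("ODE solver produced a non-finite amount at t = %f", t);
  }
  return A;
}

} // namespace

//' @useDynLib ecudose, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export(name = ".solve_pk_cpp")]]
NumericVector solve_pk_cpp(NumericVector times,
                           NumericVector dose_time,
                           NumericVector dose_amount,
                           NumericVector dose_duration,
                           NumericVector cl_occ,
                           double v, double vmax, double km,
                           double rtol = 1e-8, double atol = 1e-10) {
  const int nt = times.size();
  const int nd = dose_time.size();
  if (dose_amount.size() != nd || dose_duration.size() != nd || cl_occ.size() != nd)
    stop("dose_time, dose_amount, dose_duration and cl_occ must have equal length");
  for (int i = 1; i < nt; ++i)
    if (times[i] <= times[i - 1]) stop("output times must be strictly increasing");
  for (int i = 1; i < nd; ++i)
    if (dose_time[i] < dose_time[i - 1]) stop("doses must be sorted by time");

  NumericVector conc(nt);
  PkPars p;
  p.v = v; p.vmax = vmax; p.km = km; p.rate_in = 0.0;
  p.ke = nd > 0 ? cl_occ[0] / v : 0.0;

  // breakpoints: dose starts and infusion ends
  struct Ev { double t; int type; int idx; }; // type 0 = dose start, 1 = infusion end
  std::vector<Ev> evs;
  for (int i = 0; i < nd; ++i) {
    evs.push_back({dose_time[i], 0, i});
    if (dose_duration[i] > 0)
      evs.push_back({dose_time[i] + dose_duration[i], 1, i});
  }
  std::stable_sort(evs.begin(), evs.end(),
                   [](const Ev &a, const Ev &b) { return a.t < b.t; });

  double A = 0.0, t = 0.0;
  if (nt > 0 && times[0] < 0) stop("output times must be nonnegative");
  std::size_t ie = 0;
  int it = 0;
  while (it < nt || ie < evs.size()) {
    double t_out = it < nt ? times[it] : R_PosInf;
    double t_ev = ie < evs.size() ? evs[ie].t : R_PosInf;
    if (t_out <= t_ev) {
      // report the pre-dose (left-limit) value when an output time
      // coincides with a dose time: troughs are evaluated immediately
      // before administration
      A = integrate_span(A, t, t_out, p, rtol, atol);
      t = t_out;
      conc[it] = A / v;
      ++it;
    } else {
      A = integrate_span(A, t, t_ev, p, rtol, atol);
      t = t_ev;
      const Ev &e = evs[ie];
      if (e.type == 0) {
        p.ke = cl_occ[e.idx] / v; // new occasion begins at each dose
        if (dose_duration[e.idx] > 0)
          p.rate_in += dose_amount[e.idx] / dose_duration[e.idx];
        else
          A += dose_amount[e.idx];
      } else {
        p.rate_in -= dose_amount[e.idx] / dose_duration[e.idx];
        if (std::fabs(p.rate_in) < 1e-12) p.rate_in = 0.0;
      }
      ++ie;
    }
  }
  return conc;
}
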