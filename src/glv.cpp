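// Adaptive Dormand-Prince 5(4) integrator for the pH-dependent generalized
// Lotka-Volterra system with continuous dilution.
//
//   dS_i/dt = r_i(p) * [1 - (S_i - gamma_i)/K_i(p)] * S_i - delta * S_i
//   gamma_i = sum_{j != i} c_ij(p) * S_j
//
// r_i and K_i are piecewise-linear interpolants of tabulated pH responses,
// clamped to the end values outside the measured grid.  The pH driver is
// constant, sinusoidal, or a precomputed two-level telegraph schedule; the
// emitted pH is clamped to the grid range.  Extinction (S < n_ext -> 0) is
// applied at supplied checkpoint times; a strain at exactly 0 has zero
// derivative, so extinction is permanent.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Driver {
  int kind;  // 0 constant, 1 sinusoid, 2 telegraph
  double p0, dph, f;
  const double* tt;  // telegraph segment start times (sorted, tt[0] == 0)
  const double* tl;  // telegraph levels, level i holds on [tt[i], tt[i+1])
  int nt;
  double lo, hi;  // clamp range (pH grid extent)

  double at(double t) const {
    double p;
    if (kind == 0) {
      p = p0;
    } else if (kind == 1) {
      p = p0 + dph * std::sin(2.0 * M_PI * f * t);
    } else {
      int i = static_cast<int>(std::upper_bound(tt, tt + nt, t) - tt) - 1;
      if (i < 0) i = 0;
      if (i >= nt) i = nt - 1;
      p = tl[i];
    }
    if (p < lo) p = lo;
    if (p > hi) p = hi;
    return p;
  }
};

struct System {
  int n;        // strains
  int ng;       // pH grid points
  const double* grid;
  const double* rtab;  // n x ng, column-major (R matrix)
  const double* Ktab;  // n x ng
  const double* C;     // n x n interaction coefficients, column-major
  const double* M;     // n x n pH slopes or NULL
  double pref;         // reference pH for the slope term
  double delta;
  Driver drv;

  void rhs(double t, const std::vector<double>& S, std::vector<double>& dS,
           std::vector<double>& rv, std::vector<double>& Kv) const {
    double p = drv.at(t);
    // rtab/Ktab are n x ng column-major: element (i, k) at tab[i + k*n]
    for (int i = 0; i < n; ++i) {
      rv[i] = row_interp(rtab, i, p);
      Kv[i] = row_interp(Ktab, i, p);
    }
    double dp = (M != nullptr) ? (p - pref) : 0.0;
    for (int i = 0; i < n; ++i) {
      if (S[i] <= 0.0) {
        dS[i] = 0.0;
        continue;
      }
      double gamma = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double cij = C[i + static_cast<size_t>(j) * n];
        if (M != nullptr) cij += M[i + static_cast<size_t>(j) * n] * dp;
        gamma += cij * S[j];
      }
      dS[i] = rv[i] * (1.0 - (S[i] - gamma) / Kv[i]) * S[i] - delta * S[i];
    }
  }

  double row_interp(const double* tab, int i, double p) const {
    // linear interpolation along row i of an n x ng column-major table
    if (p <= grid[0]) return tab[i];
    if (p >= grid[ng - 1]) return tab[i + static_cast<size_t>(ng - 1) * n];
    int j = static_cast<int>(std::upper_bound(grid, grid + ng, p) - grid) - 1;
    double w = (p - grid[j]) / (grid[j + 1] - grid[j]);
    double v0 = tab[i + static_cast<size_t>(j) * n];
    double v1 = tab[i + static_cast<size_t>(j + 1) * n];
    return v0 + w * (v1 - v0);
  }
};

// Dormand-Prince 5(4) tableau
const double A21 = 1.0 / 5.0;
const double A31 = 3.0 / 40.0, A32 = 9.0 / 40.0;
const double A41 = 44.0 / 45.0, A42 = -56.0 / 15.0, A43 = 32.0 / 9.0;
const double A51 = 19372.0 / 6561.0, A52 = -25360.0 / 2187.0,
             A53 = 64448.0 / 6561.0, A54 = -212.0 / 729.0;
const double A61 = 9017.0 / 3168.0, A62 = -355.0 / 33.0,
             A63 = 46732.0 / 5247.0, A64 = 49.0 / 176.0,
             A65 = -5103.0 / 18656.0;
const double B1 = 35.0 / 384.0, B3 = 500.0 / 1113.0, B4 = 125.0 / 192.0,
             B5 = -2187.0 / 6784.0, B6 = 11.0 / 84.0;
const double E1 = 71.0 / 57600.0, E3 = -71.0 / 16695.0, E4 = 71.0 / 1920.0,
             E5 = -17253.0 / 339200.0, E6 = 22.0 / 525.0, E7 = -1.0 / 40.0;
const double C2 = 1.0 / 5.0, C3 = 3.0 / 10.0, C4 = 4.0 / 5.0, C5 = 8.0 / 9.0;

// Integrate from t0 to t1 (no events inside), updating y in place.
// Returns number of accepted steps; throws on runaway growth.
long integrate_segment(const System& sys, std::vector<double>& y, double t0,
                       double t1, double rtol, double atol, double max_total,
                       double& h, long max_steps) {
  int n = sys.n;
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n);
  std::vector<double> ytmp(n), y5(n), rv(n), Kv(n);
  double t = t0;
  long nacc = 0;
  if (h <= 0.0) h = 1e-3;
  sys.rhs(t, y, k1, rv, Kv);  // FSAL seed
  long iter = 0;
  while (t < t1) {
    if (++iter > max_steps)
      stop("glv integrator exceeded %ld steps on [%g, %g]", max_steps, t0, t1);
    if (h > t1 - t) h = t1 - t;
    // stages
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * A21 * k1[i];
    sys.rhs(t + C2 * h, ytmp, k2, rv, Kv);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
    sys.rhs(t + C3 * h, ytmp, k3, rv, Kv);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
    sys.rhs(t + C4 * h, ytmp, k4, rv, Kv);
    for (int i = 0; i < n; ++i)
      ytmp[i] =
          y[i] + h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] + A54 * k4[i]);
    sys.rhs(t + C5 * h, ytmp, k5, rv, Kv);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                            A64 * k4[i] + A65 * k5[i]);
    sys.rhs(t + h, ytmp, k6, rv, Kv);
    for (int i = 0; i < n; ++i)
      y5[i] = y[i] + h * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] + B5 * k5[i] +
                          B6 * k6[i]);
    sys.rhs(t + h, y5, k7, rv, Kv);
    // error estimate
    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = h * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] + E5 * k5[i] +
                      E6 * k6[i] + E7 * k7[i]);
      double sc =
          atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double q = e / sc;
      err += q * q;
    }
    err = std::sqrt(err / n);
    if (err <= 1.0 || h <= 1e-12) {
      t += h;
      for (int i = 0; i < n; ++i) {
        y[i] = y5[i];
        if (y[i] < 0.0) y[i] = 0.0;  // numerical undershoot only
      }
      std::swap(k1, k7);  // FSAL
      ++nacc;
      double tot = 0.0;
      for (int i = 0; i < n; ++i) tot += y[i];
      if (tot > max_total)
        stop(
            "runaway growth: total density %g exceeded %g at t = %g h; the "
            "Lotka-Volterra system is unstable (strong mutual facilitation, "
            "c_ij * c_ji > 1)",
            tot, max_total, t);
    }
    double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < 1e-12) h = 1e-12;
  }
  return nacc;
}

}  // namespace

// [[Rcpp::export(.glv_integrate)]]
List glv_integrate(NumericVector S0, NumericVector grid, NumericMatrix rtab,
                   NumericMatrix Ktab, NumericMatrix C,
                   Nullable<NumericMatrix> slopes, double pref, double delta,
                   int driver_kind, double p0, double dph, double fph,
                   NumericVector tele_times, NumericVector tele_levels,
                   double t_end, NumericVector t_out,
                   NumericVector checkpoints, double n_ext, double rtol,
                   double atol, double max_total) {
  int n = S0.size();
  System sys;
  sys.n = n;
  sys.ng = grid.size();
  sys.grid = grid.begin();
  sys.rtab = rtab.begin();
  sys.Ktab = Ktab.begin();
  sys.C = C.begin();
  NumericMatrix Mkeep;
  sys.M = nullptr;
  if (slopes.isNotNull()) {
    Mkeep = slopes.get();
    sys.M = Mkeep.begin();
  }
  sys.pref = pref;
  sys.delta = delta;
  sys.drv.kind = driver_kind;
  sys.drv.p0 = p0;
  sys.drv.dph = dph;
  sys.drv.f = fph;
  sys.drv.tt = tele_times.begin();
  sys.drv.tl = tele_levels.begin();
  sys.drv.nt = tele_times.size();
  sys.drv.lo = grid[0];
  sys.drv.hi = grid[grid.size() - 1];

  // merged, sorted event times: outputs, extinction checkpoints, telegraph
  // switches, end of horizon
  std::vector<double> events;
  events.reserve(t_out.size() + checkpoints.size() + sys.drv.nt + 1);
  for (double t : t_out)
    if (t > 0.0 && t <= t_end) events.push_back(t);
  for (double t : checkpoints)
    if (t > 0.0 && t <= t_end) events.push_back(t);
  if (driver_kind == 2)
    for (double t : tele_times)
      if (t > 0.0 && t < t_end) events.push_back(t);
  events.push_back(t_end);
  std::sort(events.begin(), events.end());
  events.erase(std::unique(events.begin(), events.end()), events.end());

  std::vector<double> y(S0.begin(), S0.end());
  NumericMatrix out(n, t_out.size());
  NumericVector ph_out(t_out.size());
  // record t = 0 outputs if requested
  int iout = 0;
  while (iout < t_out.size() && t_out[iout] <= 0.0) {
    for (int i = 0; i < n; ++i) out(i, iout) = y[i];
    ph_out[iout] = sys.drv.at(0.0);
    ++iout;
  }
  std::vector<double> cps(checkpoints.begin(), checkpoints.end());
  std::sort(cps.begin(), cps.end());

  double t = 0.0, h = 1e-3;
  long nsteps = 0;
  const long max_steps = 50000000L;
  for (double te : events) {
    if (te <= t) continue;
    nsteps += integrate_segment(sys, y, t, te, rtol, atol, max_total, h,
                                max_steps);
    t = te;
    // extinction checkpoint?
    if (std::binary_search(cps.begin(), cps.end(), te)) {
      for (int i = 0; i < n; ++i)
        if (y[i] < n_ext) y[i] = 0.0;
    }
    while (iout < t_out.size() && t_out[iout] <= te) {
      for (int i = 0; i < n; ++i) out(i, iout) = y[i];
      ph_out[iout] = sys.drv.at(te);
      ++iout;
    }
  }
  NumericVector yfin(n);
  for (int i = 0; i < n; ++i) yfin[i] = y[i];
  return List::create(_["states"] = out, _["ph"] = ph_out,
                      _["final"] = yfin, _["nsteps"] = nsteps);
}
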