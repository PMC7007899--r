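#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integration of the linearised single-link balance loop
//
//   J theta'' = mgh * theta + T(t - tau) + noise(t)
//   T = Kp * e + Kd * e' + Ki * int e,   e = w * u - theta + r
//
// The command is split into a smooth feedback part (linearly interpolated
// between command samples inside each RK4 step) and the velocity
// feedthrough Kd * w * du, which is applied as a zero-order hold.  `du`
// must be the platform velocity sampled at sample midpoints: for a
// velocity staircase whose steps fall on sample boundaries the hold is
// then exact, and for smooth stimuli the midpoint rule leaves only an
// O(dt^2) error.  The transport delay is dlay whole samples.
//
// [[Rcpp::export]]
List pendulum_loop(NumericVector u, NumericVector du, double dt,
                   double J, double mgh, double Kp, double Kd, double Ki,
                   int dlay, double w, double r, NumericVector noise,
                   double theta0, double omega0, double E0,
                   double fall_rad) {
  const int n = u.size();
  NumericVector th(n), om(n), torque(n);
  std::vector<double> Tfb(n), Tff(n);

  th[0] = theta0;
  om[0] = omega0;
  double E = E0;
  double eprev = w * u[0] - th[0] + r;
  Tfb[0] = Kp * eprev - Kd * om[0] + Ki * E;
  for (int k = 0; k < n; k++) Tff[k] = Kd * w * du[k];

  bool fell = false;
  int fell_at = -1;

  // applied torque emitted at sample times (drives the centre of pressure)
  {
    double F0 = Tfb[0], Z = Tff[0];
    torque[0] = F0 + Z + noise[0];
  }

  for (int k = 0; k < n - 1; k++) {
    int i0 = k - dlay, i1 = k - dlay + 1;
    double F0 = (i0 >= 0) ? Tfb[i0] : Tfb[0];
    double F1 = (i1 >= 0) ? Tfb[i1] : Tfb[0];
    double Z  = (i0 >= 0) ? Tff[i0] : Tff[0];
    if (dlay == 0) { F0 = Tfb[k]; F1 = Tfb[k]; Z = Tff[k]; }
    const double nz = noise[k];
    const double Fm = 0.5 * (F0 + F1);

    const double a0 = F0 + Z + nz, am = Fm + Z + nz, a1 = F1 + Z + nz;
    const double t0 = th[k], o0 = om[k];

    // RK4 stages for theta' = omega, omega' = (mgh*theta + T)/J
    const double k1t = o0;
    const double k1o = (mgh * t0 + a0) / J;
    const double k2t = o0 + 0.5 * dt * k1o;
    const double k2o = (mgh * (t0 + 0.5 * dt * k1t) + am) / J;
    const double k3t = o0 + 0.5 * dt * k2o;
    const double k3o = (mgh * (t0 + 0.5 * dt * k2t) + am) / J;
    const double k4t = o0 + dt * k3o;
    const double k4o = (mgh * (t0 + dt * k3t) + a1) / J;

    th[k + 1] = t0 + dt / 6.0 * (k1t + 2 * k2t + 2 * k3t + k4t);
    om[k + 1] = o0 + dt / 6.0 * (k1o + 2 * k2o + 2 * k3o + k4o);

    const double e = w * u[k + 1] - th[k + 1] + r;
    E += dt * 0.5 * (eprev + e);
    eprev = e;
    Tfb[k + 1] = Kp * e - Kd * om[k + 1] + Ki * E;

    {
      int j0 = k + 1 - dlay;
      double Fa = (j0 >= 0) ? Tfb[j0] : Tfb[0];
      double Za = (j0 >= 0) ? Tff[j0] : Tff[0];
      if (dlay == 0) { Fa = Tfb[k + 1]; Za = Tff[k + 1]; }
      torque[k + 1] = Fa + Za + noise[k + 1];
    }

    if (std::fabs(th[k + 1]) > fall_rad) {
      fell = true;
      fell_at = k + 1;
      break;
    }
  }

  return List::create(_["theta"] = th, _["omega"] = om,
                      _["torque"] = torque, _["fell"] = fell,
                      _["fell_at"] = fell_at + 1);
}
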