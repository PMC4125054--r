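#include <Rcpp.h>
using namespace Rcpp;

// Discretized Brownian walkers for the two organ geometries, plus the
// kinetic Monte Carlo circulation loop. All use R's RNG (set.seed applies).
// Units: lengths in micrometres, motility M in um^2/min (3D MSD = 6 M t,
// in-plane MSD = 4 M t), time steps in minutes, returned times in hours.

// First-passage times of 3D Brownian motion from the centre of an absorbing
// sphere of radius R. Per-axis step sd = sqrt(2 M dt).
// [[Rcpp::export]]
NumericVector cpp_sphere_fpt(int n, double radius, double motility, double dt) {
  NumericVector out(n);
  const double sd = std::sqrt(2.0 * motility * dt);
  const double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    double x = 0.0, y = 0.0, z = 0.0, t = 0.0;
    for (;;) {
      x += sd * norm_rand();
      y += sd * norm_rand();
      z += sd * norm_rand();
      t += dt;
      if (x * x + y * y + z * z >= r2) break;
    }
    out[i] = t / 60.0;
  }
  return out;
}

// Transit times through the spleen cross-section: 2D Brownian motion in a
// disc of radius R, entering at the boundary point (-R, 0). The boundary
// reflects (radial specular projection per step) except for an absorbing
// arc of half-width alpha/2 centred at (+R, 0), diametrically opposite the
// entry point.
// [[Rcpp::export]]
NumericVector cpp_disc_transit(int n, double radius, double alpha,
                               double motility, double dt) {
  NumericVector out(n);
  const double sd = std::sqrt(2.0 * motility * dt);
  const double half = alpha / 2.0;
  for (int i = 0; i < n; ++i) {
    double x = -radius, y = 0.0, t = 0.0;
    for (;;) {
      x += sd * norm_rand();
      y += sd * norm_rand();
      t += dt;
      double r = std::sqrt(x * x + y * y);
      if (r >= radius) {
        // angle relative to the exit direction (+x axis)
        double ang = std::atan2(y, x);
        if (std::fabs(ang) <= half) break;
        // reflect back into the disc
        double rnew = 2.0 * radius - r;
        if (rnew < 0) rnew = 0;
        x *= rnew / r;
        y *= rnew / r;
      }
    }
    out[i] = t / 60.0;
  }
  return out;
}

// Linear-interpolation draw from a tabulated CDF (F grid vs t grid, both
// increasing). u beyond the table is clamped to the last knot.
static double q_interp(double u, const NumericVector& F, const NumericVector& t) {
  int n = F.size();
  if (u <= F[0]) return t[0];
  if (u >= F[n - 1]) return t[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (F[mid] <= u) lo = mid; else hi = mid;
  }
  double w = (u - F[lo]) / (F[hi] - F[lo]);
  return t[lo] + w * (t[hi] - t[lo]);
}

// Kinetic Monte Carlo circulation of independent T cells between blood,
// spleen and LN spheres.
//
// Compartment codes in the episode table: 0 = blood, 1 = spleen,
// 2..(n_ln+1) = LN sphere index + 2.
//
// sigma_ln:    baseline entry rate per LN sphere (per hour)
// dln:         integer 0/1 flags per sphere
// ramp_fold:   1 = no ramp; dLN entry rates scale linearly from 1x at t=0
//              to ramp_fold x at ramp_end_h, constant after (baseline for t<0)
// det_transit: > 0 fixes the LN dwell; <= 0 samples from the LN table
// ln_F/ln_t, sp_F/sp_t: tabulated transit-time CDFs (hours)
// priming shape/rate: > 0 enables retention in dLN spheres from t = 0 on;
//              a Gamma(shape, rate) retention time A is drawn per dLN visit
//              and the cell is retained iff A < the (remaining) dwell
// burn_in_h:   per-cell burn-in duration (hours before t = 0); cells start
//              in the blood at t = -burn_in_h[i]
// horizon_h:   recording stops at this time (hours)
// record:      if false, only per-cell outcomes are returned
// [[Rcpp::export]]
List cpp_simulate_cohort(int n_cells,
                         NumericVector burn_in_h,
                         double horizon_h,
                         double sigma_spleen,
                         NumericVector sigma_ln,
                         IntegerVector dln,
                         double ramp_fold,
                         double ramp_end_h,
                         double det_transit,
                         NumericVector ln_F, NumericVector ln_t,
                         NumericVector sp_F, NumericVector sp_t,
                         double priming_shape,
                         double priming_rate,
                         double dln_visit_prob,
                         bool record) {
  const int n_ln = sigma_ln.size();
  double base_ln_total = 0.0, dln_total = 0.0;
  for (int j = 0; j < n_ln; ++j) {
    base_ln_total += sigma_ln[j];
    if (dln[j]) dln_total += sigma_ln[j];
  }
  const double lambda_base = sigma_spleen + base_ln_total;
  const double lambda_max = lambda_base + (ramp_fold - 1.0) * dln_total;
  const bool priming = priming_shape > 0 && priming_rate > 0;

  std::vector<int> ep_cell, ep_comp;
  std::vector<double> ep_entry, ep_exit;
  NumericVector retention_time(n_cells, NA_REAL);
  IntegerVector outcome(n_cells); // 0 censored/circulating, 1 retained
  IntegerVector initial_dln(n_cells); // 1 if inside a dLN when t crosses 0

  for (int i = 0; i < n_cells; ++i) {
    double t = -burn_in_h[i];
    bool retained = false;
    while (t < horizon_h && !retained) {
      // --- blood episode: thinning against lambda_max ---
      double t0 = t;
      for (;;) {
        t += exp_rand() / lambda_max;
        double fold = 1.0;
        if (ramp_fold > 1.0 && t > 0.0)
          fold = (t >= ramp_end_h) ? ramp_fold
                                   : 1.0 + (ramp_fold - 1.0) * t / ramp_end_h;
        double lambda_t = lambda_base + (fold - 1.0) * dln_total;
        if (unif_rand() <= lambda_t / lambda_max) break;
      }
      if (record && t > 0.0) {
        ep_cell.push_back(i + 1); ep_comp.push_back(0);
        ep_entry.push_back(t0);
        ep_exit.push_back(t < horizon_h ? t : horizon_h);
      }
      if (t >= horizon_h) break;

      // --- choose next organ with probability rate / Lambda(t) ---
      double fold = 1.0;
      if (ramp_fold > 1.0 && t > 0.0)
        fold = (t >= ramp_end_h) ? ramp_fold
                                 : 1.0 + (ramp_fold - 1.0) * t / ramp_end_h;
      double lambda_t = lambda_base + (fold - 1.0) * dln_total;
      double u = unif_rand() * lambda_t;
      int comp;
      if (u < sigma_spleen) {
        comp = 1;
      } else {
        u -= sigma_spleen;
        comp = -1;
        for (int j = 0; j < n_ln; ++j) {
          double rate = sigma_ln[j] * (dln[j] ? fold : 1.0);
          if (u < rate) { comp = j + 2; break; }
          u -= rate;
        }
        if (comp < 0) comp = n_ln + 1; // numerical edge: last sphere
      }

      // --- organ episode ---
      double dwell;
      if (comp == 1) {
        dwell = q_interp(unif_rand(), sp_F, sp_t);
      } else if (det_transit > 0.0) {
        dwell = det_transit;
      } else {
        dwell = q_interp(unif_rand(), ln_F, ln_t);
      }
      double t_exit = t + dwell;
      // a visit counts as a dLN visit either via the per-sphere flags or,
      // when dln_visit_prob >= 0, via an i.i.d. Bernoulli draw per LN visit
      // (exact representation of a dLN *fraction* under even entry rates)
      bool is_dln_visit = false;
      if (comp >= 2) {
        if (dln_visit_prob >= 0.0) is_dln_visit = unif_rand() < dln_visit_prob;
        else is_dln_visit = dln[comp - 2] != 0;
      }
      if (is_dln_visit && t <= 0.0 && t_exit > 0.0) initial_dln[i] = 1;
      if (priming && is_dln_visit && t_exit > 0.0) {
        // antigen appears at t = 0; priming runs only over the part of the
        // dwell after that
        double t_start = (t > 0.0) ? t : 0.0;
        double A = R::rgamma(priming_shape, 1.0 / priming_rate);
        if (t_start + A < t_exit) {
          retained = true;
          retention_time[i] = t_start + A;
          outcome[i] = 1;
          t_exit = t_start + A;
        }
      }
      if (record && t_exit > 0.0) {
        ep_cell.push_back(i + 1); ep_comp.push_back(comp);
        ep_entry.push_back(t);
        ep_exit.push_back(t_exit < horizon_h ? t_exit : horizon_h);
      }
      t = t_exit;
    }
  }

  List out = List::create(
    _["outcome"] = outcome,
    _["retention_time"] = retention_time,
    _["initial_dln"] = initial_dln);
  if (record) {
    out["episodes"] = DataFrame::create(
      _["cell_id"] = wrap(ep_cell),
      _["compartment"] = wrap(ep_comp),
      _["t_entry_h"] = wrap(ep_entry),
      _["t_exit_h"] = wrap(ep_exit));
  }
  return out;
}
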