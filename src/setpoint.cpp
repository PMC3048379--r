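#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial recursion of the setpoint state-space model family.
//
// States: x_hat, the internal model's estimate of the rotation, and s, the
// strategy state (both degrees). The aiming location is the current
// strategy state (re-aiming recenters the setpoint), weighted by the
// availability K. Per trial n:
//   e_n    = r_n - x_hat_n + s_n           (target error)
//   ehat_n = r_n - x_hat_n + (1 - K)*s_n   (aiming error, K-weighted aim)
//   x_hat_{n+1} = A*x_hat_n + B*err_n      (err_n = e or ehat by variant)
//   s_{n+1}     = E*s_n - F*e_n            (full_dynamic, rotation block)
// Hand angle h_n = e_n - r_n. No state update on no-feedback trials.
//
// Variant codes: 0 standard, 1 feedthrough_target_error,
// 2 feedthrough_fixed_strategy (K forced to 1), 3 feedthrough_fixed_strategy_K,
// 4 full_dynamic.
//
// Block codes: 0 other, 1 strategy_only, 2 rotation_strategy.
// On strategy_only trials feedback is veridical and centred on the aim, so
// the learning error is the true aim-referenced error (K forced to 1) and
// the strategy state is pinned at the instructed angle.

// [[Rcpp::export(name = ".sp_simulate_cpp")]]
NumericMatrix sp_simulate_cpp(IntegerVector block_code,
                              NumericVector rotation,
                              LogicalVector strategy_instructed,
                              LogicalVector feedback,
                              double A, double B, double E, double K,
                              double F, double s_star,
                              int variant) {
  const int n = block_code.size();
  NumericMatrix out(n, 5);
  colnames(out) = CharacterVector::create("x_hat", "s", "target_error",
                                          "aiming_error", "hand_angle");
  double xhat = 0.0, s_carry = 0.0;
  bool in_rot_strat = false;

  for (int i = 0; i < n; ++i) {
    const double r = rotation[i];
    const bool instr = strategy_instructed[i];
    const double sstar = (variant == 0) ? 0.0 : (instr ? s_star : 0.0);

    // strategy state for this trial
    double s;
    if (variant == 0) {
      s = 0.0;
    } else if (variant != 4) {
      s = sstar;
    } else {
      if (block_code[i] == 2) {            // rotation_strategy: dynamic
        if (!in_rot_strat) s_carry = s_star; // (re)engage strategy at block start
        s = s_carry;
      } else if (instr) {                  // strategy_only: pinned at aim
        s = s_star;
      } else {                             // no strategy in use
        s = 0.0;
      }
    }
    in_rot_strat = (block_code[i] == 2);

    const double e = r - xhat + s;
    double Keff;
    if (variant == 2) Keff = 1.0;
    else if (variant == 3 || variant == 4) Keff = K;
    else Keff = 1.0;                       // variants 0,1: err choice below
    if (block_code[i] == 1) Keff = 1.0;    // veridical feedback on the aim
    const double ehat = r - xhat + s - Keff * s;

    double err;
    if (variant == 0) err = e;
    else if (variant == 1) err = (block_code[i] == 1) ? ehat : e;
    else err = ehat;

    out(i, 0) = xhat;
    out(i, 1) = s;
    out(i, 2) = e;
    out(i, 3) = ehat;
    out(i, 4) = e - r;

    if (feedback[i]) {
      const double xnew = A * xhat + B * err;
      if (variant == 4 && block_code[i] == 2)
        s_carry = E * s - F * e;
      else
        s_carry = s;
      xhat = xnew;
    }
    // no-feedback trials: both states carried forward unchanged
  }
  return out;
}

// Root-mean-square error between observed and model target error on the
// fitted trials, used inside the simplex loop.

// [[Rcpp::export(name = ".sp_rms_cpp")]]
double sp_rms_cpp(IntegerVector block_code,
                  NumericVector rotation,
                  LogicalVector strategy_instructed,
                  LogicalVector feedback,
                  double A, double B, double E, double K, double F,
                  double s_star,
                  NumericVector observed,
                  LogicalVector fitted_mask) {
  NumericMatrix tr = sp_simulate_cpp(block_code, rotation,
                                     strategy_instructed, feedback,
                                     A, B, E, K, F, s_star, 4);
  double ss = 0.0;
  int m = 0;
  for (int i = 0; i < observed.size(); ++i) {
    if (fitted_mask[i]) {
      const double d = observed[i] - tr(i, 2);
      ss += d * d;
      ++m;
    }
  }
  if (m == 0) return NA_REAL;
  return std::sqrt(ss / m);
}
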