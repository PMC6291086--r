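#include <Rcpp.h>
using namespace Rcpp;

// Inner loop of the generalized sleep model. One call advances the state
// (H, A, z) through n = (burn_days + days) * q ten-minute periods, consuming
// standard-normal draws from `eps` in order. Per period:
//   z_t   = rho_pp * z_{t-1} + sigma * eps_t
//   y_t   = -cos(2 pi t / q)                      (t counted from the start,
//                                                  period 0 = midnight)
//   H^w   = mu_W + (H_{t-1} - mu_W) * aW          (candidate wake update)
//   H^s   = mu_S + (H_{t-1} - mu_S) * aS          (candidate sleep update)
//   U(0)  = [e^z xi_t (mu_W - H_{t-1})^eta]^gamma - chi|H^w - y|^kappa
//           - lam [A_{t-1} != 0]
//   U(1)  = -chi|H^s - y|^kappa - lam [A_{t-1} != 1]
// The chosen action is the argmax; exact ties keep the previous action.
// aW, aS are the per-period decay factors exp(-24/(nu_hours * q)) and rho_pp
// the per-period AR coefficient; both conversions happen on the R side so a
// single convention rules the whole package.
//
// `xi_schedule` (length q) optionally modulates xi by time of day; length 0
// disables it. With full_output = false only the per-day sleep-hour vector is
// returned, which keeps calibration loops allocation-light.

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector eps, int q, int days, int burn_days,
              double kappa, double eta, double gamma_, double rho_pp,
              double aW, double aS, double mu_W, double mu_S,
              double lam, double chi, double xi, double sigma,
              double H0, int A0, double z0,
              NumericVector xi_schedule, bool full_output) {
  const int n_total = (days + burn_days) * q;
  const int n_keep = days * q;
  const int n_burn = burn_days * q;
  if (eps.size() < n_total)
    stop("draw bank too short: need %d draws, have %d", n_total,
         (int)eps.size());
  const bool sched = xi_schedule.size() == q;
  const bool k2 = (kappa == 2.0), e1 = (eta == 1.0), g1 = (gamma_ == 1.0);

  std::vector<double> ytab(q);
  for (int i = 0; i < q; ++i)
    ytab[i] = -std::cos(2.0 * M_PI * (double)i / (double)q);

  IntegerVector A(full_output ? n_keep : 0);
  NumericVector H(full_output ? n_keep : 0), Z(full_output ? n_keep : 0),
      U(full_output ? n_keep : 0), Y(full_output ? n_keep : 0);
  IntegerVector day_sleep(days);

  double h = H0, zz = z0;
  int a = A0;
  for (int t = 0; t < n_total; ++t) {
    zz = rho_pp * zz + sigma * eps[t];
    const int ph = t % q;
    const double y = ytab[ph];
    const double xi_t = sched ? xi * xi_schedule[ph] : xi;
    const double Hw = mu_W + (h - mu_W) * aW;
    const double Hs = mu_S + (h - mu_S) * aS;
    double cap = mu_W - h;
    if (cap < 0.0) cap = 0.0;  // guards rounding at the asymptote
    double prod = std::exp(zz) * xi_t * (e1 ? cap : std::pow(cap, eta));
    const double W = g1 ? prod : std::pow(prod, gamma_);
    const double dw = std::fabs(Hw - y), ds = std::fabs(Hs - y);
    const double pw = chi * (k2 ? dw * dw : std::pow(dw, kappa));
    const double ps = chi * (k2 ? ds * ds : std::pow(ds, kappa));
    const double Uw = W - pw - (a != 0 ? lam : 0.0);
    const double Us = -ps - (a != 1 ? lam : 0.0);
    if (Us > Uw)
      a = 1;
    else if (Uw > Us)
      a = 0;  // exact tie keeps previous action
    h = (a == 1) ? Hs : Hw;
    if (t >= n_burn) {
      const int k = t - n_burn;
      day_sleep[k / q] += a;
      if (full_output) {
        A[k] = a;
        H[k] = h;
        Z[k] = zz;
        U[k] = (a == 1) ? Us : Uw;
        Y[k] = y;
      }
    }
  }

  NumericVector daily_hours(days);
  for (int d = 0; d < days; ++d)
    daily_hours[d] = day_sleep[d] * 24.0 / (double)q;

  if (full_output)
    return List::create(_["A"] = A, _["H"] = H, _["z"] = Z, _["U"] = U,
                        _["y"] = Y, _["daily_hours"] = daily_hours,
                        _["H_end"] = h, _["A_end"] = a, _["z_end"] = zz);
  return List::create(_["daily_hours"] = daily_hours, _["H_end"] = h,
                      _["A_end"] = a, _["z_end"] = zz);
}
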