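#include <Rcpp.h>
using namespace Rcpp;

// Local linear trend state space recursion.
//
// State Z_t = (a_t, b_t)', transition G = [[1,1],[0,1]], state noise
// diag(s2a, s2b), observation y_t = a_t + eps_t with eps ~ N(0, s2eps).
// The prior N(m0, diag(P0)) applies to the state at the first time point;
// missing observations (NA) perform the time update only.
//
// Covariances are carried as (p11, p12, p22); the 2x2 matrices involved are
// small enough that the unrolled scalar recursion is both the fastest and
// the clearest way to write this.

// [[Rcpp::export(name = ".kalman_cpp")]]
List kalman_cpp(NumericVector y, double s2eps, double s2a, double s2b,
                NumericVector m0, NumericVector P0, bool smooth) {
  const int T = y.size();
  NumericMatrix mf(T, 2), Pf(T, 3);   // filtered means / covariances
  NumericMatrix mp(T, 2), Pp(T, 3);   // one-step predicted
  double loglik = 0.0;
  int nobs = 0;

  double m1 = m0[0], m2 = m0[1];
  double p11 = P0[0], p12 = 0.0, p22 = P0[1];

  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      // time update through G and state noise
      double n1 = m1 + m2, n2 = m2;
      double q11 = p11 + 2.0 * p12 + p22 + s2a;
      double q12 = p12 + p22;
      double q22 = p22 + s2b;
      m1 = n1; m2 = n2; p11 = q11; p12 = q12; p22 = q22;
    }
    mp(t, 0) = m1; mp(t, 1) = m2;
    Pp(t, 0) = p11; Pp(t, 1) = p12; Pp(t, 2) = p22;

    if (!NumericVector::is_na(y[t])) {
      double F = p11 + s2eps;
      if (F <= 0.0) { loglik = R_NegInf; }
      else {
        double v = y[t] - m1;
        loglik += -0.5 * (std::log(2.0 * M_PI * F) + v * v / F);
        double K1 = p11 / F, K2 = p12 / F;
        m1 += K1 * v;
        m2 += K2 * v;
        // covariance update; p12 must use the pre-update p12
        double u11 = p11 - K1 * p11;
        double u12 = p12 - K1 * p12;
        double u22 = p22 - K2 * p12;
        p11 = u11; p12 = u12; p22 = u22;
      }
      ++nobs;
    }
    mf(t, 0) = m1; mf(t, 1) = m2;
    Pf(t, 0) = p11; Pf(t, 1) = p12; Pf(t, 2) = p22;
  }

  List out = List::create(
    _["loglik"] = loglik, _["n_obs"] = nobs,
    _["m_filt"] = mf, _["P_filt"] = Pf,
    _["m_pred"] = mp, _["P_pred"] = Pp);

  if (!smooth) return out;

  // Rauch-Tung-Striebel fixed-interval smoother
  NumericMatrix ms(T, 2), Ps(T, 3);
  ms(T - 1, 0) = mf(T - 1, 0); ms(T - 1, 1) = mf(T - 1, 1);
  Ps(T - 1, 0) = Pf(T - 1, 0); Ps(T - 1, 1) = Pf(T - 1, 1);
  Ps(T - 1, 2) = Pf(T - 1, 2);

  for (int t = T - 2; t >= 0; --t) {
    double f11 = Pf(t, 0), f12 = Pf(t, 1), f22 = Pf(t, 2);
    double q11 = Pp(t + 1, 0), q12 = Pp(t + 1, 1), q22 = Pp(t + 1, 2);
    double det = q11 * q22 - q12 * q12;
    double J11, J12, J21, J22;
    if (det <= 0.0 || !R_finite(1.0 / det)) {
      // degenerate predictive covariance (all variances zero): carry forward
      J11 = J12 = J21 = J22 = 0.0;
    } else {
      // A = Pf G' = [[f11 + f12, f12], [f12 + f22, f22]]; J = A Ppred^{-1}
      double a11 = f11 + f12, a12 = f12, a21 = f12 + f22, a22 = f22;
      double i11 = q22 / det, i12 = -q12 / det, i22 = q11 / det;
      J11 = a11 * i11 + a12 * i12;
      J12 = a11 * i12 + a12 * i22;
      J21 = a21 * i11 + a22 * i12;
      J22 = a21 * i12 + a22 * i22;
    }
    double d1 = ms(t + 1, 0) - mp(t + 1, 0);
    double d2 = ms(t + 1, 1) - mp(t + 1, 1);
    ms(t, 0) = mf(t, 0) + J11 * d1 + J12 * d2;
    ms(t, 1) = mf(t, 1) + J21 * d1 + J22 * d2;

    double e11 = Ps(t + 1, 0) - q11;
    double e12 = Ps(t + 1, 1) - q12;
    double e22 = Ps(t + 1, 2) - q22;
    // J E J'
    double t11 = J11 * e11 + J12 * e12, t12 = J11 * e12 + J12 * e22;
    double t21 = J21 * e11 + J22 * e12, t22 = J21 * e12 + J22 * e22;
    Ps(t, 0) = f11 + t11 * J11 + t12 * J12;
    Ps(t, 1) = f12 + t11 * J21 + t12 * J22;
    Ps(t, 2) = f22 + t21 * J21 + t22 * J22;
  }

  out["m_smooth"] = ms;
  out["P_smooth"] = Ps;
  return out;
}
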