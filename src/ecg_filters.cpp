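#include <Rcpp.h>
using namespace Rcpp;

// Sample-rate inner loops of the extended and ensemble Kalman filters for
// the two-dimensional polar ECG model (state = phase theta, amplitude z;
// observation = observed phase phi, observed amplitude s). Kept in C++ so a
// 60 s record at 1 kHz with a 70-member ensemble filters in milliseconds.

static const double TWO_PI = 6.283185307179586476925286766559;

static inline double wrap2pi(double x) {
  double y = x - TWO_PI * std::floor(x / TWO_PI);
  if (y >= TWO_PI) y -= TWO_PI;  // guard against rounding at the boundary
  if (y < 0) y = 0.0;
  return y;
}

static inline double wrappi(double x) {
  return wrap2pi(x + M_PI) - M_PI;
}

// Gaussian-sum phase derivative G'(theta) and its derivative G''(theta)
static inline void gsum_d1_d2(double theta, const double* alpha,
                              const double* b, const double* thw,
                              double* d1, double* d2) {
  double s1 = 0.0, s2 = 0.0;
  for (int i = 0; i < 5; ++i) {
    double d = wrappi(theta - thw[i]);
    double b2 = b[i] * b[i];
    double e = std::exp(-d * d / (2.0 * b2));
    s1 += -alpha[i] * d / b2 * e;
    s2 += -alpha[i] / b2 * (1.0 - d * d / b2) * e;
  }
  *d1 = s1;
  *d2 = s2;
}

// [[Rcpp::export]]
List ecg_ekf_cpp(NumericVector phi, NumericVector s, NumericVector omega,
                 double delta, NumericVector alpha, NumericVector b,
                 NumericVector thw, double q_theta, double q_z,
                 double r_phi, double r_z, double theta0, double z0,
                 double p0) {
  int n = phi.size();
  NumericVector th_hat(n), z_hat(n);
  double th = theta0, z = z0;
  double p11 = p0, p12 = 0.0, p22 = p0;
  const double* al = alpha.begin();
  const double* bb = b.begin();
  const double* tw = thw.begin();
  for (int k = 0; k < n; ++k) {
    double dth = omega[k] * delta;
    double th_pred = wrap2pi(th + dth);
    double g1, g2;
    gsum_d1_d2(th_pred, al, bb, tw, &g1, &g2);
    double z_pred = z + dth * g1;
    double a21 = dth * g2;  // d z_pred / d theta_prev
    // P_pred = A P A' + Qu with A = [[1,0],[a21,1]]
    double q11 = p11 + q_theta;
    double q12 = a21 * p11 + p12;
    double q22 = a21 * a21 * p11 + 2.0 * a21 * p12 + p22 + q_z;
    // S = P_pred + R (H = I)
    double s11 = q11 + r_phi, s12 = q12, s22 = q22 + r_z;
    double det = s11 * s22 - s12 * s12;
    if (det <= 0 || !R_finite(det)) {
      stop("ecg_ekf_cpp: singular innovation covariance at sample %d", k + 1);
    }
    double i11 = s22 / det, i12 = -s12 / det, i22 = s11 / det;
    double k11 = q11 * i11 + q12 * i12, k12 = q11 * i12 + q12 * i22;
    double k21 = q12 * i11 + q22 * i12, k22 = q12 * i12 + q22 * i22;
    double e1 = wrappi(phi[k] - th_pred);
    double e2 = s[k] - z_pred;
    th = wrap2pi(th_pred + k11 * e1 + k12 * e2);
    z = z_pred + k21 * e1 + k22 * e2;
    // P = (I - K) P_pred, symmetrized
    double n11 = (1.0 - k11) * q11 - k12 * q12;
    double n12 = (1.0 - k11) * q12 - k12 * q22;
    double n21 = -k21 * q11 + (1.0 - k22) * q12;
    double n22 = -k21 * q12 + (1.0 - k22) * q22;
    p11 = n11;
    p12 = 0.5 * (n12 + n21);
    p22 = n22;
    th_hat[k] = th;
    z_hat[k] = z;
  }
  return List::create(_["theta_hat"] = th_hat, _["z_hat"] = z_hat);
}

// [[Rcpp::export]]
List ecg_enkf_cpp(NumericVector phi, NumericVector s, NumericVector omega,
                  double delta, NumericVector alpha, NumericVector b,
                  NumericVector thw, double q_theta, double q_z,
                  double r_phi, double r_z, int n_ens, double theta0,
                  double z0, bool perturb_literal) {
  int n = phi.size();
  if (n_ens < 2) stop("ecg_enkf_cpp: need at least 2 ensemble members");
  NumericVector th_hat(n), z_hat(n);
  std::vector<double> th(n_ens), z(n_ens);
  double sd_qt = std::sqrt(q_theta), sd_qz = std::sqrt(q_z);
  double sd_rp = std::sqrt(r_phi), sd_rz = std::sqrt(r_z);
  const double* al = alpha.begin();
  const double* bb = b.begin();
  const double* tw = thw.begin();
  // members initialized Gaussian around the first observation with Qw spread
  for (int i = 0; i < n_ens; ++i) {
    th[i] = wrap2pi(theta0 + R::norm_rand() * sd_rp);
    z[i] = z0 + R::norm_rand() * sd_rz;
  }
  for (int k = 0; k < n; ++k) {
    double dth = omega[k] * delta;
    double cs = 0.0, sn = 0.0, mz = 0.0;
    for (int i = 0; i < n_ens; ++i) {
      double tp = wrap2pi(th[i] + dth + R::norm_rand() * sd_qt);
      double g1, g2;
      gsum_d1_d2(tp, al, bb, tw, &g1, &g2);
      th[i] = tp;
      z[i] = z[i] + dth * g1 + R::norm_rand() * sd_qz;
      cs += std::cos(tp);
      sn += std::sin(tp);
      mz += z[i];
    }
    mz /= n_ens;
    double mth = wrap2pi(std::atan2(sn, cs));  // circular mean of phases
    // sample covariances of (theta, z); phase deviations wrapped around the
    // circular mean; h is the identity so Pxy = Pyy = P
    double p11 = 0.0, p12 = 0.0, p22 = 0.0;
    for (int i = 0; i < n_ens; ++i) {
      double dt = wrappi(th[i] - mth);
      double dz = z[i] - mz;
      p11 += dt * dt;
      p12 += dt * dz;
      p22 += dz * dz;
    }
    p11 /= n_ens; p12 /= n_ens; p22 /= n_ens;  // 1/N normalization
    double eps = 1e-8 * (p11 + p22) / 2.0;
    double s11 = p11 + r_phi + eps, s12 = p12, s22 = p22 + r_z + eps;
    double det = s11 * s22 - s12 * s12;
    if (det <= 0 || !R_finite(det)) {
      stop("ecg_enkf_cpp: singular innovation covariance at sample %d", k + 1);
    }
    double i11 = s22 / det, i12 = -s12 / det, i22 = s11 / det;
    double k11 = p11 * i11 + p12 * i12, k12 = p11 * i12 + p12 * i22;
    double k21 = p12 * i11 + p22 * i12, k22 = p12 * i12 + p22 * i22;
    cs = 0.0; sn = 0.0; mz = 0.0;
    for (int i = 0; i < n_ens; ++i) {
      double vp = R::norm_rand() * sd_rp;
      double vz = R::norm_rand() * sd_rz;
      // literal variant: perturbations centred on the ensemble obs mean
      if (perturb_literal) { vp += mth; vz += mz; }
      // perturbed-observation innovation, phase part wrapped
      double e1 = wrappi(phi[k] + vp - th[i]);
      double e2 = s[k] + vz - z[i];
      double tn = wrap2pi(th[i] + k11 * e1 + k12 * e2);
      double zn = z[i] + k21 * e1 + k22 * e2;
      if (!R_finite(tn) || !R_finite(zn)) {
        stop("ecg_enkf_cpp: non-finite member %d after update at sample %d",
             i + 1, k + 1);
      }
      th[i] = tn;
      z[i] = zn;
      cs += std::cos(tn);
      sn += std::sin(tn);
      mz += zn;
    }
    th_hat[k] = wrap2pi(std::atan2(sn, cs));
    z_hat[k] = mz / n_ens;
  }
  return List::create(_["theta_hat"] = th_hat, _["z_hat"] = z_hat);
}
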