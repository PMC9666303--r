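#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Transfer functions: 0 = linear, 1 = rectified, 2 = bi-sigmoid.
static inline double transfer_eval(double h, int kind, double sm, double sp) {
  switch (kind) {
  case 0: return h;
  case 1: return h > 0.0 ? h : 0.0;
  default: return h < 0.0 ? sm * std::tanh(h / sm) : sp * std::tanh(h / sp);
  }
}

// Euler integration of BCM / weight-dependent BCM learning.
//
// One stimulus presentation lasts one time unit and is integrated with
// m = 1/dt Euler substeps; a single Gaussian noise draw per presentation is
// added to the activity (matching the R reference steppers, which use R's
// RNG in the same order).  Per substep the threshold is updated first with
// the noisy activity, then the weights with the same activity and the
// updated threshold.
//
// rule: 0 standard, 1 weight-dependent.  theta_mode: 0 online, 1 mean-field.
// For the weight-dependent depression branch the excitatory weight v = w + u
// is scaled multiplicatively; the factor is clamped at 0 so v cannot cross
// zero within a single substep (clamp events are counted in guard_trips).
// [[Rcpp::export]]
List cpp_bcm_run(NumericMatrix X, IntegerVector pres_order, NumericVector w0,
                 double theta0, int rule, double u, double tau_w,
                 double tau_theta, double sigma_y, double dt, int transfer,
                 double sigma_minus, double sigma_plus, int theta_mode,
                 int n_pres, int record_every, double conv_tol, double w_cap) {
  const int K = X.nrow(), N = X.ncol();
  const int m = (int)std::lround(1.0 / dt);
  const double dt_w = dt / tau_w, dt_t = dt / tau_theta;
  const double sig2 = sigma_y * sigma_y;

  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> w_epoch(N);
  double theta = theta0;
  long guard_trips = 0;
  bool converged = false;
  int done = 0;
  // time average of theta over the most recently completed epoch (the
  // online threshold oscillates within the presentation cycle, so the
  // instantaneous value is phase-dependent)
  double theta_accum = 0.0, theta_epoch_mean = theta0;

  const int ns_max = (record_every > 0 ? n_pres / record_every : 0) + 2;
  std::vector<double> rec_t, rec_theta, rec_w, rec_y;
  rec_t.reserve(ns_max);
  rec_theta.reserve(ns_max);
  rec_w.reserve((size_t)ns_max * N);
  rec_y.reserve((size_t)ns_max * K);

  for (int p = 0; p < n_pres; ++p) {
    const int k = pres_order[p % K];
    if (p % K == 0)
      for (int i = 0; i < N; ++i) w_epoch[i] = w[i];

    const double nu = (sigma_y > 0.0) ? R::rnorm(0.0, sigma_y) : 0.0;

    for (int s = 0; s < m; ++s) {
      double h = 0.0;
      for (int i = 0; i < N; ++i) h += w[i] * X(k, i);
      const double y = transfer_eval(h, transfer, sigma_minus, sigma_plus);
      const double yt = y + nu;

      if (theta_mode == 0) {
        theta += dt_t * (yt * yt - theta);
      } else {
        double s2 = 0.0;
        for (int kk = 0; kk < K; ++kk) {
          double hk = 0.0;
          for (int i = 0; i < N; ++i) hk += w[i] * X(kk, i);
          const double yk = transfer_eval(hk, transfer, sigma_minus, sigma_plus);
          s2 += yk * yk;
        }
        theta = s2 / K + sig2;
      }

      theta_accum += theta;
      const double F = yt * (yt - theta);
      if (rule == 1 && F < 0.0) {
        for (int i = 0; i < N; ++i) {
          double fac = 1.0 + dt_w * X(k, i) * F;
          if (fac < 0.0) { fac = 0.0; ++guard_trips; }
          w[i] = (w[i] + u) * fac - u;
        }
      } else {
        for (int i = 0; i < N; ++i) w[i] += dt_w * X(k, i) * F;
      }
    }

    double w_max = 0.0;
    bool finite = std::isfinite(theta);
    for (int i = 0; i < N; ++i) {
      const double a = std::fabs(w[i]);
      if (a > w_max) w_max = a;
      if (!std::isfinite(w[i])) finite = false;
    }
    if (!finite || w_max > w_cap)
      stop("weight dynamics diverged at presentation %d (max|w| = %g, "
           "tau_theta = %g, tau_w = %g, u = %g): unstable parameter regime",
           p + 1, w_max, tau_theta, tau_w, u);

    done = p + 1;
    if (done % K == 0) {
      theta_epoch_mean = theta_accum / ((double)K * m);
      theta_accum = 0.0;
    }
    if (record_every > 0 && done % record_every == 0) {
      rec_t.push_back((double)done);
      rec_theta.push_back(theta);
      for (int i = 0; i < N; ++i) rec_w.push_back(w[i]);
      for (int kk = 0; kk < K; ++kk) {
        double hk = 0.0;
        for (int i = 0; i < N; ++i) hk += w[i] * X(kk, i);
        rec_y.push_back(transfer_eval(hk, transfer, sigma_minus, sigma_plus));
      }
    }

    if (sigma_y == 0.0 && conv_tol > 0.0 && done % K == 0) {
      double d_max = 0.0;
      for (int i = 0; i < N; ++i) {
        const double d = std::fabs(w[i] - w_epoch[i]);
        if (d > d_max) d_max = d;
      }
      if (d_max < conv_tol * (1.0 + w_max)) { converged = true; break; }
    }
  }

  const int ns = (int)rec_t.size();
  NumericMatrix rw(ns, N), ry(ns, K);
  for (int s = 0; s < ns; ++s) {
    for (int i = 0; i < N; ++i) rw(s, i) = rec_w[(size_t)s * N + i];
    for (int kk = 0; kk < K; ++kk) ry(s, kk) = rec_y[(size_t)s * K + kk];
  }

  return List::create(
      _["w"] = NumericVector(w.begin(), w.end()), _["theta"] = theta,
      _["converged"] = converged, _["n_done"] = done,
      _["theta_epoch_mean"] = theta_epoch_mean,
      _["guard_trips"] = (double)guard_trips,
      _["rec_t"] = NumericVector(rec_t.begin(), rec_t.end()),
      _["rec_theta"] = NumericVector(rec_theta.begin(), rec_theta.end()),
      _["rec_w"] = rw, _["rec_y"] = ry);
}
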