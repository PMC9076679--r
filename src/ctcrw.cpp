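#include <Rcpp.h>
using namespace Rcpp;

// Scalar-observation Kalman filter for the 2-state (position, velocity)
// CTCRW, run independently over the two planar axes.  Transition and
// process-noise entries are precomputed in R (transition_moments) so the
// discretization lives in one place.
static double kalman_axis(const NumericVector& y, const NumericVector& r2,
                          const NumericVector& fxv, const NumericVector& fvv,
                          const NumericVector& qxx, const NumericVector& qxv,
                          const NumericVector& qvv,
                          double p0, double v0var) {
  const int n = y.size();
  double mx = y[0], mv = 0.0;
  double Pxx = p0, Pxv = 0.0, Pvv = v0var;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      const double a = fxv[i - 1], e = fvv[i - 1];
      const double nmx = mx + a * mv;
      const double nmv = e * mv;
      const double nPxx = Pxx + 2.0 * a * Pxv + a * a * Pvv + qxx[i - 1];
      const double nPxv = e * (Pxv + a * Pvv) + qxv[i - 1];
      const double nPvv = e * e * Pvv + qvv[i - 1];
      mx = nmx; mv = nmv; Pxx = nPxx; Pxv = nPxv; Pvv = nPvv;
    }
    const double S = Pxx + r2[i];
    if (!(S > 0.0)) return R_NegInf;
    const double innov = y[i] - mx;
    ll -= 0.5 * (std::log(2.0 * M_PI * S) + innov * innov / S);
    const double Kx = Pxx / S, Kv = Pxv / S;
    mx += Kx * innov;
    mv += Kv * innov;
    const double oPxx = Pxx, oPxv = Pxv;
    Pxx = oPxx - Kx * oPxx;
    Pxv = oPxv - Kx * oPxv;
    Pvv = Pvv - Kv * oPxv;
  }
  return ll;
}

// [[Rcpp::export]]
double ctcrw_kalman_cpp(NumericVector y1, NumericVector y2,
                        NumericVector r2x, NumericVector r2y,
                        NumericVector fxv, NumericVector fvv,
                        NumericVector qxx, NumericVector qxv,
                        NumericVector qvv,
                        double init_pos_var, double v0var) {
  return kalman_axis(y1, r2x, fxv, fvv, qxx, qxv, qvv, init_pos_var, v0var) +
         kalman_axis(y2, r2y, fxv, fvv, qxx, qxv, qvv, init_pos_var, v0var);
}

// Euler-Maruyama integration of the OU velocity / integrated position pair;
// an independent brute-force oracle for the exact transition moments.
// [[Rcpp::export]]
NumericMatrix ou_em_cpp(double beta, double sigma, double delta, double v0,
                        double dt, int nrep) {
  const int nstep = (int)std::ceil(delta / dt);
  const double sq = sigma * std::sqrt(dt);
  NumericMatrix out(nrep, 2);
  RNGScope scope;
  for (int r = 0; r < nrep; ++r) {
    double x = 0.0, v = v0;
    double t = 0.0;
    for (int s = 0; s < nstep; ++s) {
      const double h = std::min(dt, delta - t);
      x += v * h;
      v += -beta * v * h + (h == dt ? sq : sigma * std::sqrt(h)) * norm_rand();
      t += h;
    }
    out(r, 0) = x;
    out(r, 1) = v;
  }
  return out;
}
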