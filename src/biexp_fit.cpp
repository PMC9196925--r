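#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

//' Truncated discrete linear convolution
//'
//' `out[t] = sum_{k=0..t} a[k] * b[t-k]`: the discrete convolution of two
//' sequences on the acquisition time base, truncated to the finite
//' acquisition window (both inputs and the output share one length).
//' Multiplied by the sample spacing this approximates the continuous
//' convolution of an IRF with a fluorescence impulse response.
//'
//' @param a,b Numeric vectors of equal length.
//' @return Numeric vector of the same length.
//' @export
// [[Rcpp::export]]
NumericVector conv_trunc(NumericVector a, NumericVector b) {
  int n = a.size();
  if (b.size() != n) stop("conv_trunc: inputs must have equal length");
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    double s = 0.0;
    for (int k = 0; k <= t; ++k) s += a[k] * b[t - k];
    out[t] = s;
  }
  return out;
}

namespace {

struct FitWork {
  const double *irf;
  const double *y;
  int n;
  double dt;
  double yty;
  std::vector<double> h, c;
};

// Model curve for parameters (alpha, tau_f, tau_s): c = dt * (irf (*) h),
// h[t] = alpha * rf^t + (1 - alpha) * rs^t with rf = exp(-dt/tau_f).
// The linear amplitude s is profiled out (variable projection):
// s = <y, c> / <c, c>.  Returns the residual sum of squares; stores s.
double sse_at(FitWork &w, double alpha, double tf, double ts, double &s_out) {
  const int n = w.n;
  double rf = std::exp(-w.dt / tf), rs = std::exp(-w.dt / ts);
  double pf = 1.0, ps = 1.0;
  for (int t = 0; t < n; ++t) {
    w.h[t] = alpha * pf + (1.0 - alpha) * ps;
    pf *= rf;
    ps *= rs;
  }
  // truncated convolution with the IRF
  for (int t = 0; t < n; ++t) {
    double acc = 0.0;
    for (int k = 0; k <= t; ++k) acc += w.irf[k] * w.h[t - k];
    w.c[t] = acc * w.dt;
  }
  double cc = 0.0, yc = 0.0;
  for (int t = 0; t < n; ++t) {
    cc += w.c[t] * w.c[t];
    yc += w.y[t] * w.c[t];
  }
  double s = (cc > 0.0) ? yc / cc : 0.0;
  s_out = s;
  return w.yty - 2.0 * s * yc + s * s * cc;
}

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Unconstrained parameterisation: alpha = logistic(th0), tau_f = exp(th1),
// tau_s = tau_f + exp(th2); guarantees alpha in [0,1] and tau_f <= tau_s.
void decode(const double *th, int n_exp, double &alpha, double &tf, double &ts) {
  if (n_exp == 1) {
    alpha = 1.0;
    tf = std::exp(clampd(th[0], -7.0, 7.0));
    ts = tf;
  } else {
    alpha = 1.0 / (1.0 + std::exp(-clampd(th[0], -30.0, 30.0)));
    tf = std::exp(clampd(th[1], -7.0, 7.0));
    ts = tf + std::exp(clampd(th[2], -9.0, 7.0));
  }
}

double sse_theta(FitWork &w, const double *th, int n_exp, double &s_out) {
  double alpha, tf, ts;
  decode(th, n_exp, alpha, tf, ts);
  return sse_at(w, alpha, tf, ts, s_out);
}

// Solve the (np x np, np <= 3) damped normal equations by Gaussian
// elimination with partial pivoting; returns false if singular.
bool solve_small(double A[3][3], double b[3], double x[3], int np) {
  int piv[3] = {0, 1, 2};
  for (int col = 0; col < np; ++col) {
    int best = col;
    for (int r = col + 1; r < np; ++r)
      if (std::fabs(A[piv[r]][col]) > std::fabs(A[piv[best]][col])) best = r;
    std::swap(piv[col], piv[best]);
    double p = A[piv[col]][col];
    if (std::fabs(p) < 1e-300) return false;
    for (int r = col + 1; r < np; ++r) {
      double f = A[piv[r]][col] / p;
      for (int c2 = col; c2 < np; ++c2) A[piv[r]][c2] -= f * A[piv[col]][c2];
      b[piv[r]] -= f * b[piv[col]];
    }
  }
  for (int row = np - 1; row >= 0; --row) {
    double acc = b[piv[row]];
    for (int c2 = row + 1; c2 < np; ++c2) acc -= A[piv[row]][c2] * x[c2];
    x[row] = acc / A[piv[row]][row];
  }
  return true;
}

// Levenberg-Marquardt with forward-difference Jacobian of the profiled
// residual.  Convergence: relative change of the physical parameters below
// tol, or relative SSE improvement below 1e-12.
void fit_one(FitWork &w, const double *init, int n_exp, int max_iter,
             double tol, double *out /* alpha tf ts s mse conv iters */) {
  const int np = (n_exp == 1) ? 1 : 3;
  double th[3] = {0, 0, 0};
  if (n_exp == 1) {
    th[0] = std::log(init[1]);
  } else {
    th[0] = std::log(init[0] / (1.0 - init[0]));
    th[1] = std::log(init[1]);
    th[2] = std::log(std::max(init[2] - init[1], 1e-3));
  }
  const int n = w.n;
  double s = 0.0;
  double sse = sse_theta(w, th, n_exp, s);
  std::vector<double> r0(n), Jm(3 * n);
  double lambda = 1e-3;
  int it = 0;
  bool conv = false;
  for (it = 0; it < max_iter && !conv; ++it) {
    // residual at current point
    {
      double stmp;
      sse_theta(w, th, n_exp, stmp);
      for (int t = 0; t < n; ++t) r0[t] = w.y[t] - stmp * w.c[t];
    }
    // forward-difference Jacobian of the residual
    for (int j = 0; j < np; ++j) {
      double h = 1e-6 * (1.0 + std::fabs(th[j]));
      double thp[3] = {th[0], th[1], th[2]};
      thp[j] += h;
      double stmp;
      sse_theta(w, thp, n_exp, stmp);
      for (int t = 0; t < n; ++t)
        Jm[j * n + t] = ((w.y[t] - stmp * w.c[t]) - r0[t]) / h;
    }
    double JtJ[3][3] = {{0}}, Jtr[3] = {0};
    for (int a2 = 0; a2 < np; ++a2) {
      for (int b2 = a2; b2 < np; ++b2) {
        double acc = 0.0;
        for (int t = 0; t < n; ++t) acc += Jm[a2 * n + t] * Jm[b2 * n + t];
        JtJ[a2][b2] = JtJ[b2][a2] = acc;
      }
      double acc = 0.0;
      for (int t = 0; t < n; ++t) acc += Jm[a2 * n + t] * r0[t];
      Jtr[a2] = acc;
    }
    bool accepted = false;
    for (int tries = 0; tries < 12 && !accepted; ++tries) {
      double A[3][3], b[3], delta[3];
      for (int a2 = 0; a2 < np; ++a2) {
        for (int b2 = 0; b2 < np; ++b2) A[a2][b2] = JtJ[a2][b2];
        A[a2][a2] += lambda * (JtJ[a2][a2] > 0 ? JtJ[a2][a2] : 1.0);
        b[a2] = -Jtr[a2];
      }
      if (!solve_small(A, b, delta, np)) { lambda *= 10.0; continue; }
      double thn[3] = {th[0], th[1], th[2]};
      for (int j = 0; j < np; ++j) thn[j] += delta[j];
      double sn;
      double ssen = sse_theta(w, thn, n_exp, sn);
      if (ssen <= sse) {
        // relative change of the physical parameters
        double a_old, tf_old, ts_old, a_new, tf_new, ts_new;
        decode(th, n_exp, a_old, tf_old, ts_old);
        decode(thn, n_exp, a_new, tf_new, ts_new);
        double rel = std::fabs(a_new - a_old) / (std::fabs(a_old) + 1e-12);
        rel = std::max(rel, std::fabs(tf_new - tf_old) / (tf_old + 1e-12));
        rel = std::max(rel, std::fabs(ts_new - ts_old) / (ts_old + 1e-12));
        double impr = (sse - ssen) / (sse + 1e-300);
        for (int j = 0; j < np; ++j) th[j] = thn[j];
        s = sn;
        sse = ssen;
        lambda = std::max(lambda / 3.0, 1e-12);
        accepted = true;
        if (rel < tol || impr < 1e-12) conv = true;
      } else {
        lambda *= 10.0;
      }
    }
    if (!accepted) { conv = true; }  // stalled: no descent direction left
  }
  double alpha, tf, ts;
  decode(th, n_exp, alpha, tf, ts);
  // recompute the SSE from explicit residuals: the profiled identity
  // yty - 2s<y,c> + s^2<c,c> cancels catastrophically near perfect fits
  sse = sse_theta(w, th, n_exp, s);
  sse = 0.0;
  for (int t = 0; t < n; ++t) {
    double r = w.y[t] - s * w.c[t];
    sse += r * r;
  }
  out[0] = alpha;
  out[1] = tf;
  out[2] = ts;
  out[3] = s;
  out[4] = sse / n;
  out[5] = conv ? 1.0 : 0.0;
  out[6] = it;
}

}  // namespace

// Fit the reconvolution decay model to each column of Y (time x pixels).
// init = (alpha_fast, tau_fast, tau_slow) starting point; n_exp = 1 fits a
// monoexponential (alpha fixed at 1).  Returns a 7 x npix matrix with rows
// alpha_fast, tau_fast, tau_slow, scale, mse, converged, iterations.
// [[Rcpp::export]]
NumericMatrix fit_biexp_cpp(NumericMatrix Y, NumericVector irf, double dt,
                            NumericVector init, int max_iter, double tol,
                            int n_exp) {
  int n = Y.nrow(), npix = Y.ncol();
  if (irf.size() != n) stop("decay and IRF must share the time base");
  if (n_exp != 1 && n_exp != 2) stop("n_exp must be 1 or 2");
  NumericMatrix out(7, npix);
  FitWork w;
  w.irf = REAL(irf);
  w.n = n;
  w.dt = dt;
  w.h.resize(n);
  w.c.resize(n);
  double ini[3] = {init[0], init[1], init[2]};
  for (int p = 0; p < npix; ++p) {
    w.y = &Y(0, p);
    double yty = 0.0;
    for (int t = 0; t < n; ++t) yty += w.y[t] * w.y[t];
    w.yty = yty;
    fit_one(w, ini, n_exp, max_iter, tol, &out(0, p));
  }
  return out;
}
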