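#include <Rcpp.h>
using namespace Rcpp;

// Gaussian KDE machinery for the miFC estimator.
//
// Marginal and joint densities share the same per-dimension bandwidth
// h (in SD units of each variable); the joint kernel carries the sample
// covariance of (x, y) so that correlated clouds are smoothed along their
// principal axes. Entropies are evaluated by leave-one-out resubstitution:
// the self-term otherwise inflates the joint density more than the
// marginals and biases MI upward.

static const double LOG_2PI = 1.8378770664093454836;

// sample covariance entries of (x, y), ridge-regularised when (near-)singular
static void cov2(const NumericVector &x, const NumericVector &y,
                 double &sxx, double &syy, double &sxy) {
  int n = x.size();
  double mx = mean(x), my = mean(y);
  sxx = 0; syy = 0; sxy = 0;
  for (int i = 0; i < n; i++) {
    sxx += (x[i] - mx) * (x[i] - mx);
    syy += (y[i] - my) * (y[i] - my);
    sxy += (x[i] - mx) * (y[i] - my);
  }
  sxx /= (n - 1); syy /= (n - 1); sxy /= (n - 1);
  double det = sxx * syy - sxy * sxy;
  if (det < 1e-10 * sxx * syy) {
    double eps = 1e-8 * (sxx + syy);
    sxx += eps; syy += eps;
  }
}

// [[Rcpp::export]]
NumericVector cpp_kde1d(NumericVector samples, NumericVector query, double h) {
  int n = samples.size(), m = query.size();
  double sd = Rcpp::sd(samples);
  if (sd <= 0) stop("degenerate (constant) input signal");
  double bw = h * sd;
  double c = 1.0 / (std::sqrt(2.0 * M_PI) * bw * n);
  NumericVector out(m);
  for (int i = 0; i < m; i++) {
    double acc = 0;
    for (int j = 0; j < n; j++) {
      double d = (query[i] - samples[j]) / bw;
      acc += std::exp(-0.5 * d * d);
    }
    out[i] = c * acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_kde2d(NumericVector x, NumericVector y,
                        NumericVector qx, NumericVector qy, double h) {
  int n = x.size(), m = qx.size();
  double sxx, syy, sxy;
  cov2(x, y, sxx, syy, sxy);
  double det = sxx * syy - sxy * sxy;
  if (det <= 0) stop("degenerate joint covariance");
  double i11 = syy / det, i22 = sxx / det, i12 = -sxy / det;
  double c = 1.0 / (2.0 * M_PI * h * h * std::sqrt(det) * n);
  NumericVector out(m);
  for (int i = 0; i < m; i++) {
    double acc = 0;
    for (int j = 0; j < n; j++) {
      double dx = qx[i] - x[j], dy = qy[i] - y[j];
      double q = dx * dx * i11 + 2.0 * dx * dy * i12 + dy * dy * i22;
      acc += std::exp(-0.5 * q / (h * h));
    }
    out[i] = c * acc;
  }
  return out;
}

// online log-sum-exp accumulator: returns log(sum exp(e_j)) without underflow
struct LogSum {
  double m, s;
  LogSum() : m(R_NegInf), s(0) {}
  void add(double e) {
    if (e <= m) { s += std::exp(e - m); }
    else { s = s * std::exp(m - e) + 1.0; m = e; }
  }
  double value() const { return m + std::log(s); }
};

// leave-one-out marginal entropy, nats
// [[Rcpp::export]]
double cpp_loo_entropy1d(NumericVector x, double h) {
  int n = x.size();
  double sd = Rcpp::sd(x);
  if (sd <= 0) stop("degenerate (constant) input signal");
  double bw = h * sd;
  double lc = -0.5 * LOG_2PI - std::log(bw) - std::log((double)(n - 1));
  double H = 0;
  for (int i = 0; i < n; i++) {
    LogSum ls;
    for (int j = 0; j < n; j++) {
      if (j == i) continue;
      double d = (x[i] - x[j]) / bw;
      ls.add(-0.5 * d * d);
    }
    H -= lc + ls.value();
  }
  return H / n;
}

// leave-one-out joint entropy with covariance-shaped kernel, nats
// [[Rcpp::export]]
double cpp_loo_entropy2d(NumericVector x, NumericVector y, double h) {
  int n = x.size();
  double sxx, syy, sxy;
  cov2(x, y, sxx, syy, sxy);
  double det = sxx * syy - sxy * sxy;
  if (det <= 0) stop("degenerate joint covariance");
  double i11 = syy / det, i22 = sxx / det, i12 = -sxy / det;
  double lc = -LOG_2PI - 2.0 * std::log(h) - 0.5 * std::log(det)
              - std::log((double)(n - 1));
  double H = 0;
  for (int i = 0; i < n; i++) {
    LogSum ls;
    for (int j = 0; j < n; j++) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double q = dx * dx * i11 + 2.0 * dx * dy * i12 + dy * dy * i22;
      ls.add(-0.5 * q / (h * h));
    }
    H -= lc + ls.value();
  }
  return H / n;
}

// full pairwise MI entropy table for a volumes x regions matrix:
// returns marginal entropies (per region) and joint entropies (per pair)
// [[Rcpp::export]]
List cpp_mifc_entropies(NumericMatrix series, double h) {
  int p = series.ncol();
  NumericVector H(p);
  NumericMatrix Hxy(p, p);
  for (int r = 0; r < p; r++)
    H[r] = cpp_loo_entropy1d(series(_, r), h);
  for (int a = 0; a < p; a++) {
    Hxy(a, a) = NA_REAL;
    for (int b = a + 1; b < p; b++) {
      double v = cpp_loo_entropy2d(series(_, a), series(_, b), h);
      Hxy(a, b) = v;
      Hxy(b, a) = v;
    }
  }
  return List::create(_["H"] = H, _["Hxy"] = Hxy);
}
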