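// Bivariate Gaussian mixture fitting for pairwise gene expression.
// EM with k-means++ initialisation, multiple restarts, BIC model selection
// over K = 1..maxK. Uses R's RNG so results are reproducible under
// set.seed(). Dimension is fixed at 2 (one gene pair).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

namespace {

struct Model {
  int K = 0;
  std::vector<double> w;              // K weights
  std::vector<double> mx, my;         // K means
  std::vector<double> sxx, sxy, syy;  // K covariances
  double loglik = -std::numeric_limits<double>::infinity();
  bool ok = false;
};

// log density of N((mx,my), [[sxx,sxy],[sxy,syy]]) at (x, y)
inline double ldnorm2(double x, double y, double mx, double my, double sxx,
                      double sxy, double syy) {
  double det = sxx * syy - sxy * sxy;
  if (det <= 0.0) return -std::numeric_limits<double>::infinity();
  double dx = x - mx, dy = y - my;
  double q = (syy * dx * dx - 2.0 * sxy * dx * dy + sxx * dy * dy) / det;
  return -std::log(2.0 * M_PI) - 0.5 * std::log(det) - 0.5 * q;
}

// k-means++ seeding over the n points; returns K center indices
std::vector<int> kppSeed(const NumericVector& x, const NumericVector& y,
                         int K) {
  int n = x.size();
  std::vector<int> centers;
  centers.push_back(static_cast<int>(std::floor(unif_rand() * n)) % n);
  std::vector<double> d2(n);
  for (int k = 1; k < K; ++k) {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      double best = std::numeric_limits<double>::infinity();
      for (int c : centers) {
        double dx = x[i] - x[c], dy = y[i] - y[c];
        double d = dx * dx + dy * dy;
        if (d < best) best = d;
      }
      d2[i] = best;
      tot += best;
    }
    int pick = 0;
    if (tot > 0.0) {
      double u = unif_rand() * tot, acc = 0.0;
      for (int i = 0; i < n; ++i) {
        acc += d2[i];
        if (u <= acc) { pick = i; break; }
      }
    } else {
      pick = static_cast<int>(std::floor(unif_rand() * n)) % n;
    }
    centers.push_back(pick);
  }
  return centers;
}

Model emFit(const NumericVector& x, const NumericVector& y, int K,
            double tol, int maxIter, double ridge) {
  int n = x.size();
  Model m;
  m.K = K;
  m.w.assign(K, 1.0 / K);
  m.mx.resize(K); m.my.resize(K);
  m.sxx.assign(K, 0.0); m.sxy.assign(K, 0.0); m.syy.assign(K, 0.0);

  // overall covariance: initial spread and ridge scale
  double gmx = mean(x), gmy = mean(y), vxx = 0, vyy = 0;
  for (int i = 0; i < n; ++i) {
    vxx += (x[i] - gmx) * (x[i] - gmx);
    vyy += (y[i] - gmy) * (y[i] - gmy);
  }
  vxx = vxx / std::max(n - 1, 1); vyy = vyy / std::max(n - 1, 1);
  double eps = ridge * 0.5 * (vxx + vyy) + 1e-12;

  std::vector<int> seed = kppSeed(x, y, K);
  for (int k = 0; k < K; ++k) {
    m.mx[k] = x[seed[k]];
    m.my[k] = y[seed[k]];
    m.sxx[k] = vxx + eps; m.syy[k] = vyy + eps; m.sxy[k] = 0.0;
  }

  std::vector<double> resp(static_cast<size_t>(n) * K);
  std::vector<double> lw(K), lc(K), ixx(K), ixy(K), iyy(K);
  double ll_prev = -std::numeric_limits<double>::infinity();
  for (int it = 0; it < maxIter; ++it) {
    // E step: per-component constants hoisted out of the point loop
    bool degen = false;
    for (int k = 0; k < K; ++k) {
      double det = m.sxx[k] * m.syy[k] - m.sxy[k] * m.sxy[k];
      if (det <= 0.0 || m.w[k] <= 0.0) { degen = true; break; }
      lw[k] = std::log(m.w[k]);
      lc[k] = -std::log(2.0 * M_PI) - 0.5 * std::log(det);
      ixx[k] = m.syy[k] / det;
      iyy[k] = m.sxx[k] / det;
      ixy[k] = -m.sxy[k] / det;
    }
    if (degen) return m;  // ok stays false
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx_ = -std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        double dx = x[i] - m.mx[k], dy = y[i] - m.my[k];
        double q = ixx[k] * dx * dx + 2.0 * ixy[k] * dx * dy +
          iyy[k] * dy * dy;
        double l = lw[k] + lc[k] - 0.5 * q;
        resp[static_cast<size_t>(i) * K + k] = l;
        if (l > mx_) mx_ = l;
      }
      if (!std::isfinite(mx_)) return m;  // degenerate; ok stays false
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        s += std::exp(resp[static_cast<size_t>(i) * K + k] - mx_);
      ll += mx_ + std::log(s);
      for (int k = 0; k < K; ++k)
        resp[static_cast<size_t>(i) * K + k] =
          std::exp(resp[static_cast<size_t>(i) * K + k] - mx_) / s;
    }
    // M step
    for (int k = 0; k < K; ++k) {
      double nk = 0, sx = 0, sy = 0;
      for (int i = 0; i < n; ++i) {
        double r = resp[static_cast<size_t>(i) * K + k];
        nk += r; sx += r * x[i]; sy += r * y[i];
      }
      if (nk < 1e-8) { nk = 1e-8; }
      double mx_ = sx / nk, my_ = sy / nk;
      double cxx = 0, cxy = 0, cyy = 0;
      for (int i = 0; i < n; ++i) {
        double r = resp[static_cast<size_t>(i) * K + k];
        double dx = x[i] - mx_, dy = y[i] - my_;
        cxx += r * dx * dx; cxy += r * dx * dy; cyy += r * dy * dy;
      }
      m.w[k] = nk / n;
      m.mx[k] = mx_; m.my[k] = my_;
      m.sxx[k] = cxx / nk + eps;
      m.syy[k] = cyy / nk + eps;
      m.sxy[k] = cxy / nk;
      // keep the covariance positive definite
      double det = m.sxx[k] * m.syy[k] - m.sxy[k] * m.sxy[k];
      if (det <= 0.0) {
        double lim = 0.999 * std::sqrt(m.sxx[k] * m.syy[k]);
        m.sxy[k] = (m.sxy[k] > 0 ? lim : -lim);
      }
    }
    m.loglik = ll;
    if (std::fabs(ll - ll_prev) < tol * (1.0 + std::fabs(ll))) break;
    ll_prev = ll;
  }
  m.ok = std::isfinite(m.loglik);
  return m;
}

} // namespace

// [[Rcpp::export(name = ".cpp_fit_pair_gmm")]]
List cpp_fit_pair_gmm(NumericVector x, NumericVector y, int maxK,
                      int nRestarts, double tol, int maxIter, double ridge,
                      bool earlyStop) {
  int n = x.size();
  if (n != y.size()) stop("x and y lengths differ");
  if (n < 2) stop("need at least 2 points");
  RNGScope scope;

  NumericVector bic(maxK, NA_REAL);
  Model best;
  int bestK = 1;
  double bestBIC = std::numeric_limits<double>::infinity();

  for (int K = 1; K <= maxK; ++K) {
    Model bm;
    int rr = (K == 1) ? 1 : nRestarts;  // K=1 has a closed-form fit
    for (int r = 0; r < rr; ++r) {
      Model m = emFit(x, y, K, tol, maxIter, ridge);
      if (m.ok && m.loglik > bm.loglik) { bm = m; bm.ok = true; }
    }
    if (!bm.ok) continue;
    int npar = (K - 1) + 2 * K + 3 * K;
    double b = -2.0 * bm.loglik + npar * std::log(static_cast<double>(n));
    bic[K - 1] = b;
    if (b < bestBIC - 1e-9) { bestBIC = b; best = bm; bestK = K; }
    // stepwise search: once BIC deteriorates, larger K will not be selected
    if (earlyStop && K > 1 && !NumericVector::is_na(bic[K - 2]) &&
        b > bic[K - 2]) break;
  }
  if (!best.ok) stop("GMM fit failed for all K");

  // responsibilities and hard assignment under the selected model
  NumericMatrix resp(n, bestK);
  IntegerVector assign(n);
  for (int i = 0; i < n; ++i) {
    double mx_ = -std::numeric_limits<double>::infinity();
    std::vector<double> l(bestK);
    for (int k = 0; k < bestK; ++k) {
      l[k] = std::log(best.w[k]) +
        ldnorm2(x[i], y[i], best.mx[k], best.my[k], best.sxx[k], best.sxy[k],
                best.syy[k]);
      if (l[k] > mx_) mx_ = l[k];
    }
    double s = 0.0;
    for (int k = 0; k < bestK; ++k) s += std::exp(l[k] - mx_);
    int arg = 0;
    for (int k = 0; k < bestK; ++k) {
      resp(i, k) = std::exp(l[k] - mx_) / s;
      if (resp(i, k) > resp(i, arg)) arg = k;
    }
    assign[i] = arg + 1;
  }

  NumericMatrix means(bestK, 2);
  List covs(bestK);
  for (int k = 0; k < bestK; ++k) {
    means(k, 0) = best.mx[k];
    means(k, 1) = best.my[k];
    NumericMatrix S(2, 2);
    S(0, 0) = best.sxx[k]; S(1, 1) = best.syy[k];
    S(0, 1) = S(1, 0) = best.sxy[k];
    covs[k] = S;
  }
  NumericVector w(best.w.begin(), best.w.end());
  return List::create(_["K"] = bestK, _["bic"] = bic,
                      _["loglik"] = best.loglik, _["weights"] = w,
                      _["means"] = means, _["covariances"] = covs,
                      _["assignment"] = assign,
                      _["responsibilities"] = resp);
}
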