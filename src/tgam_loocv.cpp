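#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Leave-one-out loop for the threshold GAM: for every held-out observation,
// re-select the SST threshold and the two smoothing parameters by GCV on the
// remaining observations (rank-one downdates of X'X and X'y), then predict
// the held-out recruitment. Returns the prediction and the index of the
// threshold chosen in each fold (0 = fold failed).

// [[Rcpp::export]]
List tgam_loocv_cpp(List Xs, arma::vec y, List P1s, List P2s,
                    IntegerMatrix below, arma::vec lambda,
                    int min_per_regime) {
  const int n = y.n_elem;
  const int T = Xs.size();
  const int L = lambda.n_elem;
  std::vector<arma::mat> X(T), XtX(T), P1(T), P2(T);
  std::vector<arma::vec> Xty(T);
  std::vector<int> nbelow(T);
  for (int t = 0; t < T; ++t) {
    X[t] = as<arma::mat>(Xs[t]);
    XtX[t] = X[t].t() * X[t];
    Xty[t] = X[t].t() * y;
    P1[t] = as<arma::mat>(P1s[t]);
    P2[t] = as<arma::mat>(P2s[t]);
    int nb = 0;
    for (int i = 0; i < n; ++i) nb += below(i, t);
    nbelow[t] = nb;
  }
  const double yy_all = arma::dot(y, y);
  arma::vec pred(n);
  pred.fill(NA_REAL);
  IntegerVector chosen(n, 0);

  for (int i = 0; i < n; ++i) {
    double best_gcv = R_PosInf;
    double best_pred = NA_REAL;
    int best_t = 0;
    const double yy = yy_all - y[i] * y[i];
    const int m = n - 1;
    for (int t = 0; t < T; ++t) {
      int nb = nbelow[t] - below(i, t);
      int na = m - nb;
      if (nb < min_per_regime || na < min_per_regime) continue;
      arma::rowvec xi = X[t].row(i);
      arma::mat G = XtX[t] - xi.t() * xi;
      arma::vec h = Xty[t] - y[i] * xi.t();
      for (int a = 0; a < L; ++a) {
        for (int b = 0; b < L; ++b) {
          arma::mat K = G + lambda[a] * P1[t] + lambda[b] * P2[t];
          arma::mat Kinv;
          if (!arma::inv_sympd(Kinv, K)) continue;
          arma::vec beta = Kinv * h;
          double rss = yy - 2.0 * arma::dot(beta, h) +
                       arma::dot(beta, G * beta);
          if (rss < 0) rss = 0;
          double tr = arma::trace(Kinv * G);
          double denom = m - tr;
          if (denom < 1e-8) continue;
          double gcv = m * rss / (denom * denom);
          if (gcv < best_gcv) {
            best_gcv = gcv;
            best_pred = arma::dot(xi.t(), beta);
            best_t = t + 1;
          }
        }
      }
    }
    pred[i] = best_pred;
    chosen[i] = best_t;
  }
  return List::create(_["pred"] = NumericVector(pred.begin(), pred.end()),
                      _["threshold_index"] = chosen);
}
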