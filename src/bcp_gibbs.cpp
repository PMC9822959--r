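#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the Barry-Hartigan product-partition model with a change
// in mean. Each interior boundary indicator is resampled from its full
// conditional given all others; the conditional odds integrate the block-mean
// and noise parameters against uniform priors on (0, p0) for the boundary
// probability and (0, w0) for the variance ratio w. The w-integral is done by
// fixed-node Gauss-Legendre quadrature in log space.

static double log_ip(int c, int n, double p0) {
  // log of integral_0^p0 p^c (1-p)^(n-1-c) dp
  return R::lbeta(c + 1.0, n - (double)c) +
         R::pbeta(p0, c + 1.0, n - (double)c, 1, 1);
}

static double log_iw(int c, double W, double B, int n,
                     const NumericVector &nodes, const NumericVector &lw) {
  // log of integral_0^w0 w^(c/2) (W + B w)^(-(n-1)/2) dw
  const double half_c = 0.5 * c;
  const double expo = -0.5 * (n - 1.0);
  double m = R_NegInf;
  const int q = nodes.size();
  std::vector<double> lt(q);
  for (int j = 0; j < q; ++j) {
    double base = W + B * nodes[j];
    if (base < 1e-300) base = 1e-300;
    lt[j] = lw[j] + half_c * std::log(nodes[j]) + expo * std::log(base);
    if (lt[j] > m) m = lt[j];
  }
  double s = 0.0;
  for (int j = 0; j < q; ++j) s += std::exp(lt[j] - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
NumericVector bcp_gibbs_cpp(NumericVector x, double p0, double w0,
                            int iterations, int burnin,
                            NumericVector gl_nodes, NumericVector gl_weights) {
  const int n = x.size();
  const int nb = n - 1; // interior boundaries
  std::vector<int> rho(nb, 0);
  std::vector<double> cs(n + 1, 0.0);
  double ss2 = 0.0;
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    ss2 += x[i] * x[i];
  }
  const double grand = cs[n] * cs[n] / n; // n * xbar^2
  // log weights include the node weights (nodes already mapped to (0, w0))
  NumericVector lw(gl_weights.size());
  for (int j = 0; j < gl_weights.size(); ++j) lw[j] = std::log(gl_weights[j]);

  double S1 = grand; // sum over blocks of n_j * mean_j^2, all-merged start
  int n_active = 0;
  NumericVector counts(nb);
  RNGScope scope;

  for (int sweep = 0; sweep < iterations; ++sweep) {
    for (int i = 0; i < nb; ++i) {
      // block of observations spanning boundary i when it is inactive
      int s = i;
      while (s > 0 && rho[s - 1] == 0) --s;
      int e = i + 1;
      while (e < n - 1 && rho[e] == 0) ++e;
      // e is the last observation of the block (boundary e active or end)
      double sum_all = cs[e + 1] - cs[s];
      double m_merge = sum_all * sum_all / (e - s + 1);
      double sum_l = cs[i + 1] - cs[s];
      double sum_r = sum_all - sum_l;
      double m_split = sum_l * sum_l / (i - s + 1) + sum_r * sum_r / (e - i);
      double S1_base = S1 - (rho[i] ? m_split : m_merge);
      double S1_0 = S1_base + m_merge;
      double S1_1 = S1_base + m_split;
      int c_oth = n_active - rho[i];
      double W0 = ss2 - S1_0, B0 = S1_0 - grand;
      double W1 = ss2 - S1_1, B1 = S1_1 - grand;
      if (W0 < 0) W0 = 0;
      if (W1 < 0) W1 = 0;
      if (B0 < 0) B0 = 0;
      if (B1 < 0) B1 = 0;
      double lo = (log_ip(c_oth + 1, n, p0) - log_ip(c_oth, n, p0)) +
                  (log_iw(c_oth + 1, W1, B1, n, gl_nodes, lw) -
                   log_iw(c_oth, W0, B0, n, gl_nodes, lw));
      double pr1 = 1.0 / (1.0 + std::exp(-lo));
      int newv = (unif_rand() < pr1) ? 1 : 0;
      if (newv != rho[i]) {
        S1 = newv ? S1_1 : S1_0;
        n_active += newv ? 1 : -1;
        rho[i] = newv;
      } else {
        S1 = rho[i] ? S1_1 : S1_0;
      }
    }
    if (sweep >= burnin) {
      for (int i = 0; i < nb; ++i) counts[i] += rho[i];
    }
  }
  const double denom = iterations - burnin;
  for (int i = 0; i < nb; ++i) counts[i] /= denom;
  return counts;
}
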