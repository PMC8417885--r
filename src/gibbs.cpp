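#include <Rcpp.h>
using namespace Rcpp;

// Chinese-restaurant table draw: number of tables after x customers at
// concentration alpha, via the exact Bernoulli-sum representation
//   t = sum_{k=1..x} Bernoulli(alpha / (alpha + k - 1)).
// Marginal pmf is proportional to s(x, t) * alpha^t (unsigned Stirling
// numbers of the first kind).
static int crt_draw(int x, double alpha) {
  int t = 1; // first customer always opens a table
  for (int k = 2; k <= x; ++k) {
    if (unif_rand() < alpha / (alpha + (double)(k - 1))) ++t;
  }
  return t;
}

// [[Rcpp::export]]
IntegerVector crt_sample_cpp(IntegerVector x, NumericVector alpha) {
  int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (x[i] < 1) stop("CRT customer count must be >= 1");
    double a = alpha[i % alpha.size()];
    if (a < 0.0) stop("CRT concentration must be non-negative");
    out[i] = crt_draw(x[i], a);
  }
  return out;
}

// Escobar-West auxiliary-variable resampling of a Dirichlet-process
// concentration parameter under a Gamma(shape a, rate b) prior, given
// n customers seated at k tables.
static double resample_concentration(double alpha, int n, int k,
                                     double a, double b) {
  if (n < 1) return alpha;
  double eta = R::rbeta(alpha + 1.0, (double)n);
  double log_eta = (eta > 0.0) ? std::log(eta) : -700.0;
  double rate = b - log_eta;
  double odds = (a + (double)k - 1.0) / ((double)n * rate);
  double shape;
  if (unif_rand() < odds / (1.0 + odds)) {
    shape = a + (double)k;
  } else {
    shape = a + (double)k - 1.0;
  }
  if (shape <= 0.0) shape = a; // k = 0 cannot occur for observed data
  return R::rgamma(shape, 1.0 / rate);
}

// Four-step Gibbs sweep for the HDP approximation of the multi-site
// neutral model. counts is species x local-community. Updates per sweep:
//   (1) ancestral table counts t_ij ~ CRT(x_ij, I_i * beta_j)
//   (2) metacommunity (beta_1..beta_S, beta_u) ~ Dir(t_.1..t_.S, theta)
//   (3) theta  | total tables, occupied species  (Gamma prior)
//   (4) I_i    | N_i customers, t_i. tables      (Gamma prior)
// Returns post-burn-in chains for theta and I plus thinned parameter
// sets (theta, I, beta) for the posterior-predictive tests.
// [[Rcpp::export]]
List gibbs_msn_cpp(IntegerMatrix counts, int n_iter, int n_burn, int thin,
                   double prior_shape_theta, double prior_rate_theta,
                   double prior_shape_I, double prior_rate_I) {
  int S = counts.nrow(), T = counts.ncol();
  int n_post = n_iter - n_burn;
  int n_sets = n_post / thin;

  std::vector<double> N(T, 0.0);
  for (int i = 0; i < T; ++i) {
    for (int j = 0; j < S; ++j) N[i] += counts(j, i);
  }

  // state
  double theta = prior_shape_theta / prior_rate_theta;
  std::vector<double> I(T, prior_shape_I / prior_rate_I);
  std::vector<double> beta(S + 1, 1.0 / (double)(S + 1));
  IntegerMatrix tab(S, T);

  NumericVector theta_chain(n_post);
  NumericMatrix I_chain(T, n_post);
  NumericVector sets_theta(n_sets);
  NumericMatrix sets_I(T, n_sets);
  NumericMatrix sets_beta(S + 1, n_sets);

  std::vector<double> tdot_j(S), tdot_i(T);

  for (int it = 1; it <= n_iter; ++it) {
    // (1) ancestral states
    std::fill(tdot_j.begin(), tdot_j.end(), 0.0);
    std::fill(tdot_i.begin(), tdot_i.end(), 0.0);
    double t_total = 0.0;
    for (int i = 0; i < T; ++i) {
      for (int j = 0; j < S; ++j) {
        int x = counts(j, i);
        if (x > 0) {
          int t = crt_draw(x, I[i] * beta[j]);
          tab(j, i) = t;
          tdot_j[j] += t;
          tdot_i[i] += t;
          t_total += t;
        }
      }
    }

    // (2) metacommunity distribution
    double gsum = 0.0;
    for (int j = 0; j < S; ++j) {
      beta[j] = R::rgamma(tdot_j[j], 1.0);
      gsum += beta[j];
    }
    beta[S] = R::rgamma(theta, 1.0);
    gsum += beta[S];
    if (gsum <= 0.0) { // degenerate; fall back to uniform
      for (int j = 0; j <= S; ++j) beta[j] = 1.0 / (double)(S + 1);
    } else {
      for (int j = 0; j <= S; ++j) beta[j] /= gsum;
    }

    // (3) biodiversity parameter: top-level CRP has t_total customers
    // seated at S occupied species components (every species has >= 1
    // table since every row of counts has a positive entry)
    theta = resample_concentration(theta, (int)t_total, S,
                                   prior_shape_theta, prior_rate_theta);

    // (4) immigration rates
    for (int i = 0; i < T; ++i) {
      I[i] = resample_concentration(I[i], (int)N[i], (int)tdot_i[i],
                                    prior_shape_I, prior_rate_I);
    }

    if (it > n_burn) {
      int s = it - n_burn; // 1..n_post
      theta_chain[s - 1] = theta;
      for (int i = 0; i < T; ++i) I_chain(i, s - 1) = I[i];
      if (s % thin == 0) {
        int k = s / thin - 1;
        if (k < n_sets) {
          sets_theta[k] = theta;
          for (int i = 0; i < T; ++i) sets_I(i, k) = I[i];
          for (int j = 0; j <= S; ++j) sets_beta(j, k) = beta[j];
        }
      }
    }
  }

  return List::create(
    _["theta_chain"] = theta_chain,
    _["I_chain"] = I_chain,
    _["sets_theta"] = sets_theta,
    _["sets_I"] = sets_I,
    _["sets_beta"] = sets_beta);
}
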