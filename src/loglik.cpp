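#include <Rcpp.h>
using namespace Rcpp;

// Model codes share one likelihood kernel; parameter vectors use the
// canonical orderings documented in rl_par_names():
//   1 s1  : alpha, beta
//   2 s2  : alpha_pos, alpha_neg, beta
//   3 d1  : mu, kappa, beta
//   4 d2  : alpha1, alpha2, beta
//   5 s1w : alpha, gamma, beta
//   6 s2w : alpha_pos, alpha_neg, gamma, beta
//   7 d1w : mu, kappa, gamma, beta
//   8 d2w : alpha1, alpha2, gamma, beta

static inline double weight_prob(double p, double gamma) {
  double f = gamma * (p - 0.5) + 0.5;
  if (f < 0.0) f = 0.0;
  if (f > 1.0) f = 1.0;
  return f;
}

// log(1 / (1 + exp(-x))) without overflow
static inline double log_sigmoid(double x) {
  if (x >= 0.0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}

static double rl_loglik_one(const double *par, int model,
                            const int *chosen_A, const int *reward_A,
                            const double *mag_A, const double *mag_B,
                            const int *block, int n,
                            bool reset, bool assoc_first, double S0) {
  bool weighted = model >= 5;
  int base = weighted ? model - 4 : model;  // 1..4

  double gamma = 1.0, beta, a1 = 0.0, a2 = 0.0, mu = 0.0, kappa = 0.0;
  switch (base) {
  case 1: a1 = par[0]; break;                 // alpha
  case 2: a1 = par[0]; a2 = par[1]; break;    // alpha_pos, alpha_neg
  case 3: mu = par[0]; kappa = par[1]; break; // mu, kappa
  case 4: a1 = par[0]; a2 = par[1]; break;    // alpha1, alpha2
  }
  int k = (base == 1) ? 1 : 2;
  if (weighted) { gamma = par[k]; k++; }
  beta = par[k];

  double p = 0.5;   // predicted probability that A is rewarded
  double S = S0;    // Pearce-Hall associability
  int cur_block = block[0];
  double ll = 0.0;
  int half = n / 2; // split-half boundary: trials 1..half use alpha1

  for (int t = 0; t < n; ++t) {
    if (reset && block[t] != cur_block) {
      cur_block = block[t];
      p = 0.5;
      S = S0;
    }
    if (chosen_A[t] < 0) continue;  // no response: no likelihood, no update

    double wA = weighted ? weight_prob(p, gamma) : p;
    double wB = weighted ? weight_prob(1.0 - p, gamma) : (1.0 - p);
    double x = beta * (mag_A[t] * wA - mag_B[t] * wB);
    ll += (chosen_A[t] == 1) ? log_sigmoid(x) : log_sigmoid(-x);

    // update the chosen stimulus's predicted probability
    double pc = (chosen_A[t] == 1) ? p : 1.0 - p;
    double rc = (chosen_A[t] == 1) ? (double)reward_A[t] : 1.0 - reward_A[t];
    double delta = rc - pc;

    double alpha_t;
    switch (base) {
    case 1: alpha_t = a1; break;
    case 2: alpha_t = (delta > 0) ? a1 : a2; break;
    case 3: {
      if (assoc_first) {
        S = (1.0 - mu) * S + mu * std::fabs(delta);
        alpha_t = std::min(kappa * S, 1.0);
      } else {
        alpha_t = std::min(kappa * S, 1.0);
        S = (1.0 - mu) * S + mu * std::fabs(delta);
      }
      break;
    }
    default: alpha_t = (t + 1 <= half) ? a1 : a2; break;
    }

    pc += alpha_t * delta;
    p = (chosen_A[t] == 1) ? pc : 1.0 - pc;
  }
  return ll;
}

// [[Rcpp::export]]
double rl_loglik_cpp(NumericVector par, int model,
                     IntegerVector chosen_A, IntegerVector reward_A,
                     NumericVector mag_A, NumericVector mag_B,
                     IntegerVector block,
                     bool reset, bool assoc_first, double S0) {
  int n = chosen_A.size();
  return rl_loglik_one(par.begin(), model, chosen_A.begin(), reward_A.begin(),
                       mag_A.begin(), mag_B.begin(), block.begin(), n,
                       reset, assoc_first, S0);
}

// Batched evaluation over a parameter grid (rows of `pars`); used by the
// brute-force grid-search oracle and sensitivity sweeps.
// [[Rcpp::export]]
NumericVector rl_loglik_batch(NumericMatrix pars, int model,
                              IntegerVector chosen_A, IntegerVector reward_A,
                              NumericVector mag_A, NumericVector mag_B,
                              IntegerVector block,
                              bool reset, bool assoc_first, double S0) {
  int m = pars.nrow(), k = pars.ncol(), n = chosen_A.size();
  NumericVector out(m);
  std::vector<double> p(k);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < k; ++j) p[j] = pars(i, j);
    out[i] = rl_loglik_one(p.data(), model, chosen_A.begin(), reward_A.begin(),
                           mag_A.begin(), mag_B.begin(), block.begin(), n,
                           reset, assoc_first, S0);
  }
  return out;
}
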