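// Gibbs sampler for the no-admixture-prior ("admixture model with
// Dirichlet(alpha) individual memberships") clustering of multilocus
// genotypes, following the standard alternating scheme:
//   z | Q,P   -> multinomial per allele copy
//   P | z     -> Dirichlet(lambda = 1 + counts) per cluster x locus
//   Q | z     -> Dirichlet(alpha + counts) per individual
//   alpha     -> Metropolis random walk, uniform prior on (0, 10]
// Model likelihood ln L = sum log sum_k Q_ik P_k,l[a] over observed
// allele copies; ln Pr(X|K) estimated as mean(lnL) - var(lnL)/2 over the
// post-burn-in samples.  Uses R's RNG so a caller-side set.seed() makes
// runs exactly reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static int sample_cat(const std::vector<double>& w, double tot) {
  double u = unif_rand() * tot, acc = 0.0;
  for (size_t k = 0; k < w.size(); ++k) {
    acc += w[k];
    if (u <= acc) return (int)k;
  }
  return (int)w.size() - 1;
}

// [[Rcpp::export(name = ".admixture_gibbs")]]
List admixture_gibbs(IntegerMatrix A1, IntegerMatrix A2, IntegerVector J,
                     int K, int burnin, int reps, double alpha_init,
                     double alpha_sd, double alpha_max) {
  const int N = A1.nrow(), L = A1.ncol();
  RNGScope scope;

  // state
  std::vector<std::vector<double>> P(L);   // P[l] is K x J[l], row-major
  std::vector<double> Q(N * K, 1.0 / K);
  IntegerMatrix z1(N, L), z2(N, L);
  for (int l = 0; l < L; ++l) P[l].assign(K * J[l], 1.0 / J[l]);
  double alpha = alpha_init;

  // accumulators
  std::vector<double> Qsum(N * K, 0.0);
  std::vector<std::vector<double>> Psum(L);
  for (int l = 0; l < L; ++l) Psum[l].assign(K * J[l], 0.0);
  NumericVector trace(burnin + reps);
  double lnl_sum = 0.0, lnl_sq = 0.0, alpha_sum = 0.0;
  int n_kept = 0, alpha_hi = 0;

  std::vector<double> w(K);
  std::vector<int> cntP, cntQ(K);

  for (int it = 0; it < burnin + reps; ++it) {
    // (i) allele-origin assignments
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int copy = 0; copy < 2; ++copy) {
          int a = copy == 0 ? A1(i, l) : A2(i, l);
          if (a < 0) continue;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = Q[i * K + k] * P[l][k * J[l] + a];
            tot += w[k];
          }
          int zk = tot > 0 ? sample_cat(w, tot) : (int)(unif_rand() * K);
          if (copy == 0) z1(i, l) = zk; else z2(i, l) = zk;
        }
      }
    }
    // (ii) allele frequencies P | z, Dirichlet(1 + counts)
    for (int l = 0; l < L; ++l) {
      cntP.assign(K * J[l], 0);
      for (int i = 0; i < N; ++i) {
        if (A1(i, l) >= 0) cntP[z1(i, l) * J[l] + A1(i, l)]++;
        if (A2(i, l) >= 0) cntP[z2(i, l) * J[l] + A2(i, l)]++;
      }
      for (int k = 0; k < K; ++k) {
        double tot = 0.0;
        for (int j = 0; j < J[l]; ++j) {
          double g = R::rgamma(1.0 + cntP[k * J[l] + j], 1.0);
          P[l][k * J[l] + j] = g;
          tot += g;
        }
        for (int j = 0; j < J[l]; ++j) P[l][k * J[l] + j] /= tot;
      }
    }
    // (iii) memberships Q | z, Dirichlet(alpha + counts)
    for (int i = 0; i < N; ++i) {
      std::fill(cntQ.begin(), cntQ.end(), 0);
      for (int l = 0; l < L; ++l) {
        if (A1(i, l) >= 0) cntQ[z1(i, l)]++;
        if (A2(i, l) >= 0) cntQ[z2(i, l)]++;
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + cntQ[k], 1.0);
        Q[i * K + k] = g;
        tot += g;
      }
      for (int k = 0; k < K; ++k) Q[i * K + k] /= tot;
    }
    // (iv) alpha Metropolis step (skipped for K = 1, where Q is fixed)
    if (K > 1) {
      double prop = alpha + norm_rand() * alpha_sd;
      if (prop > 0.0 && prop <= alpha_max) {
        double slq = 0.0;
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < K; ++k)
            slq += std::log(std::max(Q[i * K + k], 1e-300));
        double lr = N * (lgamma(K * prop) - K * lgamma(prop)
                         - lgamma(K * alpha) + K * lgamma(alpha))
                    + (prop - alpha) * slq;
        if (std::log(unif_rand()) < lr) alpha = prop;
      }
    }
    // (v) model log-likelihood
    double lnl = 0.0;
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int copy = 0; copy < 2; ++copy) {
          int a = copy == 0 ? A1(i, l) : A2(i, l);
          if (a < 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k)
            s += Q[i * K + k] * P[l][k * J[l] + a];
          lnl += std::log(std::max(s, 1e-300));
        }
      }
    }
    trace[it] = lnl;
    if (it >= burnin) {
      ++n_kept;
      lnl_sum += lnl;
      lnl_sq += lnl * lnl;
      alpha_sum += alpha;
      if (alpha > alpha_max - 1e-3) ++alpha_hi;
      for (int i = 0; i < N * K; ++i) Qsum[i] += Q[i];
      for (int l = 0; l < L; ++l)
        for (size_t j = 0; j < P[l].size(); ++j) Psum[l][j] += P[l][j];
    }
  }

  double mean_lnl = lnl_sum / n_kept;
  double var_lnl = n_kept > 1
      ? (lnl_sq - n_kept * mean_lnl * mean_lnl) / (n_kept - 1) : 0.0;

  NumericMatrix Qout(N, K);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Qout(i, k) = Qsum[i * K + k] / n_kept;
  List Pout(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix pm(K, J[l]);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J[l]; ++j)
        pm(k, j) = Psum[l][k * J[l] + j] / n_kept;
    Pout[l] = pm;
  }
  return List::create(_["Q"] = Qout, _["P"] = Pout,
                      _["mean_lnl"] = mean_lnl, _["var_lnl"] = var_lnl,
                      _["lnpd"] = mean_lnl - var_lnl / 2.0,
                      _["trace"] = trace,
                      _["alpha_mean"] = alpha_sum / n_kept,
                      _["alpha_at_bound_frac"] = (double)alpha_hi / n_kept);
}
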