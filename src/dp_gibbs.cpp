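#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Collapsed Gibbs sampler for a Dirichlet-process mixture of per-sample
// binomials. Cluster VAFs theta_{k,s} carry conjugate Beta(1,1) priors and
// are integrated out: an assignment move for mutation m scores each cluster
// by the beta-binomial posterior predictive of (alt_m, depth_m) given the
// cluster's current aggregated counts. Assignments follow the Chinese
// restaurant process; the concentration alpha is resampled by the usual
// Beta-augmentation under a Gamma prior unless fixed. All randomness runs
// through R's RNG, so set.seed() in R makes runs reproducible.

struct Cluster {
  int n = 0;
  std::vector<double> A;  // summed alt per sample
  std::vector<double> D;  // summed depth per sample
  double denom = 0.0;     // cached sum_s lbeta(A+1, D-A+1)
};

static double cluster_denom(const Cluster& c, int S) {
  double v = 0.0;
  for (int s = 0; s < S; ++s)
    v += R::lbeta(c.A[s] + 1.0, c.D[s] - c.A[s] + 1.0);
  return v;
}

// [[Rcpp::export(name = ".dp_gibbs_cpp")]]
List dp_gibbs_cpp(IntegerMatrix alt, IntegerMatrix depth,
                  int n_iter, int burn_in,
                  double alpha_shape, double alpha_rate,
                  double alpha_init, bool alpha_fix) {
  const int M = alt.nrow();
  const int S = alt.ncol();
  if (M < 1) stop("no mutations to cluster");
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in");

  double alpha = alpha_init;
  std::vector<Cluster> clusters;
  std::vector<int> z(M);

  // lbeta(alt+1, depth-alt+1) per cell: the new-cluster predictive.
  NumericMatrix self_lb(M, S);
  NumericVector self_row(M);
  for (int m = 0; m < M; ++m) {
    double tot = 0.0;
    for (int s = 0; s < S; ++s) {
      self_lb(m, s) = R::lbeta(alt(m, s) + 1.0, depth(m, s) - alt(m, s) + 1.0);
      tot += self_lb(m, s);
    }
    self_row[m] = tot;
  }

  // Start from singletons: coalescing under the predictive is fast,
  // whereas splitting an over-merged cluster by single-site moves is the
  // sampler's slowest move, so this initialisation mixes far better than
  // one big cluster.
  clusters.reserve(M);
  for (int m = 0; m < M; ++m) {
    Cluster c;
    c.A.assign(S, 0.0); c.D.assign(S, 0.0);
    c.n = 1;
    for (int s = 0; s < S; ++s) { c.A[s] = alt(m, s); c.D[s] = depth(m, s); }
    c.denom = cluster_denom(c, S);
    z[m] = m;
    clusters.push_back(c);
  }

  const int n_keep = n_iter - burn_in;
  IntegerMatrix kept_z(n_keep, M);
  NumericVector kept_score(n_keep);
  NumericVector kept_alpha(n_keep);
  IntegerVector kept_K(n_keep);
  NumericMatrix coassign(M, M);

  std::vector<double> logp;
  logp.reserve(64);

  for (int it = 0; it < n_iter; ++it) {
    for (int m = 0; m < M; ++m) {
      // detach m from its cluster
      int k0 = z[m];
      Cluster& c0 = clusters[k0];
      c0.n -= 1;
      for (int s = 0; s < S; ++s) { c0.A[s] -= alt(m, s); c0.D[s] -= depth(m, s); }
      if (c0.n == 0) {
        clusters.erase(clusters.begin() + k0);
        for (int j = 0; j < M; ++j) if (z[j] > k0) z[j] -= 1;
      } else {
        c0.denom = cluster_denom(c0, S);
      }

      const int K = clusters.size();
      logp.resize(K + 1);
      for (int k = 0; k < K; ++k) {
        const Cluster& c = clusters[k];
        double num = 0.0;
        for (int s = 0; s < S; ++s) {
          num += R::lbeta(alt(m, s) + c.A[s] + 1.0,
                          depth(m, s) - alt(m, s) + c.D[s] - c.A[s] + 1.0);
        }
        logp[k] = std::log((double)c.n) + num - c.denom;
      }
      logp[K] = std::log(alpha) + self_row[m];

      double mx = logp[0];
      for (int k = 1; k <= K; ++k) if (logp[k] > mx) mx = logp[k];
      double tot = 0.0;
      for (int k = 0; k <= K; ++k) { logp[k] = std::exp(logp[k] - mx); tot += logp[k]; }
      double u = R::unif_rand() * tot, acc = 0.0;
      int knew = K;
      for (int k = 0; k <= K; ++k) { acc += logp[k]; if (u <= acc) { knew = k; break; } }

      if (knew == K) {
        Cluster c;
        c.A.assign(S, 0.0); c.D.assign(S, 0.0);
        clusters.push_back(c);
      }
      Cluster& cn = clusters[knew];
      cn.n += 1;
      for (int s = 0; s < S; ++s) { cn.A[s] += alt(m, s); cn.D[s] += depth(m, s); }
      cn.denom = cluster_denom(cn, S);
      z[m] = knew;
    }

    int K = clusters.size();
    if (!alpha_fix) {
      // Beta-augmentation resampling of alpha | K, M (Gamma(a, b) prior).
      double eta = R::rbeta(alpha + 1.0, (double)M);
      double odds = (alpha_shape + K - 1.0) /
                    ((double)M * (alpha_rate - std::log(eta)));
      double pi_eta = odds / (1.0 + odds);
      double shape = (R::unif_rand() < pi_eta) ? alpha_shape + K
                                               : alpha_shape + K - 1.0;
      alpha = R::rgamma(shape, 1.0 / (alpha_rate - std::log(eta)));
      if (alpha < 1e-10) alpha = 1e-10;
    }

    if (it >= burn_in) {
      int r = it - burn_in;
      double score = K * std::log(alpha) + std::lgamma(alpha) -
                     std::lgamma(alpha + M);
      for (int k = 0; k < K; ++k)
        score += std::lgamma((double)clusters[k].n) + clusters[k].denom;
      kept_score[r] = score;
      kept_alpha[r] = alpha;
      kept_K[r] = K;
      for (int m = 0; m < M; ++m) kept_z(r, m) = z[m] + 1;

      // co-assignment counts, accumulated within clusters
      std::vector<std::vector<int>> members(K);
      for (int m = 0; m < M; ++m) members[z[m]].push_back(m);
      for (int k = 0; k < K; ++k) {
        const std::vector<int>& mem = members[k];
        for (size_t a = 0; a < mem.size(); ++a)
          for (size_t b = a; b < mem.size(); ++b) {
            coassign(mem[a], mem[b]) += 1.0;
            if (a != b) coassign(mem[b], mem[a]) += 1.0;
          }
      }
    }
  }

  for (int i = 0; i < M; ++i)
    for (int j = 0; j < M; ++j) coassign(i, j) /= (double)n_keep;

  return List::create(_["assignments"] = kept_z,
                      _["log_post"] = kept_score,
                      _["alpha"] = kept_alpha,
                      _["n_clusters"] = kept_K,
                      _["coassign"] = coassign);
}
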