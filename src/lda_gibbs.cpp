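// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// Symmetric Dirichlet priors (alpha on document-topic, beta on
// topic-word). phi and the marginal topic distribution are averaged
// over post-burn-in sweeps. A private mt19937 stream keyed by `seed`
// makes fits reproducible independently of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List lda_gibbs_cpp(List docs, int V, int K, double alpha, double beta,
                   int n_iter, int burn_in, int seed) {
  const int D = docs.size();
  std::vector<std::vector<int> > w(D);
  long N = 0;
  for (int d = 0; d < D; ++d) {
    IntegerVector v = docs[d];
    w[d].assign(v.begin(), v.end());
    for (size_t i = 0; i < w[d].size(); ++i) {
      if (w[d][i] < 0 || w[d][i] >= V)
        stop("word id out of range");
    }
    N += w[d].size();
  }

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<std::vector<int> > z(D);
  std::vector<int> nw(static_cast<size_t>(K) * V, 0);
  std::vector<int> nd(static_cast<size_t>(D) * K, 0);
  std::vector<int> nwsum(K, 0);

  for (int d = 0; d < D; ++d) {
    const size_t len = w[d].size();
    z[d].resize(len);
    for (size_t i = 0; i < len; ++i) {
      int t = static_cast<int>(unif(rng) * K);
      if (t >= K) t = K - 1;
      z[d][i] = t;
      ++nw[static_cast<size_t>(t) * V + w[d][i]];
      ++nd[static_cast<size_t>(d) * K + t];
      ++nwsum[t];
    }
  }

  std::vector<double> probs(K);
  std::vector<double> phi_acc(static_cast<size_t>(K) * V, 0.0);
  std::vector<double> ptop_acc(K, 0.0);
  NumericVector loglik(n_iter);
  int n_samples = 0;
  const double Vbeta = V * beta;

  for (int it = 0; it < n_iter; ++it) {
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
    for (int d = 0; d < D; ++d) {
      const size_t len = w[d].size();
      int* ndd = &nd[static_cast<size_t>(d) * K];
      for (size_t i = 0; i < len; ++i) {
        const int v = w[d][i];
        const int told = z[d][i];
        --nw[static_cast<size_t>(told) * V + v];
        --ndd[told];
        --nwsum[told];
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          const double p = (nw[static_cast<size_t>(k) * V + v] + beta) /
                           (nwsum[k] + Vbeta) * (ndd[k] + alpha);
          probs[k] = p;
          tot += p;
        }
        double u = unif(rng) * tot;
        int tnew = 0;
        double cum = probs[0];
        while (u > cum && tnew < K - 1) {
          ++tnew;
          cum += probs[tnew];
        }
        z[d][i] = tnew;
        ++nw[static_cast<size_t>(tnew) * V + v];
        ++ndd[tnew];
        ++nwsum[tnew];
      }
    }

    // joint log p(w, z) under the collapsed model
    double ll = K * (std::lgamma(Vbeta) - V * std::lgamma(beta));
    for (int k = 0; k < K; ++k) {
      const int* nwk = &nw[static_cast<size_t>(k) * V];
      for (int v = 0; v < V; ++v) ll += std::lgamma(nwk[v] + beta);
      ll -= std::lgamma(nwsum[k] + Vbeta);
    }
    const double Kalpha = K * alpha;
    for (int d = 0; d < D; ++d) {
      const int* ndd = &nd[static_cast<size_t>(d) * K];
      ll += std::lgamma(Kalpha) - K * std::lgamma(alpha);
      for (int k = 0; k < K; ++k) ll += std::lgamma(ndd[k] + alpha);
      ll -= std::lgamma(w[d].size() + Kalpha);
    }
    loglik[it] = ll;

    if (it >= burn_in) {
      for (int k = 0; k < K; ++k) {
        const double denom = nwsum[k] + Vbeta;
        double* acc = &phi_acc[static_cast<size_t>(k) * V];
        const int* nwk = &nw[static_cast<size_t>(k) * V];
        for (int v = 0; v < V; ++v) acc[v] += (nwk[v] + beta) / denom;
        ptop_acc[k] += (nwsum[k] + alpha) / (N + Kalpha);
      }
      ++n_samples;
    }
  }

  NumericMatrix phi(K, V);
  for (int k = 0; k < K; ++k) {
    double rowsum = 0.0;
    for (int v = 0; v < V; ++v) rowsum += phi_acc[static_cast<size_t>(k) * V + v];
    for (int v = 0; v < V; ++v)
      phi(k, v) = phi_acc[static_cast<size_t>(k) * V + v] / rowsum;
  }
  NumericVector ptopic(K);
  double psum = 0.0;
  for (int k = 0; k < K; ++k) psum += ptop_acc[k];
  for (int k = 0; k < K; ++k) ptopic[k] = ptop_acc[k] / psum;

  return List::create(_["phi"] = phi, _["ptopic"] = ptopic,
                      _["loglik"] = loglik,
                      _["n_samples"] = n_samples);
}
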