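// Collapsed Gibbs sampling for latent Dirichlet allocation, plus a fold-in
// sampler that infers a new document's topic mixture under a fixed
// word-topic matrix. Uses R's RNG so results are reproducible under
// set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static int sample_index(const std::vector<double>& p, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int K = (int)p.size();
  for (int k = 0; k < K; ++k) {
    acc += p[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// [[Rcpp::export]]
List lda_gibbs_fit(List docs, int V, int K, double alpha, double beta,
                   int n_iter) {
  int D = docs.size();
  std::vector<std::vector<int> > w(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    w[d].assign(dv.begin(), dv.end());
  }
  IntegerMatrix ndk(D, K);
  IntegerMatrix nkw(K, V);
  std::vector<int> nk(K, 0);
  std::vector<std::vector<int> > z(D);

  for (int d = 0; d < D; ++d) {
    int n = (int)w[d].size();
    z[d].resize(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      z[d][i] = k;
      ndk(d, k)++;
      nkw(k, w[d][i])++;
      nk[k]++;
    }
  }

  std::vector<double> p(K);
  double Vbeta = V * beta;
  for (int it = 0; it < n_iter; ++it) {
    for (int d = 0; d < D; ++d) {
      int n = (int)w[d].size();
      for (int i = 0; i < n; ++i) {
        int word = w[d][i];
        int k = z[d][i];
        ndk(d, k)--; nkw(k, word)--; nk[k]--;
        double total = 0.0;
        for (int t = 0; t < K; ++t) {
          p[t] = (ndk(d, t) + alpha) * (nkw(t, word) + beta) / (nk[t] + Vbeta);
          total += p[t];
        }
        k = sample_index(p, total);
        z[d][i] = k;
        ndk(d, k)++; nkw(k, word)++; nk[k]++;
      }
    }
    if (it % 20 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix phi(K, V);
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v)
      phi(k, v) = (nkw(k, v) + beta) / (nk[k] + Vbeta);

  NumericMatrix theta(D, K);
  for (int d = 0; d < D; ++d) {
    double nd = (double)w[d].size();
    for (int k = 0; k < K; ++k)
      theta(d, k) = (ndk(d, k) + alpha) / (nd + K * alpha);
  }
  return List::create(_["phi"] = phi, _["theta"] = theta);
}

// [[Rcpp::export]]
NumericVector lda_gibbs_infer(IntegerVector doc, NumericMatrix phi,
                              double alpha, int n_iter) {
  int K = phi.nrow();
  int n = doc.size();
  NumericVector theta(K);
  if (n == 0) {
    for (int k = 0; k < K; ++k) theta[k] = 1.0 / K;
    return theta;
  }
  std::vector<int> nkcnt(K, 0);
  std::vector<int> z(n);
  for (int i = 0; i < n; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    nkcnt[k]++;
  }
  std::vector<double> p(K);
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      int word = doc[i];
      int k = z[i];
      nkcnt[k]--;
      double total = 0.0;
      for (int t = 0; t < K; ++t) {
        p[t] = (nkcnt[t] + alpha) * phi(t, word);
        total += p[t];
      }
      k = sample_index(p, total);
      z[i] = k;
      nkcnt[k]++;
    }
  }
  for (int k = 0; k < K; ++k) theta[k] = (nkcnt[k] + alpha) / (n + K * alpha);
  return theta;
}
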