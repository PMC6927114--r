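// Skip-gram with negative sampling over integer token streams.
// Single-threaded and fully determined by the seed.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double sigmoidd(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
NumericMatrix cpp_sgns(List sents, int V, int dim, int window, int epochs,
                       double lr, int negative, int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // token counts for the unigram^0.75 negative-sampling distribution
  std::vector<double> cnt(V, 0.0);
  long total = 0;
  for (int s = 0; s < sents.size(); ++s) {
    IntegerVector sv = sents[s];
    for (int i = 0; i < sv.size(); ++i) {
      if (sv[i] >= 0 && sv[i] < V) { cnt[sv[i]] += 1.0; ++total; }
    }
  }
  if (total == 0) stop("cpp_sgns: empty token stream");
  std::vector<double> cum(V, 0.0);
  double z = 0.0;
  for (int v = 0; v < V; ++v) { z += std::pow(cnt[v], 0.75); cum[v] = z; }
  auto sampleNeg = [&]() {
    double u = unif(rng) * z;
    int lo = 0, hi = V - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  std::vector<double> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif(rng) - 0.5) / dim;

  std::vector<double> grad(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    double alpha = lr * (1.0 - (double)ep / std::max(1, epochs));
    if (alpha < lr * 1e-3) alpha = lr * 1e-3;
    for (int s = 0; s < sents.size(); ++s) {
      IntegerVector sv = sents[s];
      int n = sv.size();
      for (int i = 0; i < n; ++i) {
        int c = sv[i];
        if (c < 0 || c >= V) continue;
        int b = 1 + (int)(unif(rng) * window);  // dynamic window, word2vec style
        for (int j = std::max(0, i - b); j <= std::min(n - 1, i + b); ++j) {
          if (j == i) continue;
          int t = sv[j];
          if (t < 0 || t >= V) continue;
          double *v0 = &syn0[(size_t)c * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target; double label;
            if (k == 0) { target = t; label = 1.0; }
            else {
              target = sampleNeg();
              if (target == t) continue;
              label = 0.0;
            }
            double *v1 = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v0[d] * v1[d];
            double g = alpha * (label - sigmoidd(dot));
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v1[d];
              v1[d] += g * v0[d];
            }
          }
          for (int d = 0; d < dim; ++d) v0[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int v = 0; v < V; ++v)
    for (int d = 0; d < dim; ++d)
      out(v, d) = syn0[(size_t)v * dim + d];
  return out;
}
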