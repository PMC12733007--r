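#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Minimal deterministic xorshift RNG so embedding training does not depend
// on R's global RNG stream and reproduces exactly across platforms.
static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}
static inline double runif01(uint64_t &s) {
  return (xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over a walk corpus.
// walks: list of integer vectors with 1-based vocabulary indices.
// Returns a V x dim matrix of input (center) vectors.
// [[Rcpp::export]]
NumericMatrix sgns_train(List walks, int vocab_size, int dim, int window,
                         int epochs, int negative, double alpha,
                         int seed) {
  const int V = vocab_size;
  std::vector<double> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0);
  uint64_t rng = (uint64_t)seed * 2654435761u + 1u;
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (runif01(rng) - 0.5) / dim;

  // unigram^0.75 table for negative sampling
  std::vector<double> counts(V, 0.0);
  long long total_tokens = 0;
  for (int w = 0; w < walks.size(); ++w) {
    IntegerVector walk = walks[w];
    total_tokens += walk.size();
    for (int i = 0; i < walk.size(); ++i) counts[walk[i] - 1] += 1.0;
  }
  const int table_size = 1 << 17;
  std::vector<int> unigram(table_size);
  double norm = 0.0;
  for (int v = 0; v < V; ++v) norm += std::pow(counts[v], 0.75);
  if (norm <= 0.0) norm = 1.0;
  {
    int v = 0;
    double cum = std::pow(counts[0], 0.75) / norm;
    for (int i = 0; i < table_size; ++i) {
      unigram[i] = v;
      if ((double)(i + 1) / table_size > cum && v < V - 1) {
        ++v;
        cum += std::pow(counts[v], 0.75) / norm;
      }
    }
  }

  const double min_alpha = alpha * 0.01;
  long long processed = 0;
  const long long total = (long long)epochs * total_tokens;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < walks.size(); ++w) {
      IntegerVector walk = walks[w];
      const int n = walk.size();
      for (int i = 0; i < n; ++i) {
        double lr = alpha * (1.0 - (double)processed / (total + 1));
        if (lr < min_alpha) lr = min_alpha;
        ++processed;
        // dynamic window as in word2vec: uniform in [1, window]
        int b = 1 + (int)(runif01(rng) * window);
        if (b > window) b = window;
        for (int j = i - b; j <= i + b; ++j) {
          if (j == i || j < 0 || j >= n) continue;
          const int center = walk[i] - 1;
          const int context = walk[j] - 1;
          double *v_in = &syn0[(size_t)center * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = context;
              label = 1.0;
            } else {
              target = unigram[(int)(runif01(rng) * table_size)];
              if (target == context) continue;
              label = 0.0;
            }
            double *v_out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int v = 0; v < V; ++v)
    for (int d = 0; d < dim; ++d) out(v, d) = syn0[(size_t)v * dim + d];
  return out;
}
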