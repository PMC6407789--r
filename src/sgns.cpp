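// Skip-gram with negative sampling (SGNS), single-threaded and fully
// deterministic given a seed. The objective follows the classical word2vec
// formulation: for each (center c, context o) pair within a per-position
// randomly reduced window, ascend the gradient of
//   log sigma(v_c . v'_o) + sum_{i=1}^{neg} log sigma(-v_c . v'_{n_i})
// with negatives n_i drawn from the unigram distribution raised to 0.75.
// Frequent tokens are down-sampled with probability
//   p_discard = max(0, 1 - sqrt(t / f)),  f = corpus frequency of the token.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// xorshift64* PRNG: deterministic across platforms, independent of R's RNG
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  uint64_t below(uint64_t n) { return next() % n; }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, IntegerVector counts, int dim,
                         int window, int negative, double sample,
                         int epochs, double alpha, int seed) {
  const int V = counts.size();
  if (V == 0) stop("empty vocabulary");
  if (dim <= 0 || window < 1 || negative < 0 || epochs < 1)
    stop("invalid training parameters");

  XorShift rng(static_cast<uint64_t>(seed) * 2862933555777941757ULL + 3037000493ULL);

  // input (center) and output (context) vectors
  std::vector<double> syn0(static_cast<size_t>(V) * dim);
  std::vector<double> syn1(static_cast<size_t>(V) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  double total_count = 0.0;
  for (int i = 0; i < V; ++i) total_count += counts[i];

  // pre-computed keep probabilities for frequent-token down-sampling
  std::vector<double> keep(V, 1.0);
  if (sample > 0) {
    for (int i = 0; i < V; ++i) {
      double f = counts[i] / total_count;
      keep[i] = (f > sample) ? std::sqrt(sample / f) : 1.0;
    }
  }

  // unigram^0.75 table for negative sampling
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  {
    double norm = 0.0;
    for (int i = 0; i < V; ++i) norm += std::pow((double)counts[i], 0.75);
    double cum = std::pow((double)counts[0], 0.75) / norm;
    int w = 0;
    for (int i = 0; i < table_size; ++i) {
      table[i] = w;
      if ((double)(i + 1) / table_size > cum && w < V - 1) {
        ++w;
        cum += std::pow((double)counts[w], 0.75) / norm;
      }
    }
  }

  const int n_sent = sentences.size();
  double words_planned = total_count * epochs;
  double words_done = 0.0;
  std::vector<double> grad(dim);
  std::vector<int> sent;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int si = 0; si < n_sent; ++si) {
      IntegerVector raw = sentences[si];
      sent.clear();
      for (int t = 0; t < raw.size(); ++t) {
        int w = raw[t];
        if (w < 0 || w >= V) continue; // out-of-vocabulary token
        words_done += 1.0;
        if (keep[w] < 1.0 && rng.unif() > keep[w]) continue;
        sent.push_back(w);
      }
      const int n = (int)sent.size();
      if (n < 2) continue;
      double lr = alpha * (1.0 - words_done / (words_planned + 1.0));
      if (lr < alpha * 1e-4) lr = alpha * 1e-4;
      for (int pos = 0; pos < n; ++pos) {
        const int center = sent[pos];
        const int reduced = 1 + (int)rng.below((uint64_t)window);
        const int lo = std::max(0, pos - reduced);
        const int hi = std::min(n - 1, pos + reduced);
        double* vc = &syn0[(size_t)center * dim];
        for (int p2 = lo; p2 <= hi; ++p2) {
          if (p2 == pos) continue;
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = sent[p2];
              label = 1.0;
            } else {
              target = table[rng.below(table_size)];
              if (target == sent[p2]) continue;
              label = 0.0;
            }
            double* vo = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int j = 0; j < dim; ++j) dot += vc[j] * vo[j];
            double g = (label - sigmoid(dot)) * lr;
            for (int j = 0; j < dim; ++j) {
              grad[j] += g * vo[j];
              vo[j] += g * vc[j];
            }
          }
          for (int j = 0; j < dim; ++j) vc[j] += grad[j];
        }
      }
      if (si % 256 == 0) Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int j = 0; j < dim; ++j)
      out(i, j) = syn0[(size_t)i * dim + j];
  return out;
}
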