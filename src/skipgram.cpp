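#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over k-mer token streams.
// `streams`: list of integer vectors with tokens in 1..V (0 = masked, e.g.
// an N-containing k-mer; skipped as centre and context). Negatives are
// drawn from the unigram distribution raised to 3/4. Uses the R RNG, so
// the result is deterministic under set.seed(). Returns the input
// (centre-word) embedding matrix, V x d.
// [[Rcpp::export]]
NumericMatrix cpp_skipgram_train(List streams, int V, int d, int window,
                                 int negatives, int epochs, double lr0) {
  // unigram counts -> cumulative sampling table with 3/4 power
  std::vector<double> cum(V, 0.0);
  {
    std::vector<double> cnt(V, 0.0);
    for (int s = 0; s < streams.size(); ++s) {
      IntegerVector t = streams[s];
      for (int i = 0; i < t.size(); ++i)
        if (t[i] > 0) cnt[t[i] - 1] += 1.0;
    }
    double tot = 0.0;
    for (int v = 0; v < V; ++v) { tot += std::pow(cnt[v], 0.75); cum[v] = tot; }
    if (tot <= 0) stop("no unmasked tokens in the training streams");
    for (int v = 0; v < V; ++v) cum[v] /= tot;
  }

  // init: W_in uniform in (-0.5/d, 0.5/d), W_out zeros (word2vec convention)
  std::vector<double> Win((size_t)V * d), Wout((size_t)V * d, 0.0);
  for (size_t i = 0; i < Win.size(); ++i)
    Win[i] = (unif_rand() - 0.5) / d;

  // count total centre-context pairs for the learning-rate schedule
  long long total_pairs = 0;
  for (int s = 0; s < streams.size(); ++s) {
    IntegerVector t = streams[s];
    for (int i = 0; i < t.size(); ++i)
      if (t[i] > 0)
        for (int o = -window; o <= window; ++o) {
          if (o == 0) continue;
          int j = i + o;
          if (j >= 0 && j < t.size() && t[j] > 0) ++total_pairs;
        }
  }
  total_pairs *= epochs;
  if (total_pairs == 0) stop("streams too short for the requested window");

  std::vector<double> grad(d);
  long long done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < streams.size(); ++s) {
      IntegerVector t = streams[s];
      int n = t.size();
      for (int i = 0; i < n; ++i) {
        if (t[i] <= 0) continue;
        double *vin = &Win[(size_t)(t[i] - 1) * d];
        for (int o = -window; o <= window; ++o) {
          if (o == 0) continue;
          int j = i + o;
          if (j < 0 || j >= n || t[j] <= 0) continue;
          double lr = lr0 * std::max(0.1, 1.0 - (double)done / (double)total_pairs);
          ++done;
          std::fill(grad.begin(), grad.end(), 0.0);
          // one positive + `negatives` sampled targets
          for (int neg = 0; neg <= negatives; ++neg) {
            int target; double label;
            if (neg == 0) { target = t[j] - 1; label = 1.0; }
            else {
              double u = unif_rand();
              target = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
              if (target >= V) target = V - 1;
              if (target == t[j] - 1) continue;
              label = 0.0;
            }
            double *vout = &Wout[(size_t)target * d];
            double dot = 0.0;
            for (int q = 0; q < d; ++q) dot += vin[q] * vout[q];
            double g = (label - sigmoid(dot)) * lr;
            for (int q = 0; q < d; ++q) {
              grad[q] += g * vout[q];
              vout[q] += g * vin[q];
            }
          }
          for (int q = 0; q < d; ++q) vin[q] += grad[q];
        }
      }
    }
  }

  NumericMatrix out(V, d);
  for (int v = 0; v < V; ++v)
    for (int q = 0; q < d; ++q)
      out(v, q) = Win[(size_t)v * d + q];
  return out;
}
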