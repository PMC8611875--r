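#include <Rcpp.h>
using namespace Rcpp;

// Sample a nucleotide sequence (bases coded 0..3) from an order-3 Markov
// chain. `cumprob` is 64 x 4: row = 3-mer context code (16*b1 + 4*b2 + b3),
// columns = cumulative probabilities of the next base. `init` holds the
// first three bases. Uses the R RNG so results are reproducible under
// set.seed().
// [[Rcpp::export]]
IntegerVector cpp_sample_markov3(int n, NumericMatrix cumprob, IntegerVector init) {
  if (n < 3) stop("sequence length must be >= 3");
  IntegerVector out(n);
  out[0] = init[0]; out[1] = init[1]; out[2] = init[2];
  for (int i = 3; i < n; ++i) {
    int ctx = 16 * out[i - 3] + 4 * out[i - 2] + out[i - 1];
    double u = unif_rand();
    int b = 0;
    while (b < 3 && u > cumprob(ctx, b)) ++b;
    out[i] = b;
  }
  return out;
}
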