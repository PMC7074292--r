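#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Sample a nucleotide sequence from an order-m Markov chain over A,C,G,T.
// trans is a 4^m x 4 row-stochastic matrix whose rows are indexed by the
// base-4 encoding of the length-m context (A=0, C=1, G=2, T=3); the first
// m bases are drawn i.i.d. from init.  Uses R's RNG.
// [[Rcpp::export]]
std::string markovChainCpp(int m, const NumericMatrix& trans,
                           const NumericVector& init, double length) {
  const long L = (long)length;
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string s((size_t)L, 'A');
  long pow4m = 1;
  for (int i = 0; i < m; ++i) pow4m *= 4;
  long ctx = 0;
  for (long i = 0; i < L; ++i) {
    const double u = unif_rand();
    double c = 0.0;
    int b = 3;
    if (i < m) {
      for (int j = 0; j < 4; ++j) { c += init[j]; if (u < c) { b = j; break; } }
    } else {
      for (int j = 0; j < 4; ++j) { c += trans(ctx, j); if (u < c) { b = j; break; } }
    }
    s[(size_t)i] = bases[b];
    if (m > 0) ctx = (ctx * 4 + b) % pow4m;
  }
  return s;
}
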