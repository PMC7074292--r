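#include <Rcpp.h>
#include <map>
#include <string>

using namespace Rcpp;

// Overlapping k-mer counts on the forward strand (no reverse-complement
// canonicalization).  A window of width k slides with step 1; any window
// containing a character outside {A,C,G,T} -- ambiguity codes or the '-'
// record separator -- is skipped.  The sequence is assumed already
// normalized to uppercase.  Keys come back in lexicographic order
// (std::map), which is the canonical vocabulary order used throughout.
// [[Rcpp::export]]
List countKmersCpp(const std::string& seq, int k) {
  const long n = (long)seq.size();
  std::map<std::string, int> tab;
  double valid = 0.0;
  long run = 0;  // length of the A/C/G/T run ending at position i
  for (long i = 0; i < n; ++i) {
    const char c = seq[i];
    run = (c == 'A' || c == 'C' || c == 'G' || c == 'T') ? run + 1 : 0;
    if (run >= k) {
      ++tab[seq.substr(i - k + 1, k)];
      valid += 1.0;
    }
  }
  const int V = (int)tab.size();
  CharacterVector kmers(V);
  IntegerVector counts(V);
  int idx = 0;
  for (std::map<std::string, int>::const_iterator it = tab.begin();
       it != tab.end(); ++it, ++idx) {
    kmers[idx] = it->first;
    counts[idx] = it->second;
  }
  counts.attr("names") = kmers;
  return List::create(_["counts"] = counts, _["n_valid_windows"] = valid);
}
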