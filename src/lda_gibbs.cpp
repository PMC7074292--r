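#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>

using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.  theta and phi are integrated out and
// each token's topic is resampled from its full conditional
//   P(z_i = j | z_-i, w) \propto (n_dj + alpha) (n_jv + beta) / (n_j + V beta)
// Tokens arrive as parallel 0-based doc/word id vectors.  All randomness
// comes from R's RNG (unif_rand under the RNGScope that Rcpp attributes
// install), so set.seed() on the R side makes runs bit-reproducible.
//
// traceEvery > 0 records the per-token log-likelihood under the current
// smoothed theta/phi every traceEvery sweeps.  recordStates tallies the
// full assignment vector once per sweep, encoded base-nTopics (only
// meaningful for tiny corpora where nTopics^n fits a double exactly).
// zInit, when given, resumes from a previous state instead of a uniform
// random initialization.
// [[Rcpp::export]]
List ldaGibbsCpp(const IntegerVector& doc, const IntegerVector& word,
                 int nDocs, int nVocab, int nTopics,
                 double alpha, double beta, int nSweeps,
                 int traceEvery, bool recordStates,
                 Nullable<IntegerVector> zInit = R_NilValue) {
  const int n = doc.size();
  IntegerVector z(n);
  if (zInit.isNotNull()) {
    IntegerVector zi(zInit);
    for (int i = 0; i < n; ++i) z[i] = zi[i];
  } else {
    for (int i = 0; i < n; ++i) {
      int t = (int)(unif_rand() * nTopics);
      if (t >= nTopics) t = nTopics - 1;
      z[i] = t;
    }
  }

  IntegerMatrix ndj(nDocs, nTopics), njv(nTopics, nVocab);
  std::vector<int> nj(nTopics, 0), nd(nDocs, 0);
  for (int i = 0; i < n; ++i) {
    ndj(doc[i], z[i])++;
    njv(z[i], word[i])++;
    nj[z[i]]++;
    nd[doc[i]]++;
  }

  const double vb = (double)nVocab * beta;
  const double ta = (double)nTopics * alpha;
  std::vector<double> p(nTopics);
  std::map<double, double> stateTab;
  std::vector<double> trace;

  for (int s = 1; s <= nSweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      const int d = doc[i], v = word[i];
      int t = z[i];
      ndj(d, t)--; njv(t, v)--; nj[t]--;
      double tot = 0.0;
      for (int j = 0; j < nTopics; ++j) {
        p[j] = (ndj(d, j) + alpha) * (njv(j, v) + beta) / (nj[j] + vb);
        tot += p[j];
      }
      const double u = unif_rand() * tot;
      double c = 0.0;
      t = nTopics - 1;
      for (int j = 0; j < nTopics; ++j) {
        c += p[j];
        if (u < c) { t = j; break; }
      }
      z[i] = t;
      ndj(d, t)++; njv(t, v)++; nj[t]++;
    }
    if (recordStates) {
      double code = 0.0, mult = 1.0;
      for (int i = 0; i < n; ++i) {
        code += (double)z[i] * mult;
        mult *= (double)nTopics;
      }
      stateTab[code] += 1.0;
    }
    if (traceEvery > 0 && (s % traceEvery == 0)) {
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        const int d = doc[i], v = word[i];
        double pw = 0.0;
        for (int j = 0; j < nTopics; ++j)
          pw += (ndj(d, j) + alpha) / (nd[d] + ta) *
                (njv(j, v) + beta) / (nj[j] + vb);
        ll += std::log(pw);
      }
      trace.push_back(ll);
    }
  }

  List out = List::create(_["z"] = z, _["ndj"] = ndj, _["njv"] = njv,
                          _["trace"] = wrap(trace));
  if (recordStates) {
    const int S = (int)stateTab.size();
    NumericVector codes(S), cnts(S);
    int idx = 0;
    for (std::map<double, double>::const_iterator it = stateTab.begin();
         it != stateTab.end(); ++it, ++idx) {
      codes[idx] = it->first;
      cnts[idx] = it->second;
    }
    out["state_codes"] = codes;
    out["state_counts"] = cnts;
  }
  return out;
}
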