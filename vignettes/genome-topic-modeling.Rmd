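---
title: "Whole-genome k-mer topic modeling: model, assumptions and design choices"
author: "kmerTopics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome k-mer topic modeling: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerTopics)
```

## The problem and the model

Alignment-free genome comparison asks whether two genomes are related
without computing an alignment.  kmerTopics treats each genome as a
*document* and its overlapping k-mers as *words*: a genome of length
$l$ contributes $N = l - k + 1$ word tokens (windows containing
ambiguity codes or record separators are dropped).  The corpus over $M$
genomes is then modeled with latent Dirichlet allocation (LDA): each
document is a mixture of $T$ latent topics, each topic a multinomial
over the vocabulary, so the probability of word $w_i$ in a document is

$$P(w_i) = \sum_{j=1}^{T} P(w_i \mid z = z_j)\, P(z = z_j).$$

The generative process behind this mixture draws a document length
$N \sim \mathrm{Poisson}(\xi)$, topic proportions
$\theta \sim \mathrm{Dir}(\alpha)$, and for every token a topic
$z_n \sim \mathrm{Multinomial}(\theta)$ followed by a word from the
topic's word distribution.  Note the Poisson draw matters only for
*simulation*: in inference the document lengths are observed, so $\xi$
lives exclusively in the synthetic generator.

Inference is by collapsed Gibbs sampling: $\theta$ and $\phi$ are
integrated out and each token's topic is resampled from

$$P(z_i = j \mid z_{-i}, w) \propto
  (n_{dj}^{-i} + \alpha)\,\frac{n_{jv}^{-i} + \beta}{n_j^{-i} + V\beta},$$

where $n_{dj}$ counts tokens of document $d$ in topic $j$ and $n_{jv}$
counts assignments of word $v$ to topic $j$.  The point estimates are
the smoothed posterior means at the final sweep,
$\hat\theta_{dj} = (n_{dj}+\alpha)/(n_d+T\alpha)$ and
$\hat\phi_{jv} = (n_{jv}+\beta)/(n_j+V\beta)$.  Genomes are then
compared by hierarchically clustering the rows of $\hat\theta$; cutting
the tree at the number of families under study gives a flat
classification scored by purity and the adjusted Rand index.

## Choosing k: cumulative relative entropy

The word length k balances resolution against estimability.  For each
genome and each $j$, the observed $j$-mer frequencies are compared with
the second-order Markov extrapolation from the genome's own $(j-1)$-
and $(j-2)$-mer frequencies,

$$\hat f(n_1\ldots n_j) =
  \frac{f(n_1\ldots n_{j-1})\, f(n_2\ldots n_j)}{f(n_2\ldots n_{j-1})},$$

via the Kullback–Leibler divergence in bits (`RE_j`), and the profile
is summarized by the tail sum $\mathrm{CRE}(k) = \sum_{j\ge k} RE_j$.
When CRE falls below a threshold (0.1 bits by default), words longer
than $k$ add essentially no information beyond what shorter words
already predict; `selectK()` returns the smallest k at which *every*
genome is below threshold.  On the 30-genome bacterial design this
criterion selects k = 13.

Two numerical choices are worth stating explicitly.  First,
`relativeEntropy()` is the raw generalized KL divergence over the
common support, matching its closed-form unit cases; the guaranteed
non-negativity of `RE_j` comes from `creProfile()`, which restricts
*both* the observed and the expected distribution to their common
support and renormalizes them there before taking the divergence
(renormalizing only one side can produce negative values when observed
mass falls outside the support).  Second, the plug-in KL estimate is
biased upward by roughly $4^j/(2N\ln 2)$ bits for $N$ windows, so
profiles are only meaningful for $j$ well below $\log_4 N$; the
package's property checks on 1 Mbp simulated genomes therefore scan
$j \in [3, 6]$, where the bias is below 0.003 bits.  Base-2 logarithms
are used throughout ("bits"), making the 0.1 threshold unit-dependent;
both the base convention and the threshold are fixed, documented
choices rather than tuned values.

## The corpus filter

With three families of ten genomes each, the vocabulary is restricted
to k-mers present in at least ten genomes (`minDf = 10`, also
expressible as a fraction of documents for other designs).  The matrix
holds occurrence *counts* — LDA consumes word multiplicities — while
the reported "presence sum" statistic counts (genome, word) presence
pairs, i.e. the sum of document frequencies over the retained
vocabulary.  Storage is sparse (`dgCMatrix`): at k = 13 the unfiltered
union easily exceeds $10^7$ distinct words.  Counting is forward-strand
only, with no reverse-complement canonicalization; multi-record genomes
(chromosome plus plasmids, draft contigs) are concatenated with a `-`
separator that no window may span, so draft assemblies are handled
correctly.

## Hyperparameters and defaults

| parameter | default | meaning |
|---|---|---|
| `nTopics` (T) | user-chosen | number of topics; pick deliberately (e.g. the number of families studied) |
| `alpha` | 50/T | document-topic Dirichlet concentration |
| `beta` | 0.1 | topic-word Dirichlet concentration |
| `nIter` | 2000 | Gibbs sweeps |
| `burnIn` | `nIter/4` | discarded sweeps (posterior-mean estimate only) |
| `minDf` | 10 | document-frequency vocabulary filter |
| CRE threshold | 0.1 bits | k-selection criterion |
| metric / linkage | euclidean / average | theta-tree construction |

The Gibbs defaults are the conventional collapsed-Gibbs LDA choices.
The default point estimate is the final Gibbs state (common package
behavior); `estimate = "mean"` instead averages post-burn-in samples
after aligning topics to the final sample with `matchTopics()`, which
removes some single-sweep jitter at the cost of blurring across modes.
Topic labels are identifiable only up to permutation (label
switching), so any comparison of two fits, or of a fit against planted
truth, must first align topics; `matchTopics()` does this by exhaustive
permutation search, which is exact and cheap for the small T this
method uses.

Distance and linkage for the dendrogram are genuinely open choices;
euclidean distance on theta with average linkage (UPGMA) is the
default, Jensen–Shannon distance and complete/Ward linkage are
available, and the choice is echoed in every report so trees are
reproducible.  Ties in the merge order are resolved deterministically
by `stats::hclust`, and all randomness in the package flows through
explicit integer seeds on R's own RNG — identical inputs, config and
seed reproduce every output byte for byte.

## The FFP baseline

As a classical point of comparison, `ffpTree()` implements a
feature-frequency-profile tree: per-genome k-mer frequency vectors over
the *same* filtered vocabulary as the topic model (so the two trees are
directly comparable; using the unfiltered union is possible by passing
a different vocabulary), compared with the Jensen–Shannon divergence in
bits and clustered with the same linkage.  No over- or
under-represented words are removed — tolerating them is precisely what
the topic model brings, so the baseline must keep them too.

## What the synthetic generators emulate — and what they do not

`generateCorpus()` draws bag-of-words corpora *exactly* from the LDA
generative process with one fixed theta row per family, so
planted-parameter recovery can be scored without confounding.
`generateMarkovGenome()` samples DNA from order-m Markov chains, the
natural null model for the CRE criterion: the second-order extrapolation
is exact in expectation for sources of order $\le j - 2$, so `RE_j`
must vanish there and the package's checks verify it does (median under
0.01 bits at 1 Mbp).  `generateFamilyGenomes()` concatenates
topic-drawn k-mer words into sequences; re-extraction recovers the
planted words plus *junction* k-mers spanning word boundaries.  This
junction noise is accepted deliberately (designing de Bruijn-consistent
sequences would be brittle); it is quantifiable — planted-word windows
are $1/k$ of all windows — and the pipeline has to tolerate exactly
this kind of contamination on real genomes anyway.

Passing these checks therefore shows the machinery is correct under
the model's own assumptions and under controlled violations
(junction noise), but *not* that real genomes satisfy those
assumptions: real bacterial genomes carry phylogenetic correlation,
repeats, horizontal transfer and strand asymmetries that no generator
here emulates.  The simulated study conditions mirror the 30-genome
design (three families, ten genomes each, T = 3): corpora at
V = 1000 words and mean length $\xi = 5000$ tokens for recovery, DNA
fixtures of thirty 12 kbp genomes over an 8-mer vocabulary for the
end-to-end and baseline checks, and 1 Mbp genomes for the entropy
properties — sizes chosen so the full validation runs comfortably on a
laptop while keeping every per-genome token count far above $T\alpha$,
the regime the real corpus occupies.

## Degenerate inputs and numerical details

Documents with zero tokens are rejected (the full conditional is
undefined); `T = 1` collapses to closed forms used as unit oracles;
empty FASTA files yield empty record lists; a vocabulary filter that
removes everything yields an empty corpus that refuses to fit.  The
sampler is single-threaded by design — bit-reproducibility is part of
the contract — and uses R's RNG stream under a locally saved-and-
restored `.Random.seed`, so package calls never disturb the caller's
stream.  Sampler correctness is validated against brute-force
enumeration of the collapsed posterior on six-token corpora
(`sampleStateDistribution()`), a route entirely independent of the
sampler's own arithmetic.

## Known limitations

- Exact in-memory counting only: no minimizers, sketches or disk-backed
  counting, so k beyond ~16 (or very many large genomes) will exhaust
  memory.  The 30-genome, k = 13 design runs in a few GB.
- No automatic topic-number selection: T is a scientific input, not a
  tuned quantity.
- No bootstrap support values and no tree plotting; trees are exported
  as Newick for external tools.
- The CRE tail sum is truncated at `kMax` (default 16); the truncation
  point is a documented configuration, and profiles near `kMax` on
  short genomes are dominated by estimation bias (see above).
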