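---
title: "Self-organized semantic discovery of biomarker candidates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organized semantic discovery of biomarker candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markermine)
```

# The problem

Literature-based discovery asks whether relationships that no single
publication states outright can be assembled from fragments dispersed over a
document collection. `markermine` implements one concrete instance: screening
a corpus of biomedical abstracts for terms that behave, distributionally, like
known biomarkers or phenotypes of a disease (the running examples are diabetes
and obesity). The method is deliberately not sentence-level NLP: it never
parses grammar or extracts lexicalized relations. Instead it compares whole
*document subsets* — all documents mentioning a candidate term together with a
disease — against reference models built from documents about known
biomarkers, inside a semantic representation learned unsupervised from the
collection itself.

# The pipeline

## Lexicon and taxonomy

The knowledge substrate is a lexicon of *synonym groups*: sets of surface
forms with near-identical meaning (e.g. an abbreviation and its expansion),
each linked to a hypernym *taxon* in a single-rooted tree of at most seven
levels. Every entry carries a *significance rank* 0–4; rank 0 marks glue
(stop) words, rank 4 highly specific terms. Matching is longest-first over
token spans, so a three-token collocation is consumed before its constituent
unigrams, and all comparisons ignore case, punctuation, and extra whitespace.
The significance ranks of the bundled fixtures are assigned by the generator;
how such ranks are curated in a production lexicon is outside this package's
scope.

## Content space and descriptors

Documents are projected into a `d`-dimensional *content space* (default
`d = 100`). The axes are the `d` synonym groups maximizing a discrimination
score

\[ s(g) = \mathrm{significance}(g) \cdot \mathrm{df}(g) \cdot \frac{1}{1 + H(g)}, \]

where `df` is document frequency and `H(g)` the Shannon entropy (bits) of the
group's occurrence distribution over documents. The three factors reuse the
same weighting notions applied elsewhere in the pipeline: specific, frequent,
*concentrated* terms discriminate; terms dispersed evenly over the collection
do not. A document's vector holds `s(g)`-weighted occurrence counts,
L2-normalized, so projection is scale-invariant in counts. How the original
engine chose its 100 dimensions is unpublished; group-valued axes were chosen
here because they make every component interpretable and testable. Per-document
*descriptors* (the most relevant keywords) are ranked by
`count x significance / (1 + entropy)` with lexicographic tie-breaks.

## Information map

A Kohonen self-organizing map over the content vectors yields the *information
map*: a grid of neurons, each a semantic document class, with similar classes
adjacent. Two details matter:

* **Initialization.** Rather than random prototypes, documents are first
  clustered into `max(4, floor(sqrt(cells)))` coarse groups (seeded k-means);
  centroids are placed on the grid greedily — most populous at the center,
  each next centroid at the free cell whose already-placed neighbors it
  resembles most — and remaining cells are interpolated from placed
  neighbors. The published description of this "coarse group rebalancing"
  initial guess gives no algorithm for text, so this two-stage construction
  is this package's own interpretation of a similarity-preserving warm start;
  it is a declared deviation point.
* **Batch updates.** The default training mode recomputes best-matching units
  once per epoch and sets each prototype to the Gaussian-neighborhood-weighted
  mean of the data. This makes training deterministic given the seed and
  independent of document presentation order (both properties are tested
  bit-for-bit). An online mode exists for completeness.

Grid size defaults to roughly ten documents per neuron
(`ceiling(sqrt(n/10))` per side); the neighborhood radius decays linearly to
0.5. The reference engine's grid size and schedule are unpublished, so these
defaults are declared, not inferred.

Neurons are labeled with the top-level taxonomy branch most frequent among
their documents' recognized terms, and connected same-label regions are merged
(smallest into most-similar neighbor) until exactly `M` *main topics* remain.
`M` defaults to the number of branches present; the emulated large-corpus
configuration uses `M = 15`.

## Similarity

Document similarity is a convex combination (defaults 0.4/0.3/0.3, exposed in
configuration since the original weights are unpublished) of

1. the cosine of the content vectors (normalized dot chosen over a raw scalar
   product for boundedness),
2. a capped reciprocal Kullback–Leibler distance between main-topic
   distributions: both distributions are floored at 1e-9 and renormalized,
   the divergence is symmetrized as `(KL(p||q) + KL(q||p))/2` in bits, and
   `min(cap, 1/(eps + KLsym))` returned with `eps = 1e-3`, `cap = 1/eps`.
   Flooring and symmetrization make the measure total and symmetric, which a
   bare "reciprocal KL distance" is not;
3. a shared-concept score counting common synonym groups (weight 1), common
   direct hypernym taxa (weight 1/2), and common taxonomy nodes at levels
   2–4 (weight 1/4; the root is excluded as universally shared). The counts
   are combined as the cosine of the corresponding weighted indicator
   vectors, which is symmetric, bounded in [0, 1] by Cauchy–Schwarz, and
   exactly 1 for identical term profiles. A normalization by the
   self-score of one argument alone would break the symmetry that the
   measure's own contract requires, which is why the geometric-mean
   denominator was adopted.

## Constructed hypernyms for unknown terms

Out-of-vocabulary terms occurring at least three times are given a meaning by
cross-tabulation: against all known, non-glue terms occurring in the unknown
term's evidence documents (counts restricted to those documents — the
restriction matches the method's worked example of a term occurring in three
numbered documents). Each cross-term votes for its hypernym taxon with weight

\[ \mathrm{occ}(c) \cdot \mathrm{significance}(c) \cdot \frac{1}{1 + H(c)} \cdot J(u, c), \]

where `J` is the Jaccard overlap between the sets of neurons containing the
unknown term and the cross-term. `1/(1+H)` rather than `1/H` avoids division
by zero for single-document terms while preserving the "high entropy, low
discriminating power" semantics. `J` formalizes the prose notion of a
correction for disjunct neurons as a quantity bounded in [0, 1] that vanishes
exactly when the two terms never co-occupy a neuron. Scores then receive
`lambda = 0.25` times the summed scores of each taxon's branch neighbors
(parent, siblings, children); the top taxon is accepted as "is-a" hypernym
only if it dominates the runner-up by `theta = 1.5`. Both constants quantify
qualitative phrases ("partial contributions", "relatively clear dominance")
and sit in the configuration. When no taxon dominates, the fallback reports
the highest-scoring *associated descriptor* aggregated over the evidence
documents — a looser "is related to" estimate.

## Reference models and qualification

For each relation x disease category (biomarker-for/phenotype-of x
diabetes/obesity), the documents containing a reference term together with the
disease are featurized as `2M`-component vectors: the `M` main-topic
probabilities followed by the scores of the run-wide top-`M` concepts (30
components at `M = 15`). The concept block is min-max scaled with scaling
fitted once over the whole collection — fitting it per subset, as a literal
reading of the contract suggests, would make candidate-evidence vectors
incommensurable with reference centroids fitted on a different subset, so the
global fit was adopted. Each category subset is clustered by average-linkage
agglomerative clustering (Euclidean distance; the standard default, since the
original linkage is unstated) and cut at `k = clamp(round(sqrt(n)), 2, 6)`
sub-clusters — the square-root rule of thumb with the published ceiling of 6;
at `n ~ 50` this gives around 5–6 subgroups. Sub-cluster centroids encode the
5–6 possible meanings of, say, "biomarker for diabetes".

A candidate's evidence subset qualifies when at least a quorum (default 0.5,
inclusive) of its documents lie within a deviation threshold `tau` of their
*nearest* sub-cluster centroid — each document may match any of the reference
meanings, which is how the qualification prose reads and measurably more
robust than holding every document to one shared centroid when reference
sub-clusters are tight. By default `tau` is self-calibrated per model as the
90th percentile of the reference documents' own deviations from their
sub-cluster centroids: evidence qualifies when it sits no farther from a
reference meaning than the reference documents themselves typically do.

## Confidence levels

Qualified candidates are scored

\[ \mathrm{CL} = 100 \cdot \mathrm{clip}\!\left( \mathrm{base}\cdot\left(1 - \frac{\bar d}{d_{max}}\right)\cdot\left(1 + \beta \log_{10}(1 + \#\mathrm{docs})\right),\ 0,\ 1 \right) \]

with `base = 0.5`, `beta = 0.15`, `d_max` the largest mean deviation among the
run's qualified candidates, and `\bar d` the candidate's mean deviation from
the closest sub-cluster. The score decreases strictly in deviation and grows
logarithmically with evidence volume. The published account states the two
ingredients but no formula; the constants here were calibrated once so that a
standard synthetic run spans the low-single-digit to ~70% confidence range
reported for the emulated experiment. Document-count up-weighting is known to
inflate generic terms ("insulin", "lipid"); `beta = 0` is the documented
alternative, deliberately not the default. Reference-set members are retained
in the output, flagged, and reported at CL 100, as the emulated study's
figures do; downstream novelty analyses exclude them.

# The synthetic world

Since the original lexicon, corpora, and benchmarks are proprietary, all
validation runs on generated worlds with known ground truth
(`generate_synthetic()`): a balanced taxonomy (default depth 4, 6 topic
branches including metabolic disorders with diabetes/obesity synonym groups),
Zipf-weighted topic vocabularies (exponent 1.1, mimicking natural frequency
skew), and four document kinds — reference evidence (8 reference terms per
category, 3 documents each), planted association evidence (10 terms with
log-spaced document counts 4–30, mentioning their disease with probability
0.9), planted unknown-term evidence (terms absent from the lexicon co-occurring
with synonyms of one true taxon at a 3:1 signal ratio over 5 documents each),
and background documents. Half of the background documents mention a disease:
the emulated collection was retrieved by disease queries, so disease mentions
pervade it, and incidental term–disease co-occurrences must be spread over
heterogeneous documents rather than confined to reference-like ones. The
standard fixture holds 350 documents; the hypernym-recovery experiment scales
to 50 planted unknowns in 600 documents. All sizes were chosen as the smallest
at which the planted structure is unambiguous; a single pipeline run takes a
few seconds.

What the generator does *not* emulate: real biomedical language (tokens are
synthetic words), polysemy, cross-lingual synonymy, document length beyond a
negative-binomial budget, and citation or temporal structure. Passing tests
therefore demonstrate that the algorithms recover structure *their own
assumptions describe*, not performance on PubMed.

# Numerical and degenerate-input choices

* Entropies are in bits; the base cancels wherever entropy enters as a
  relative weight.
* Ties in axis selection, descriptor ranking, and candidate ordering break
  lexicographically; k-means initialization and all sampling are seeded, and
  batch SOM training is order-independent, so a fixed seed reproduces every
  artifact byte-for-byte.
* Documents with no recognized axis term project to the zero vector and to a
  uniform topic distribution.
* Empty reference categories produce a warning and are skipped rather than
  failing the run; candidates with fewer than two evidence documents are
  dropped with a log entry.
* Prototype cells receiving negligible neighborhood mass in a batch epoch
  keep their previous prototype.

# Known limitations

* Candidate terms are reported at the granularity of synonym groups; a group
  is represented by its most significant member surface.
* The qualification threshold's self-calibration assumes the reference
  categories are populated with at least a handful of documents each; very
  small categories produce tight thresholds and conservative candidate lists.
* Word-sense disambiguation is out of scope: an unknown term used in two
  senses receives a single constructed hypernym.
* The confidence score's document-count term inflates generic terms by
  design fidelity; an entropy- or joint-entropy-based redesign is an
  extension point, not implemented.
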