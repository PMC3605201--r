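# markermine

Self-organized semantic text mining for disease biomarker and phenotype
discovery.

`markermine` is for researchers exploring literature-based discovery: finding
candidate relationships (here, *term is a biomarker for / phenotype of a
disease*) that no single document states explicitly, by analyzing a document
collection as a whole rather than sentence by sentence. The package
implements the complete pipeline:

1. **Ingest & recognize** — documents (JSON-lines or MEDLINE-style abstracts)
   are matched against a lexicon of synonym groups linked into a ≤7-level
   hypernym taxonomy, with longest-match collocation handling and per-term
   occurrence entropies.
2. **Categorize** — documents are projected into a *d*-dimensional content
   space whose axes are the synonym groups maximizing
   s(g) = significance(g) · df(g) / (1 + H(g)), then clustered on a Kohonen
   self-organizing map (coarse-group-rebalanced initialization, deterministic
   batch training) whose labeled regions are the collection's *M* main
   topics.
3. **Infer meanings** — each out-of-vocabulary term occurring ≥ 3 times gets a
   *constructed hypernym* by cross-tabulating it against known terms in its
   evidence documents, weighting each cross-term by
   occ · significance · 1/(1+H) · J, where J is the neuron-level Jaccard
   overlap (disjunct-neuron correction), plus taxonomy-neighbor propagation;
   a dominance test (θ = 1.5) decides between the hypernym and an
   associated-descriptor fallback.
4. **Reference models** — for each relation × disease category, documents
   mentioning known reference terms with the disease are featurized as
   2M-component vectors (topic probabilities + top-M concept scores; 30
   components at M = 15) and clustered into k = clamp(round(√n), 2, 6)
   sub-clusters whose centroids encode the possible meanings of, e.g.,
   "biomarker for diabetes".
5. **Discover & score** — every term under a qualifying taxonomy node is
   tested: its evidence subset qualifies if most documents lie within a
   calibrated deviation threshold of a reference sub-cluster, and qualified
   candidates get a confidence level
   CL = 100 · clip(base · (1 − d̄/d_max) · (1 + β·log₁₀(1 + #docs)), 0, 1).
6. **Evaluate** — exact/partial benchmark matching with preferred/all synonym
   counting, precision/recall/novelty, match-type triage
   (exact / left-substring / between-2), and distribution reports.

A seeded synthetic-world generator (`generate_synthetic()`) provides
lexicons, topic-structured corpora, and ground-truth manifests (planted
unknown terms with true hypernyms, planted term–disease associations) for
validation; see the methods vignette (`vignettes/methods.Rmd`) for the model,
the design decisions, and what the synthetic results do and do not show.

## Worked example

```r
library(markermine)

world <- generate_synthetic(synthetic_spec(seed = 1), dir = tempfile())
res   <- run_pipeline(run_config(seed = 1), world = world)

head(res$candidates[, c("term","relation","disease","confidence","n_docs","origin")], 8)
#>    term     relation  disease confidence n_docs        origin
#>  bekeka BiomarkerFor diabetes        100     68 known_lexicon
#>  bugoga BiomarkerFor  obesity        100     71 known_lexicon
#>  daroza BiomarkerFor diabetes        100     64 known_lexicon
#>  domezu  PhenoTypeOf diabetes        100     20 known_lexicon
#>  gagoza  PhenoTypeOf diabetes        100     21 known_lexicon
#>  gavano BiomarkerFor diabetes        100     39 known_lexicon
#>  gegamu  PhenoTypeOf diabetes        100     13 known_lexicon
#>  gipimo BiomarkerFor  obesity        100     62 known_lexicon
```

The top rows are reference-set members, flagged and reported at confidence
100; novel candidates follow with computed CLs (here spanning 0–55%).
Constructed hypernyms for planted unknown words recover their true taxa:

```r
head(res$hypernyms[res$hypernyms$method == "hypernym",
                   c("term","taxon_label","dominance_ratio")], 4)
#>      term               taxon_label dominance_ratio
#>  badubeba   proteins subclass 31_42        2.309413
#>  damalimu   hormones subclass 31_41        4.000000
#>  dirivoko   hormones subclass 31_41        1.506364
#>  fisovebe procedures subclass 32_41        1.608796
```

Benchmark arithmetic works directly from match counts:

```r
compute_metrics(182, 2551, 182, 308)
#> precision = 7%; recall = 37%; novelty = 93%
```

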