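test_that("qualifying-node resolution includes subnodes transitively", {
  lex <- tiny_lexicon()
  q <- qualifying_taxa(lex, c("causal agents", "diabetes"))
  expect_setequal(q, c("drugs", "diuretic", "antidiab", "diab_tax"))
  # labels absent from the taxonomy are ignored
  expect_setequal(qualifying_taxa(lex, c("causal agents", "unicorns")),
                  c("drugs", "diuretic", "antidiab"))
})

test_that("candidate enumeration covers known and constructed-hypernym routes", {
  lex <- tiny_lexicon()
  docs <- make_docs(c("hctz diabetes", "body diabetes", "unky hctz diabetes"))
  a <- analyze_corpus(docs, lex)
  hyp <- data.frame(term = c("unky", "unkz"),
                    taxon_id = c("diuretic", NA),
                    taxon_label = c("diuretic drug", NA),
                    descriptor = c(NA, "x"),
                    method = c("hypernym", "descriptor_fallback"),
                    dominance_ratio = c(3, 1), n_docs = c(1, 1),
                    stringsAsFactors = FALSE)
  q <- qualifying_taxa(lex, c("causal agents"))
  got <- enumerate_candidates(a, hyp, q, reference_terms = "hctz")
  # known term under the qualifying branch (group label = "hctz")
  expect_true("hctz" %in% got$term)
  # unknown term via constructed hypernym under the branch
  expect_true("unky" %in% got$term)
  expect_equal(got$origin[got$term == "unky"], "constructed_hypernym")
  # term under a non-qualifying branch excluded; fallback-term excluded
  expect_false("body" %in% got$term)
  expect_false("unkz" %in% got$term)
  # reference flagging
  expect_true(got$is_reference[got$term == "hctz"])
})

test_that("evidence assembly honors synonym groups for both sides", {
  lex <- tiny_lexicon()
  docs <- make_docs(c(
    "hctz dm2 result",                  # synonyms on both sides -> in
    "hydrochlorothiazide notes",        # term only -> out
    "diabetes type 2 context",          # disease only -> out
    "hctz diabetes plain"))
  a <- analyze_corpus(docs, lex)
  got <- assemble_evidence("hydrochlorothiazide", "diabetes", a)
  expect_equal(got, c("d01", "d04"))
  # deterministic and a subset of the corpus
  expect_equal(assemble_evidence("hydrochlorothiazide", "diabetes", a), got)
  expect_true(all(got %in% docs$doc_id))
})

test_that("the quorum boundary qualifies at exactly one half", {
  run <- standard_run()
  model <- run$models[[1]]
  # synthetic two-doc subset: one member doc (deviation ~ 0 to its own
  # centroid region) and one far-away construct
  FV <- rbind(model$centroids[1, ], model$centroids[1, ] + 10)
  rownames(FV) <- c("near", "far")
  q <- markermine:::qualify_fv(FV, model, tau = 0.5, quorum = 0.5)
  expect_equal(q$fraction_below, 0.5)
  expect_true(q$qualified)                     # >= is inclusive
  q2 <- markermine:::qualify_fv(FV, model, tau = 0.5, quorum = 0.51)
  expect_false(q2$qualified)
  # subset identical to a centroid: zero deviation, qualifies for any tau > 0
  FV0 <- rbind(model$centroids[2, ], model$centroids[2, ])
  rownames(FV0) <- c("a", "b")
  q0 <- markermine:::qualify_fv(FV0, model, tau = 1e-6, quorum = 0.5)
  expect_true(q0$qualified)
  expect_equal(q0$mean_deviation, 0, tolerance = 1e-9)
})

test_that("pure-noise subsets do not qualify at small tau", {
  run <- standard_run()
  model <- run$models[[1]]
  set.seed(9)
  FVn <- matrix(stats::runif(10 * ncol(model$centroids), 2, 3), nrow = 10)
  rownames(FVn) <- sprintf("n%02d", 1:10)
  q <- markermine:::qualify_fv(FVn, model, tau = 0.05, quorum = 0.5)
  expect_false(q$qualified)
})

test_that("confidence is monotone in deviation and document count", {
  d_max <- 2
  # decreasing in mean deviation
  cls <- confidence_level(seq(0, 2, by = 0.25), 10, d_max)
  expect_true(all(diff(cls) < 0))
  expect_equal(cls[length(cls)], 0)            # deviation = d_max -> 0
  # nondecreasing in doc count at fixed deviation
  expect_gt(confidence_level(0.5, 100, d_max), confidence_level(0.5, 10, d_max))
  # beta = 0 disables the doc-count up-weighting
  expect_equal(confidence_level(0.5, 100, d_max, beta = 0),
               confidence_level(0.5, 10, d_max, beta = 0))
  # bounded in [0, 100]
  expect_lte(confidence_level(0, 1e6, d_max), 100)
  expect_gte(confidence_level(5, 1, d_max), 0)
})

test_that("planted associations surface with confidence above background", {
  run <- standard_run()
  world <- standard_world()
  cand <- run$candidates
  assoc <- world$manifest$planted_associations
  found <- mapply(function(tm, dis) {
    any(cand$term == tm & cand$disease == dis & cand$relation == "BiomarkerFor")
  }, assoc$term, assoc$disease)
  expect_true(all(found))
  planted <- cand$term %in% assoc$term
  med_planted <- stats::median(cand$confidence[planted & !cand$is_reference])
  med_bg <- stats::median(cand$confidence[!planted & !cand$is_reference])
  expect_gt(med_planted, med_bg)
})

test_that("reference-set members are reported at confidence 100", {
  run <- standard_run()
  cand <- run$candidates
  expect_true(any(cand$is_reference))
  expect_true(all(cand$confidence[cand$is_reference] == 100))
})

test_that("candidate totals add up across relation x disease categories", {
  run <- standard_run()
  cand <- run$candidates
  tab <- table(cand$relation, cand$disease)
  expect_equal(sum(tab), nrow(cand))
})

test_that("the candidate table round-trips through TSV", {
  run <- standard_run()
  p <- tempfile(fileext = ".tsv")
  write_candidates(run$candidates, p)
  got <- read_candidates(p)
  expect_equal(nrow(got), nrow(run$candidates))
  expect_equal(names(got), c("term", "relationship", "object", "conf_percent",
                             "n_docs", "doc_ids"))
  # sorted by confidence descending, ties by term
  expect_true(all(diff(got$conf_percent) <= 0))
  # doc id lists truncated at three entries plus ellipsis
  long <- got$n_docs > 3
  if (any(long)) {
    expect_true(all(grepl(",\\.\\.\\.$", got$doc_ids[long])))
  }
  # empty list -> header-only file
  p2 <- tempfile(fileext = ".tsv")
  write_candidates(run$candidates[0, ], p2)
  expect_equal(nrow(read_candidates(p2)), 0)
})
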