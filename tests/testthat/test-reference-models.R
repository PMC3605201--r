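test_that("evidence retrieval requires both reference term and disease", {
  lex <- tiny_lexicon()
  docs <- make_docs(c(
    "sitagliptin diabetes stuff",        # term + disease -> in
    "sitagliptin alone here",            # no disease -> out
    "dm2 sitagliptin outcome",           # synonym-mediated disease -> in
    "diabetes only no term",             # no reference term -> out
    "hctz diabetes type 2"               # different term, synonym disease
  ))
  a <- analyze_corpus(docs, lex)
  got <- retrieve_evidence("sitagliptin", "diabetes", a)
  expect_setequal(got, c("d01", "d03"))
  got2 <- retrieve_evidence(c("sitagliptin", "hctz"), "diabetes", a)
  expect_setequal(got2, c("d01", "d03", "d05"))
  expect_warning(retrieve_evidence("sitagliptin", "obesityzz", a), "no evidence")
  expect_error(retrieve_evidence(character(0), "diabetes", a), "empty")
})

test_that("feature vectors concatenate topic and scaled concept blocks", {
  run <- standard_run()
  M <- run$M
  ids <- run$analysis$corpus$doc_id[1:20]
  FV <- feature_vectors(ids, run$vectors, run$map, run$basis)
  expect_equal(ncol(FV), 2 * M)
  expect_equal(unname(rowSums(FV[, seq_len(M), drop = FALSE])), rep(1, 20),
               tolerance = 1e-9)
  C <- FV[, (M + 1):(2 * M), drop = FALSE]
  expect_true(all(C >= -1e-12 & C <= 1 + 1e-12))
})

test_that("a 15-topic configuration yields 30-component feature vectors", {
  spec <- synthetic_spec(seed = 3, n_topics = 15, n_groups_per_topic = 8,
                         n_docs = 320, n_planted_unknowns = 2,
                         n_planted_associations = 2,
                         assoc_docs_range = c(4L, 6L),
                         n_reference_terms = 4L, docs_per_reference = 2L)
  world <- generate_synthetic(spec, dir = tempfile())
  a <- analyze_corpus(world$corpus, world$lexicon)
  sp <- suppressWarnings(build_content_space(a, d = 60))
  v <- project_documents(a, sp)
  map <- fit_infomap(v, rows = 6, cols = 6, seed = 3)
  map <- label_topics(map, a, M = 15)
  basis <- concept_basis(a, M = 15)
  FV <- feature_vectors(a$corpus$doc_id[1:5], v, map, basis)
  expect_equal(ncol(FV), 30)
  expect_equal(max(map$topic_labels), 15)
})

test_that("the sub-cluster count rule clamps sqrt(n) to 2..6", {
  expect_equal(subcluster_count(4), 2)     # floor
  expect_equal(subcluster_count(9), 3)
  expect_equal(subcluster_count(25), 5)
  expect_equal(subcluster_count(50), 6)    # around 5-6 at n ~ 50
  expect_equal(subcluster_count(36), 6)
  expect_equal(subcluster_count(1000), 6)  # ceiling
})

test_that("reference models partition members and keep simplex centroids", {
  run <- standard_run()
  for (m in run$models) {
    expect_gte(m$k, 2); expect_lte(m$k, 6)
    expect_equal(sum(lengths(m$members)), m$n)
    M <- run$M
    topic_sums <- rowSums(m$centroids[, seq_len(M), drop = FALSE])
    expect_equal(unname(topic_sums), rep(1, m$k), tolerance = 1e-9)
  }
  expect_error(build_reference_model(c("D0001", "D0002"), run$vectors,
                                     run$map, run$basis),
               "too small")
})

test_that("clustering separates a planted 2-cluster subset perfectly", {
  run <- standard_run()
  world <- standard_world()
  # two well-separated document families: one reference term's docs for
  # diabetes vs one for obesity (different topics by construction)
  dia_docs <- retrieve_evidence(world$reference_lists$BiomarkerFor$diabetes[1],
                                "diabetes", run$analysis)
  obe_docs <- retrieve_evidence(world$reference_lists$PhenoTypeOf$obesity[1],
                                "obesity", run$analysis)
  dia_docs <- setdiff(dia_docs, obe_docs)[1:3]
  obe_docs <- setdiff(obe_docs, dia_docs)[1:3]
  m <- build_reference_model(c(dia_docs, obe_docs), run$vectors, run$map,
                             run$basis, k = 2)
  truth <- c(rep(1, 3), rep(2, 3))
  names(truth) <- c(dia_docs, obe_docs)
  purity <- sum(vapply(m$members, function(ids) {
    max(table(truth[ids]))
  }, 0)) / 6
  expect_equal(purity, 1)
})

test_that("model construction is invariant to document input order", {
  run <- standard_run()
  docs <- run$models[[1]]$members
  docs <- unlist(docs, use.names = FALSE)
  m1 <- build_reference_model(docs, run$vectors, run$map, run$basis)
  m2 <- build_reference_model(rev(docs), run$vectors, run$map, run$basis)
  expect_equal(m1$centroids[order(m1$centroids[, 1]), ],
               m2$centroids[order(m2$centroids[, 1]), ], tolerance = 1e-12)
})
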