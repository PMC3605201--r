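# a micro world with three taxa and hand-set counts for oracle checking
micro_world <- function() {
  lex <- tiny_lexicon()
  docs <- make_docs(c(
    "unkdrug hctz hctz sitagliptin",
    "unkdrug hctz diabetes",
    "unkdrug hydrochlorothiazide body",
    "body mass index body diabetes",
    "sitagliptin diabetes"
  ))
  a <- analyze_corpus(docs, lex)
  sp <- suppressWarnings(build_content_space(a, d = 4))
  v <- project_documents(a, sp)
  map <- train_som(v, som_config(2, 2, epochs = 5, seed = 1))
  list(lex = lex, a = a, map = map)
}

test_that("cross-tabulation is restricted to the evidence documents", {
  w <- micro_world()
  cross <- cross_tabulate("unkdrug", w$a)
  # only groups from docs d01-d03; counts restricted to those docs
  expect_setequal(cross$group_id, c("g_hctz", "g_sita", "g_diab", "g_body"))
  expect_equal(cross$count[cross$group_id == "g_hctz"], 4L)   # 2 + 1 + 1
  expect_equal(cross$count[cross$group_id == "g_sita"], 1L)   # d01 only
  expect_false("g_bmi" %in% cross$group_id)                   # d04 not evidence
  # glue groups excluded by the significance filter
  expect_false(any(c("g_the", "g_of") %in% cross$group_id))
  expect_error(cross_tabulate("hapax", w$a), "gate")
})

test_that("hypernym scores equal a brute-force aggregation oracle", {
  w <- micro_world()
  cross <- cross_tabulate("unkdrug", w$a)
  tab <- score_hypernyms("unkdrug", cross, w$a, w$map, lambda = 0.25)

  # independent spreadsheet-style oracle
  lex <- w$lex
  H <- stats::setNames(w$a$group_stats$entropy, w$a$group_stats$group_id)
  u_docs <- c("d01", "d02", "d03")
  u_cells <- unique(unname(w$map$assignments[u_docs]))
  base <- numeric(0)
  for (i in seq_len(nrow(cross))) {
    g <- cross$group_id[i]
    g_docs <- unique(w$a$doc_groups$doc_id[w$a$doc_groups$group_id == g])
    g_cells <- unique(unname(w$map$assignments[g_docs]))
    J <- length(intersect(u_cells, g_cells)) / length(union(u_cells, g_cells))
    contrib <- cross$count[i] * lex$group_sig[[g]] / (1 + H[[g]]) * J
    h <- lex$group_taxon[[g]]
    base[h] <- (if (is.na(base[h])) 0 else base[h]) + contrib
  }
  base <- base[!is.na(base)]
  targets <- unique(c(names(base),
                      unlist(lapply(names(base), branch_neighbors, lex = lex))))
  oracle <- vapply(targets, function(h) {
    own <- if (h %in% names(base)) base[[h]] else 0
    nb <- intersect(branch_neighbors(h, lex), names(base))
    own + 0.25 * sum(base[nb])
  }, 0)
  oracle <- sort(oracle, decreasing = TRUE)
  expect_equal(tab$scores, oracle, tolerance = 1e-12)
  expect_equal(tab$base_scores[order(names(tab$base_scores))],
               base[order(names(base))], tolerance = 1e-12)
  expect_gte(tab$dominance_ratio, 1)
})

test_that("disjunct neurons zero out contributions", {
  w <- micro_world()
  # forge a map where the unknown term's docs (d01-d03, cell 1) and the
  # cross-term's docs (g_bmi: d04 only, cell 2) never share a neuron
  map <- w$map
  map$assignments[] <- c(1L, 1L, 1L, 2L, 2L)
  cross <- data.frame(group_id = "g_bmi", count = 1L,
                      stringsAsFactors = FALSE)
  tab <- score_hypernyms("unkdrug", cross, w$a, map)
  expect_length(tab$scores, 0)   # J = 0 -> no contribution at all
})

test_that("dominance selection and descriptor fallback follow the threshold", {
  t1 <- structure(list(term = "u", scores = c(a = 3, b = 1),
                       base_scores = c(a = 3, b = 1), dominance_ratio = 3),
                  class = "mm_hypernym_table")
  expect_equal(select_hypernym(t1, theta = 1.5)$taxon_id, "a")
  t2 <- structure(list(term = "u", scores = c(a = 2, b = 2),
                       base_scores = c(a = 2, b = 2), dominance_ratio = 1),
                  class = "mm_hypernym_table")
  expect_equal(select_hypernym(t2, theta = 1.5)$method, "descriptor_fallback")
  t3 <- structure(list(term = "u", scores = c(a = 2), base_scores = c(a = 2),
                       dominance_ratio = Inf),
                  class = "mm_hypernym_table")
  expect_equal(select_hypernym(t3)$taxon_id, "a")
  empty <- structure(list(term = "u", scores = numeric(0),
                          base_scores = numeric(0),
                          dominance_ratio = NA_real_),
                     class = "mm_hypernym_table")
  expect_equal(select_hypernym(empty)$method, "descriptor_fallback")
})

test_that("descriptor fallback aggregates evidence-document descriptors", {
  lex <- tiny_lexicon()
  docs <- make_docs(c(
    "unkx sitagliptin sitagliptin hctz",
    "unkx sitagliptin sitagliptin",
    "unkx sitagliptin sitagliptin body"))
  a <- analyze_corpus(docs, lex)
  expect_equal(descriptor_fallback("unkx", a), "sitagliptin")
  # invariant to doc order
  a2 <- analyze_corpus(docs[3:1, ], lex)
  expect_equal(descriptor_fallback("unkx", a2), "sitagliptin")
})

test_that("planted unknown terms recover their true taxa", {
  run <- standard_run()
  man <- standard_world()$manifest$planted_unknowns
  merged <- merge(run$hypernyms, man, by = "term")
  expect_equal(nrow(merged), nrow(man))
  recovery <- mean(merged$taxon_id.x == merged$taxon_id.y, na.rm = TRUE)
  expect_gte(recovery, 0.9)
})

test_that("hypernym TSV output mirrors the three-column layout", {
  run <- standard_run()
  p <- tempfile(fileext = ".tsv")
  write_hypernyms(run$hypernyms, p)
  got <- utils::read.delim(p, stringsAsFactors = FALSE)
  expect_equal(names(got), c("unknown_term", "constructed_hypernym",
                             "associated_descriptor_1"))
  expect_equal(nrow(got), nrow(run$hypernyms))
})
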