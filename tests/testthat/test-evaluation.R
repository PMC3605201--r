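test_that("normalization keys ignore case, spaces, and punctuation", {
  expect_equal(normalize_key("Diabetes"), normalize_key("diabetes"))
  expect_equal(normalize_key("DM-2"), normalize_key("dm2"))
  expect_equal(normalize_key(normalize_key("A b-C")), normalize_key("A b-C"))
})

test_that("exact and partial matching follow the 2x2 match matrix", {
  bm <- markermine:::benchmark_from_list(list(
    "Diabetes Type 2" = c("DM2"),
    "Insulin" = character(0),
    "Uric Acid" = c("urate")
  ))
  terms <- c("diabetes", "insulin", "unmatched term")
  # partial: "diabetes" token set strictly inside "Diabetes Type 2"
  m_all <- match_benchmark(terms, bm, match_type = "all", counting = "preferred")
  expect_setequal(m_all$matched_candidates, c("diabetes", "insulin"))
  expect_true(any(m_all$pairs$kind == "partial"))
  # exact mode never returns partials
  m_ex <- match_benchmark(terms, bm, match_type = "exact", counting = "preferred")
  expect_equal(unique(m_ex$pairs$kind), "exact")
  expect_setequal(m_ex$matched_candidates, "insulin")
  # exact matches are a subset of all matches
  expect_true(all(m_ex$matched_candidates %in% m_all$matched_candidates))
  # synonym conflation: DM2 counts under its preferred term in preferred mode
  m_syn <- match_benchmark("dm2", bm, match_type = "exact", counting = "preferred")
  expect_equal(m_syn$matched_benchmark, "Diabetes Type 2")
  m_syn_all <- match_benchmark("dm2", bm, match_type = "exact", counting = "all")
  expect_equal(m_syn_all$matched_benchmark, "DM2")
  expect_equal(m_syn_all$benchmark_total, 5)  # every synonym counted
})

test_that("precision, recall, and novelty reproduce the worked example", {
  m <- compute_metrics(182, 2551, 182, 308)
  expect_equal(m$precision, 7L)
  expect_equal(m$recall, 37L)
  expect_equal(m$novelty, 93L)
  expect_equal(m$precision + m$novelty, 100L)
  # degenerate cases are marked, not thrown
  m2 <- compute_metrics(0, 10, 0, 5)
  expect_equal(m2$precision, 0L); expect_equal(m2$novelty, 100L)
  m3 <- compute_metrics(5, 5, 5, 0)
  expect_equal(m3$precision, 100L); expect_equal(m3$novelty, 0L)
  m4 <- compute_metrics(0, 0, 0, 0)
  expect_true(is.na(m4$precision)); expect_true(is.na(m4$recall))
})

test_that("conservative and liberal estimates order as expected on fixtures", {
  bm <- markermine:::benchmark_from_list(list(
    "Diabetes Type 2" = c("DM2", "type 2 diabetes"),
    "Insulin Resistance" = c("IR"),
    "Leptin" = character(0)
  ))
  terms <- c("diabetes", "insulin resistance", "leptin", "novel thing",
             "another novelty")
  cons <- evaluate_candidates(terms, bm, match_type = "exact", counting = "all")
  lib <- evaluate_candidates(terms, bm, match_type = "all", counting = "preferred")
  expect_lte(cons$precision_raw, lib$precision_raw)
  expect_lte(cons$recall_raw, lib$recall_raw)
})

test_that("triage labels follow exact > left_substring > between_2", {
  dump <- c("ABCC8 gene", "Acute Coronary Syndrome", "Alpha Rays",
            "C ara A", "CD100 antigen", "9-cis-retinoic acid biosynthesis")
  expect_equal(triage_match("ABCC8 gene", dump), "exact")
  expect_equal(triage_match("ABCC8", dump), "left_substring")
  expect_equal(triage_match("9-cis-retinoic acid", dump), "left_substring")
  expect_equal(triage_match("Cara", dump), "left_substring")
  expect_equal(triage_match("CD-1", dump), "left_substring")
  expect_equal(triage_match("acute coronary syndromes", dump), "between_2")
  expect_equal(triage_match("Bmisds", dump), "between_2")
  # labels partition: every candidate gets exactly one label
  labs <- triage_match(c("ABCC8 gene", "ABCC8", "zzz"), dump)
  expect_length(labs, 3)
  expect_true(all(labs %in% c("exact", "left_substring", "between_2")))
  expect_error(triage_match("x", character(0)), "empty")
})

test_that("distribution reports match the published match-type percentages", {
  rep1 <- distribution_report(c(exact = 789, left_substring = 591,
                                between_2 = 632))
  expect_equal(rep1$percent, c(39L, 29L, 31L))
  rep2 <- distribution_report(c(exact = 409, left_substring = 225,
                                between_2 = 155))
  expect_equal(rep2$percent, c(52L, 29L, 20L))
  # single label -> 100%; percents sum to 100 +/- 1
  expect_equal(distribution_report(c(exact = 5))$percent, 100L)
  expect_lte(abs(sum(rep1$percent) - 100), 1)
})

test_that("the match-scoring summary reproduces the novelty narrowing", {
  s <- match_scoring_summary(2551, 182, 308, 512, 71)
  expect_equal(s$novelty, 93L)
  expect_equal(s$testable_share, 20L)
  expect_equal(s$confirmed_share, 3L)
  expect_equal(match_scoring_summary(100, 100, 0, 0, 0)$novelty, 0L)
  expect_equal(match_scoring_summary(100, 10, 5, 0, 0)$testable_share, 0L)
  expect_error(match_scoring_summary(10, 20, 0, 0, 0), "inconsistent")
})

test_that("benchmark vocabularies round-trip from TSV", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("Diabetes Type 2\tDM2\ttype 2 diabetes", "Leptin"), p)
  bm <- read_benchmark(p)
  expect_equal(sum(bm$entries$is_preferred), 2)
  expect_equal(nrow(bm$entries), 4)
  writeLines(c("Leptin", "leptin"), p)
  expect_error(read_benchmark(p), "duplicate preferred")
})
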