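# Shared fixtures. The expensive synthetic world and full pipeline run are
# built once per test session and cached.

.mm_cache <- new.env(parent = emptyenv())

standard_world <- function() {
  if (is.null(.mm_cache$world)) {
    .mm_cache$world <- generate_synthetic(
      synthetic_spec(seed = 1), dir = file.path(tempdir(), "mm_std_world"))
  }
  .mm_cache$world
}

standard_run <- function() {
  if (is.null(.mm_cache$run)) {
    .mm_cache$run <- suppressMessages(
      run_pipeline(run_config(seed = 1), world = standard_world()))
  }
  .mm_cache$run
}

# hand-built micro lexicon exercising synonym groups, multiword collocations,
# glue words, and a small taxonomy
tiny_lexicon_files <- function(dir = tempfile("tinylex")) {
  dir.create(dir, showWarnings = FALSE)
  tax <- data.frame(
    taxon_id = c("root", "drugs", "diuretic", "antidiab", "disorders",
                 "metab", "diab_tax", "measures", "bmi_tax", "anatomy"),
    label = c("entity", "causal agents", "diuretic drug", "antidiabetic",
              "disorders", "metabolic disorders", "diabetes",
              "measures", "body measures", "anatomy"),
    level = c(1, 2, 3, 3, 2, 3, 4, 2, 3, 2),
    parent_id = c("", "root", "drugs", "drugs", "root", "disorders",
                  "metab", "root", "measures", "root"),
    stringsAsFactors = FALSE
  )
  ent <- data.frame(
    surface = c("hydrochlorothiazide", "hctz", "sitagliptin", "diabetes",
                "diabetes type 2", "dm2", "body", "body mass index",
                "the", "of"),
    word_type = "noun",
    language = "en",
    significance = c(4, 4, 4, 4, 4, 4, 2, 3, 0, 0),
    group_id = c("g_hctz", "g_hctz", "g_sita", "g_diab", "g_diab", "g_diab",
                 "g_body", "g_bmi", "g_the", "g_of"),
    taxon_id = c("diuretic", "diuretic", "antidiab", "diab_tax", "diab_tax",
                 "diab_tax", "anatomy", "bmi_tax", "measures", "measures"),
    stringsAsFactors = FALSE
  )
  ep <- file.path(dir, "entries.tsv")
  tp <- file.path(dir, "taxonomy.tsv")
  utils::write.table(ent, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tax, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(entries = ep, taxonomy = tp)
}

tiny_lexicon <- function() {
  f <- tiny_lexicon_files()
  load_lexicon(f$entries, f$taxonomy)
}

# small jsonl corpus on disk
write_jsonl_corpus <- function(docs, path = tempfile(fileext = ".jsonl")) {
  con <- file(path, "wb")
  for (i in seq_len(nrow(docs))) {
    writeLines(jsonlite::toJSON(
      list(id = docs$doc_id[i], source = docs$source[i],
           title = docs$title[i], body = docs$body[i]), auto_unbox = TRUE),
      con, useBytes = TRUE)
  }
  close(con)
  path
}

make_docs <- function(bodies, titles = rep("", length(bodies)),
                      ids = sprintf("d%02d", seq_along(bodies))) {
  data.frame(doc_id = ids, source = "synthetic", title = titles,
             body = bodies, stringsAsFactors = FALSE)
}

# deterministic two-blob vector set for SOM tests
two_blob_vectors <- function(n = 200, d = 10, sep = 4, seed = 42) {
  set.seed(seed)
  half <- n %/% 2
  X <- rbind(
    matrix(stats::rnorm(half * d, mean = 0), ncol = d),
    matrix(stats::rnorm((n - half) * d, mean = sep), ncol = d)
  )
  rownames(X) <- sprintf("v%03d", seq_len(n))
  attr(X, "labels") <- rep(c(1L, 2L), c(half, n - half))
  X
}
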