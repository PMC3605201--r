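# ---- seeded synthetic world generator ------------------------------------

#' Specification of a synthetic corpus world
#'
#' Controls the generated lexicon/taxonomy, the topic-structured documents,
#' and the planted ground truth (out-of-vocabulary terms with known true
#' hypernyms, term-disease associations, reference term sets).
#'
#' @param seed RNG seed; equal seeds give byte-identical outputs.
#' @param n_topics number of top-level topic branches (max 15).
#' @param n_groups_per_topic synonym groups per topic.
#' @param taxonomy_depth tree depth including the root (2..7).
#' @param n_docs total number of documents (planted + background).
#' @param doc_length_mean,doc_length_dispersion negative-binomial-ish token
#'   budget per document.
#' @param n_planted_unknowns out-of-vocabulary terms planted with a known true
#'   hypernym taxon.
#' @param unknown_signal_ratio ratio of true-taxon tokens to off-taxon noise
#'   tokens in unknown-term evidence documents (> 1).
#' @param unknown_evidence_docs evidence documents per planted unknown.
#' @param n_planted_associations planted term-disease association terms.
#' @param association_strength probability that an association document
#'   mentions the disease (in (0, 1]).
#' @param assoc_docs_range doc-count ramp (min, max) across planted
#'   association terms; counts are log-spaced so doc counts vary by an order
#'   of magnitude, as term frequencies in real collections do.
#' @param n_reference_terms reference terms per relation x disease category.
#' @param docs_per_reference evidence documents generated per reference term.
#' @param background_vocab number of background out-of-vocabulary noise words.
#' @param background_disease_rate fraction of background documents mentioning
#'   a (random) disease. The emulated collection is retrieved by disease
#'   queries, so disease mentions pervade it; incidental term-disease
#'   co-occurrences are therefore spread over heterogeneous documents.
#' @param zipf_exponent Zipf exponent for within-topic term sampling.
#' @return list of class \code{mm_synthetic_spec}.
#' @export
synthetic_spec <- function(seed = 1L, n_topics = 6L, n_groups_per_topic = 25L,
                           taxonomy_depth = 4L, n_docs = 350L,
                           doc_length_mean = 30, doc_length_dispersion = 8,
                           n_planted_unknowns = 10L, unknown_signal_ratio = 3,
                           unknown_evidence_docs = 5L,
                           n_planted_associations = 10L,
                           association_strength = 0.9,
                           assoc_docs_range = c(4L, 30L),
                           n_reference_terms = 8L, docs_per_reference = 3L,
                           background_vocab = 150L,
                           background_disease_rate = 0.5,
                           zipf_exponent = 1.1) {
  stopifnot(n_topics >= 2, n_topics <= 15, taxonomy_depth >= 2,
            taxonomy_depth <= 7, unknown_signal_ratio > 1,
            association_strength > 0, association_strength <= 1,
            n_docs > 0, n_groups_per_topic > 0)
  structure(as.list(environment()), class = "mm_synthetic_spec")
}

topic_label_pool <- function() {
  c("proteins", "hormones", "metabolic disorders", "symptoms", "anatomy",
    "procedures", "genes", "causal agents", "phenotypes", "organisms",
    "chemicals", "methods", "instruments", "environment", "populations")
}

glue_word_pool <- function() {
  c("the", "of", "and", "in", "with", "for", "was", "is", "on", "by",
    "as", "were", "at", "from", "this")
}

# deterministic pronounceable word from an RNG draw
synth_word <- function(n_syllables = 3L) {
  cons <- c("b","d","f","g","k","l","m","n","p","r","s","t","v","z")
  vow <- c("a","e","i","o","u")
  paste0(paste0(sample(cons, n_syllables, TRUE),
                sample(vow, n_syllables, TRUE)), collapse = "")
}

unique_words <- function(n, taken = character(0), n_syllables = 3L) {
  out <- character(0)
  while (length(out) < n) {
    w <- synth_word(n_syllables)
    if (!w %in% taken && !w %in% out) out <- c(out, w)
  }
  out
}

#' Generate a synthetic lexicon, corpus, and ground-truth manifest
#'
#' Builds a balanced taxonomy of the requested depth with one branch per
#' topic, synonym groups attached to the leaf taxa, disease synonym groups
#' ("diabetes", "obesity") under the metabolic-disorders branch, and four
#' kinds of documents: reference-term evidence, planted-association evidence,
#' planted-unknown evidence, and background noise. Topic tokens are sampled
#' Zipf-weighted within each topic. All randomness derives from
#' \code{spec$seed}; equal seeds give byte-identical output files.
#'
#' @param spec an \code{mm_synthetic_spec}.
#' @param dir output directory (created if needed).
#' @return list: paths (entries, taxonomy, corpus, manifest, references),
#'   lexicon, corpus (data.frame), manifest (list).
#' @export
generate_synthetic <- function(spec = synthetic_spec(), dir = tempfile("mmworld")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_local_seed(spec$seed, generate_synthetic_impl(spec, dir))
}

generate_synthetic_impl <- function(spec, dir) {
  n_topics <- spec$n_topics
  topics <- topic_label_pool()[seq_len(n_topics)]
  if (!"metabolic disorders" %in% topics) topics[3] <- "metabolic disorders"

  # ---- taxonomy: root -> topic (level 2) -> binary splits to depth --------
  tax <- data.frame(taxon_id = "t_root", label = "entity", level = 1L,
                    parent_id = "", stringsAsFactors = FALSE)
  leaf_of_topic <- list()
  for (ti in seq_along(topics)) {
    tid <- sprintf("t%02d", ti)
    tax <- rbind(tax, data.frame(taxon_id = tid, label = topics[ti],
                                 level = 2L, parent_id = "t_root"))
    frontier <- tid
    lvl <- 2L
    while (lvl < spec$taxonomy_depth) {
      lvl <- lvl + 1L
      nxt <- character(0)
      for (p in frontier) {
        for (s in 1:2) {
          cid <- sprintf("%s_%d%d", p, lvl, s)
          tax <- rbind(tax, data.frame(
            taxon_id = cid,
            label = paste(topics[ti], "subclass", sub("^t[0-9]+_", "", cid)),
            level = lvl, parent_id = p))
          nxt <- c(nxt, cid)
        }
      }
      frontier <- nxt
    }
    leaf_of_topic[[topics[ti]]] <- frontier
  }
  # function-word branch for glue entries
  tax <- rbind(tax, data.frame(taxon_id = "t_glue", label = "function words",
                               level = 2L, parent_id = "t_root"))

  # disease leaves under the metabolic-disorders branch
  md_leaves <- leaf_of_topic[["metabolic disorders"]]
  dia_parent <- md_leaves[1]
  tax <- rbind(tax,
               data.frame(taxon_id = "t_diabetes", label = "diabetes",
                          level = tax$level[tax$taxon_id == dia_parent][1] + 0L,
                          parent_id = tax$parent_id[tax$taxon_id == dia_parent][1]),
               data.frame(taxon_id = "t_obesity", label = "obesity",
                          level = tax$level[tax$taxon_id == dia_parent][1] + 0L,
                          parent_id = tax$parent_id[tax$taxon_id == dia_parent][1]))

  # ---- lexicon entries ----------------------------------------------------
  entries <- list()
  add_entry <- function(surface, sig, gid, taxon, type = "noun") {
    entries[[length(entries) + 1L]] <<- data.frame(
      surface = surface, word_type = type, language = "en",
      significance = sig, group_id = gid, taxon_id = taxon,
      stringsAsFactors = FALSE)
  }
  taken <- c(glue_word_pool(), "diabetes", "obesity")
  topic_groups <- list()   # topic -> data.frame(group_id, taxon_id, weight)
  for (ti in seq_along(topics)) {
    tp <- topics[ti]
    leaves <- leaf_of_topic[[tp]]
    gids <- character(spec$n_groups_per_topic)
    gtax <- character(spec$n_groups_per_topic)
    words <- unique_words(spec$n_groups_per_topic * 2L, taken)
    taken <- c(taken, words)
    for (gi in seq_len(spec$n_groups_per_topic)) {
      gid <- sprintf("g_%02d_%03d", ti, gi)
      leaf <- leaves[((gi - 1L) %% length(leaves)) + 1L]
      sig <- sample(1:4, 1, prob = c(0.1, 0.3, 0.3, 0.3))
      w1 <- words[2 * gi - 1L]
      add_entry(w1, sig, gid, leaf)
      if (gi %% 3L == 0L) add_entry(words[2 * gi], sig, gid, leaf)
      if (gi %% 6L == 0L) {
        add_entry(paste(w1, "factor"), sig, gid, leaf)
      }
      gids[gi] <- gid
      gtax[gi] <- leaf
    }
    topic_groups[[tp]] <- data.frame(
      group_id = gids, taxon_id = gtax,
      weight = (1 / seq_len(spec$n_groups_per_topic)^spec$zipf_exponent),
      stringsAsFactors = FALSE)
  }
  # glue entries (significance 0)
  for (i in seq_along(glue_word_pool())) {
    add_entry(glue_word_pool()[i], 0L, sprintf("g_glue_%02d", i), "t_glue")
  }
  # disease groups
  add_entry("diabetes", 4L, "g_diabetes", "t_diabetes")
  add_entry("diabetes mellitus", 4L, "g_diabetes", "t_diabetes")
  add_entry("dm2", 4L, "g_diabetes", "t_diabetes")
  add_entry("obesity", 4L, "g_obesity", "t_obesity")
  add_entry("obese", 3L, "g_obesity", "t_obesity")
  add_entry("adiposity", 4L, "g_obesity", "t_obesity")

  diseases <- c(diabetes = "g_diabetes", obesity = "g_obesity")

  # planted association terms: fresh significance-4 groups under qualifying
  # topic leaves (proteins/hormones alternating)
  assoc_topics <- intersect(c("proteins", "hormones"), topics)
  if (!length(assoc_topics)) assoc_topics <- topics[1]
  assoc_words <- unique_words(spec$n_planted_associations, taken, 4L)
  taken <- c(taken, assoc_words)
  assoc <- data.frame(term = assoc_words,
                      group_id = sprintf("g_assoc_%02d",
                                         seq_len(spec$n_planted_associations)),
                      topic = rep(assoc_topics,
                                  length.out = spec$n_planted_associations),
                      disease = rep(c("diabetes", "obesity"),
                                    length.out = spec$n_planted_associations),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(assoc))) {
    leaf <- leaf_of_topic[[assoc$topic[i]]][1]
    add_entry(assoc$term[i], 4L, assoc$group_id[i], leaf)
  }

  entries <- do.call(rbind, entries)
  lex <- new_lexicon(entries, tax)

  # ---- reference term sets ------------------------------------------------
  ref_topic_of <- list(BiomarkerFor = intersect(c("proteins", "hormones"), topics),
                       PhenoTypeOf = intersect(c("symptoms", "anatomy"), topics))
  ref_topic_of <- lapply(ref_topic_of, function(x) if (length(x)) x else topics[1])
  reference_lists <- list()
  for (rel in c("BiomarkerFor", "PhenoTypeOf")) {
    reference_lists[[rel]] <- list()
    # interleave the relation's topics and their frequency ranks so each
    # disease's reference set spans both common and rare meanings
    pools <- topic_groups[ref_topic_of[[rel]]]
    ranks <- lapply(pools, function(p) p$group_id)
    interleaved <- character(0)
    for (r in seq_len(max(lengths(ranks)))) {
      for (p in ranks) if (r <= length(p)) interleaved <- c(interleaved, p[r])
    }
    for (di in seq_along(diseases)) {
      dis <- names(diseases)[di]
      idx <- seq(from = di, by = length(diseases),
                 length.out = spec$n_reference_terms)
      take <- interleaved[idx[idx <= length(interleaved)]]
      reference_lists[[rel]][[dis]] <- unname(lex$group_label[take])
    }
  }

  # ---- planted unknowns ---------------------------------------------------
  plant_leaves <- unlist(lapply(topics, function(tp) leaf_of_topic[[tp]]))
  unknown_words <- unique_words(spec$n_planted_unknowns, taken, 4L)
  taken <- c(taken, unknown_words)
  unknowns <- data.frame(
    term = unknown_words,
    taxon_id = rep(plant_leaves, length.out = spec$n_planted_unknowns),
    stringsAsFactors = FALSE)

  bg_words <- unique_words(spec$background_vocab, taken, 4L)

  # ---- document synthesis -------------------------------------------------
  docs <- list()
  doc_topic <- character(0)
  add_doc <- function(tokens, topic, title_tokens = NULL) {
    id <- sprintf("D%04d", length(docs) + 1L)
    if (is.null(title_tokens)) {
      title_tokens <- tokens[seq_len(min(3L, length(tokens)))]
    }
    docs[[length(docs) + 1L]] <<- data.frame(
      doc_id = id, source = "synthetic",
      title = paste(title_tokens, collapse = " "),
      body = paste(tokens, collapse = " "), stringsAsFactors = FALSE)
    doc_topic <<- c(doc_topic, topic)
    id
  }
  sample_topic_tokens <- function(topic, n) {
    tg <- topic_groups[[topic]]
    gsel <- sample(tg$group_id, n, replace = TRUE, prob = tg$weight)
    surfaces_of_group(gsel, lex)
  }
  glue_tokens <- function(n) sample(glue_word_pool(), n, replace = TRUE)
  disease_tokens <- function(dis, n) {
    surf <- lex$entries$surface[lex$entries$group_id == diseases[[dis]]]
    sample(surf, n, replace = TRUE)
  }
  body_budget <- function() {
    max(12L, stats::rnbinom(1, mu = spec$doc_length_mean,
                            size = spec$doc_length_dispersion))
  }

  # reference evidence docs
  for (rel in names(reference_lists)) {
    for (dis in names(reference_lists[[rel]])) {
      for (term in reference_lists[[rel]][[dis]]) {
        gid <- lookup_term(term, lex)
        tp <- topic_of_group(gid, topic_groups)
        for (r in seq_len(spec$docs_per_reference)) {
          n <- body_budget()
          toks <- c(rep(term, 2L), disease_tokens(dis, 2L),
                    sample_topic_tokens(tp, max(6L, n - 10L)),
                    glue_tokens(5L), sample(bg_words, 1L))
          add_doc(sample(toks), tp, title_tokens = c(term, dis))
        }
      }
    }
  }
  # planted association docs (log-spaced doc-count ramp across terms)
  n_per_assoc <- round(exp(seq(log(spec$assoc_docs_range[1]),
                               log(spec$assoc_docs_range[2]),
                               length.out = nrow(assoc))))
  assoc$n_docs <- as.integer(n_per_assoc)
  for (i in seq_len(nrow(assoc))) {
    for (r in seq_len(assoc$n_docs[i])) {
      n <- body_budget()
      toks <- c(rep(assoc$term[i], 2L),
                sample_topic_tokens(assoc$topic[i], max(6L, n - 10L)),
                glue_tokens(5L), sample(bg_words, 1L))
      with_disease <- stats::runif(1) <= spec$association_strength
      if (with_disease) toks <- c(toks, disease_tokens(assoc$disease[i], 2L))
      add_doc(sample(toks), assoc$topic[i],
              title_tokens = c(assoc$term[i],
                               if (with_disease) assoc$disease[i]))
    }
  }
  # planted unknown evidence docs
  for (i in seq_len(nrow(unknowns))) {
    leaf <- unknowns$taxon_id[i]
    tp <- topics[which(vapply(topics, function(t)
      leaf %in% topic_groups[[t]]$taxon_id, TRUE))][1]
    tg <- topic_groups[[tp]]
    leaf_groups <- tg[tg$taxon_id == leaf, , drop = FALSE]
    other <- do.call(rbind, topic_groups[setdiff(topics, tp)])
    for (r in seq_len(spec$unknown_evidence_docs)) {
      n_signal <- 9L
      n_noise <- max(1L, round(n_signal / spec$unknown_signal_ratio))
      sig_g <- sample(leaf_groups$group_id, n_signal, replace = TRUE,
                      prob = leaf_groups$weight)
      noise_g <- sample(other$group_id, n_noise, replace = TRUE)
      toks <- c(rep(unknowns$term[i], 2L),
                surfaces_of_group(sig_g, lex),
                surfaces_of_group(noise_g, lex),
                glue_tokens(4L))
      add_doc(sample(toks), tp, title_tokens = unknowns$term[i])
    }
  }
  # background docs
  n_bg <- spec$n_docs - length(docs)
  if (n_bg < 0) {
    stop("n_docs (", spec$n_docs, ") smaller than the ", length(docs),
         " planted documents; increase n_docs")
  }
  for (r in seq_len(n_bg)) {
    tp <- sample(topics, 1)
    n <- body_budget()
    toks <- c(sample_topic_tokens(tp, max(8L, n - 8L)), glue_tokens(5L),
              sample(bg_words, sample(1:3, 1)))
    if (stats::runif(1) <= spec$background_disease_rate) {
      toks <- c(toks, disease_tokens(sample(names(diseases), 1), 1L))
    }
    add_doc(sample(toks), tp)
  }
  corpus <- do.call(rbind, docs)

  # ---- serialize ----------------------------------------------------------
  paths <- list(
    entries = file.path(dir, "entries.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    corpus = file.path(dir, "corpus.jsonl"),
    manifest = file.path(dir, "manifest.json"),
    references = character(0)
  )
  write_lexicon(lex, paths$entries, paths$taxonomy)
  con <- file(paths$corpus, open = "wb")
  for (i in seq_len(nrow(corpus))) {
    writeLines(jsonlite::toJSON(list(id = corpus$doc_id[i],
                                     source = corpus$source[i],
                                     title = corpus$title[i],
                                     body = corpus$body[i]),
                                auto_unbox = TRUE), con, useBytes = TRUE)
  }
  close(con)
  for (rel in names(reference_lists)) {
    for (dis in names(reference_lists[[rel]])) {
      p <- file.path(dir, sprintf("reference_%s_%s.txt", rel, dis))
      writeLines(reference_lists[[rel]][[dis]], p)
      paths$references <- c(paths$references, p)
    }
  }
  manifest <- list(
    seed = spec$seed,
    topics = topics,
    planted_unknowns = unknowns,
    planted_associations = assoc[, c("term", "group_id", "disease", "n_docs")],
    reference_terms = reference_lists,
    doc_topics = data.frame(doc_id = corpus$doc_id, topic = doc_topic,
                            stringsAsFactors = FALSE),
    n_docs = nrow(corpus)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       dataframe = "columns", digits = NA)
  list(paths = paths, lexicon = lex, corpus = corpus, manifest = manifest,
       reference_lists = reference_lists, dir = dir)
}

# representative surfaces for sampled group ids (first member surface)
surfaces_of_group <- function(group_ids, lex) {
  unname(lex$group_label[group_ids])
}

topic_of_group <- function(gid, topic_groups) {
  for (tp in names(topic_groups)) {
    if (gid %in% topic_groups[[tp]]$group_id) return(tp)
  }
  names(topic_groups)[1]
}

#' The standard bundled synthetic fixture
#'
#' The deterministic mini-world used throughout the validation suite:
#' 6 topics, 350 documents, 10 planted unknown terms, 10 planted
#' term-disease associations, seed 1.
#'
#' @param dir output directory.
#' @param seed RNG seed (default 1).
#' @return as [generate_synthetic()].
#' @export
standard_fixture <- function(dir = tempfile("mmfixture"), seed = 1L) {
  generate_synthetic(synthetic_spec(seed = seed), dir)
}
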