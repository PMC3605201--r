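# ---- orchestration -------------------------------------------------------

#' Run configuration
#'
#' Collects every tunable constant of the pipeline with its default. All
#' defaults are also accepted from a YAML file via [load_run_config()].
#'
#' @param corpus,entries,taxonomy,references,output_dir file paths; references
#'   is a named list relation -> disease -> path.
#' @param corpus_format "jsonl" or "medline".
#' @param d content-space dimensionality.
#' @param M number of map main topics (NULL: number of topic branches seen).
#' @param som_rows,som_cols,som_epochs map geometry and training length
#'   (NULL geometry: ~10 docs per neuron).
#' @param min_unknown_occurrences occurrence gate for hypernym inference.
#' @param theta hypernym dominance threshold.
#' @param lambda hypernym neighbor-propagation weight.
#' @param tau qualification deviation threshold (NULL: self-calibrated).
#' @param quorum qualification quorum.
#' @param conf_base,conf_beta confidence calibration.
#' @param qualifying_labels candidate-enumeration taxon labels.
#' @param seed master seed.
#' @return list of class \code{mm_run_config}.
#' @export
run_config <- function(corpus = NULL, entries = NULL, taxonomy = NULL,
                       references = NULL, output_dir = NULL,
                       corpus_format = "jsonl",
                       d = 100L, M = NULL, som_rows = NULL, som_cols = NULL,
                       som_epochs = 20L, min_unknown_occurrences = 3L,
                       theta = 1.5, lambda = 0.25, tau = NULL, quorum = 0.5,
                       conf_base = 0.5, conf_beta = 0.15,
                       qualifying_labels = default_qualifying_labels(),
                       seed = 1L) {
  structure(as.list(environment()), class = "mm_run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @return \code{mm_run_config}.
#' @export
load_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, obj)
}

#' Run the full discovery pipeline
#'
#' Chains the five stages — ingest and recognize, categorize on the
#' information map, infer hypernyms for unknown terms, build reference
#' models, discover and score candidates — and writes versioned artifacts
#' into the output directory when one is configured.
#'
#' @param config an \code{mm_run_config}; alternatively pass a generated world
#'   via \code{world} (paths are taken from it).
#' @param world optional result of [generate_synthetic()].
#' @return list: analysis, space, vectors, map, basis, hypernyms, models,
#'   candidates, config.
#' @export
run_pipeline <- function(config = run_config(), world = NULL) {
  if (!is.null(world)) {
    config$entries <- world$paths$entries
    config$taxonomy <- world$paths$taxonomy
    config$corpus <- world$paths$corpus
    config$references <- reference_paths_from_world(world)
  }
  if (is.null(config$corpus)) stop("config$corpus is required")
  lex <- load_lexicon(config$entries, config$taxonomy)
  corpus <- read_corpus(config$corpus, config$corpus_format)
  analysis <- analyze_corpus(corpus, lex)

  space <- build_content_space(analysis, d = config$d)
  vectors <- project_documents(analysis, space)
  map <- fit_infomap(vectors, rows = config$som_rows, cols = config$som_cols,
                     epochs = config$som_epochs, seed = config$seed)
  M <- config$M
  if (is.null(M)) M <- n_branches_present(analysis)
  map <- label_topics(map, analysis, M)

  hypernyms <- infer_hypernyms(analysis, map,
                               min_occurrences = config$min_unknown_occurrences,
                               theta = config$theta, lambda = config$lambda)

  reference_lists <- lapply(config$references, function(by_dis) {
    lapply(by_dis, read_reference_terms)
  })
  basis <- concept_basis(analysis, M)
  models <- build_reference_models(reference_lists, analysis, vectors, map,
                                   basis)
  candidates <- discover_candidates(
    analysis, vectors, map, basis, models, hypernyms, reference_lists,
    qualifying_labels = config$qualifying_labels,
    tau = config$tau, quorum = config$quorum,
    base = config$conf_base, beta = config$conf_beta)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_candidates(candidates, file.path(config$output_dir, "candidates.tsv"))
    write_hypernyms(hypernyms, file.path(config$output_dir, "hypernyms.tsv"))
    write_infomap(map, file.path(config$output_dir, "infomap.json"))
    write_content_space(space, file.path(config$output_dir, "content_space.json"))
    jsonlite::write_json(list(seed = config$seed, M = M, d = length(space$axes),
                              n_docs = nrow(corpus),
                              n_candidates = nrow(candidates)),
                         file.path(config$output_dir, "run_info.json"),
                         auto_unbox = TRUE)
  }
  list(analysis = analysis, space = space, vectors = vectors, map = map,
       basis = basis, hypernyms = hypernyms, models = models,
       candidates = candidates, reference_lists = reference_lists,
       config = config, M = M)
}

# number of distinct top-level branches with non-glue occurrences
n_branches_present <- function(analysis) {
  lex <- analysis$lexicon
  gids <- unique(analysis$doc_groups$group_id)
  gids <- gids[unname(lex$group_sig[gids]) > 0]
  branches <- vapply(gids, function(g) {
    chain <- taxon_chain(lex$group_taxon[[g]], lex)
    b <- chain[lex$taxon_level[chain] == 2L]
    if (length(b)) b[1] else lex$root
  }, "")
  length(unique(branches))
}

reference_paths_from_world <- function(world) {
  out <- list()
  for (p in world$paths$references) {
    m <- regmatches(basename(p),
                    regexec("^reference_([A-Za-z]+)_([a-z]+)\\.txt$", basename(p)))[[1]]
    out[[m[2]]][[m[3]]] <- p
  }
  out
}
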