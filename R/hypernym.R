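# ---- constructed hypernyms for out-of-vocabulary terms -------------------

#' Cross-tabulate an unknown term against known terms
#'
#' The cross-terms are the known, non-glue synonym groups occurring in at
#' least one of the documents that contain the unknown term; occurrence counts
#' are restricted to those evidence documents.
#'
#' @param term unknown term (normalized surface).
#' @param analysis an \code{mm_analysis}.
#' @param min_occurrences the occurrence gate (default 3).
#' @return data.frame(group_id, count) restricted to the evidence documents.
#' @export
cross_tabulate <- function(term, analysis, min_occurrences = 3L) {
  st <- analysis$unknown_stats
  row <- st[st$term == term, ]
  if (!nrow(row) || row$total[1] < min_occurrences) {
    stop("term '", term, "' does not pass the ", min_occurrences,
         "-occurrence gate")
  }
  docs <- analysis$doc_unknowns$doc_id[analysis$doc_unknowns$term == term]
  dg <- analysis$doc_groups
  dg <- dg[dg$doc_id %in% docs, , drop = FALSE]
  dg <- dg[unname(analysis$lexicon$group_sig[dg$group_id]) > 0, , drop = FALSE]
  if (!nrow(dg)) {
    return(data.frame(group_id = character(0), count = integer(0)))
  }
  agg <- stats::aggregate(count ~ group_id, data = dg, FUN = sum)
  agg[order(agg$group_id), , drop = FALSE]
}

# neuron-occupancy sets: cells whose assigned docs contain the key
neurons_containing <- function(doc_ids, map) {
  unique(unname(map$assignments[as.character(doc_ids)]))
}

# group_id -> neuron cells containing it, for the whole analysis
group_cell_index <- function(analysis, map) {
  dg <- analysis$doc_groups
  cells <- unname(map$assignments[dg$doc_id])
  lapply(split(cells, dg$group_id), unique)
}

#' Score candidate hypernyms for an unknown term
#'
#' Each cross-term contributes occ * significance * 1/(1+entropy) * J to the
#' score of its direct hypernym taxon, where J is the neuron-level Jaccard
#' overlap between the unknown term and the cross-term (the disjunct-neuron
#' correction: terms never co-assigned to a neuron contribute nothing).
#' Scores are then propagated: each taxon additionally receives lambda times
#' the summed base scores of its taxonomy-branch neighbors.
#'
#' @param term unknown term.
#' @param cross data.frame(group_id, count) from [cross_tabulate()].
#' @param analysis an \code{mm_analysis}.
#' @param map trained \code{mm_infomap}.
#' @param lambda neighbor-propagation weight (default 0.25).
#' @param group_cells optional precomputed list mapping group_id to the set of
#'   neurons whose documents contain the group (computed when NULL).
#' @return list of class \code{mm_hypernym_table}: \code{scores} (named,
#'   descending), \code{base_scores}, \code{dominance_ratio}.
#' @export
score_hypernyms <- function(term, cross, analysis, map, lambda = 0.25,
                            group_cells = NULL) {
  lex <- analysis$lexicon
  empty <- list(term = term, scores = numeric(0), base_scores = numeric(0),
                dominance_ratio = NA_real_)
  class(empty) <- "mm_hypernym_table"
  if (!nrow(cross)) return(empty)

  u_docs <- analysis$doc_unknowns$doc_id[analysis$doc_unknowns$term == term]
  u_cells <- neurons_containing(u_docs, map)
  H <- stats::setNames(analysis$group_stats$entropy, analysis$group_stats$group_id)
  if (is.null(group_cells)) group_cells <- group_cell_index(analysis, map)

  base <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(cross))) {
    g <- cross$group_id[i]
    c_cells <- group_cells[[g]]
    inter <- length(intersect(u_cells, c_cells))
    uni <- length(union(u_cells, c_cells))
    J <- if (uni > 0) inter / uni else 0
    if (J == 0) next
    contrib <- cross$count[i] * unname(lex$group_sig[g]) /
      (1 + unname(H[g])) * J
    h <- unname(lex$group_taxon[g])
    base[[h]] <- (if (is.null(base[[h]])) 0 else base[[h]]) + contrib
  }
  base_scores <- unlist(as.list(base))
  if (is.null(base_scores) || !length(base_scores)) return(empty)

  # neighbor propagation over base taxa and their branch neighbors
  targets <- unique(c(names(base_scores),
                      unlist(lapply(names(base_scores), branch_neighbors, lex = lex))))
  scores <- vapply(targets, function(h) {
    own <- if (h %in% names(base_scores)) base_scores[[h]] else 0
    nb <- branch_neighbors(h, lex)
    own + lambda * sum(base_scores[intersect(nb, names(base_scores))])
  }, 0)
  scores <- sort(scores, decreasing = TRUE)
  ratio <- if (length(scores) == 1L) Inf else {
    if (scores[2] == 0) Inf else scores[1] / scores[2]
  }
  structure(list(term = term, scores = scores, base_scores = base_scores,
                 dominance_ratio = ratio),
            class = "mm_hypernym_table")
}

#' Select a constructed hypernym from a score table
#'
#' The top taxon is accepted as "is-a" hypernym only when it dominates the
#' runner-up by at least \code{theta}; otherwise the caller should fall back
#' to the associated-descriptor estimate.
#'
#' @param table an \code{mm_hypernym_table}.
#' @param theta dominance threshold (default 1.5).
#' @return list(term, taxon_id, method) with method "hypernym" or
#'   "descriptor_fallback" (taxon NA).
#' @export
select_hypernym <- function(table, theta = 1.5) {
  if (!length(table$scores) || is.na(table$dominance_ratio) ||
      table$dominance_ratio < theta) {
    return(list(term = table$term, taxon_id = NA_character_,
                method = "descriptor_fallback"))
  }
  list(term = table$term, taxon_id = names(table$scores)[1], method = "hypernym")
}

#' Associated descriptor for an unknown term
#'
#' When no hypernym dominates, the descriptors of the documents containing the
#' unknown term are aggregated (per-document descriptor scores summed) and the
#' top-scoring term returned as a loose "is related to" meaning estimate.
#'
#' @param term unknown term.
#' @param analysis an \code{mm_analysis}.
#' @return the descriptor term, or NA when the evidence documents carry none.
#' @export
descriptor_fallback <- function(term, analysis) {
  docs <- unique(analysis$doc_unknowns$doc_id[analysis$doc_unknowns$term == term])
  if (!length(docs)) return(NA_character_)
  agg <- new.env(parent = emptyenv())
  for (d in docs) {
    sc <- descriptor_scores(d, analysis)
    for (i in seq_len(nrow(sc))) {
      t <- sc$term[i]
      agg[[t]] <- (if (is.null(agg[[t]])) 0 else agg[[t]]) + sc$score[i]
    }
  }
  v <- unlist(as.list(agg))
  if (is.null(v) || !length(v)) return(NA_character_)
  v <- v[order(-v, names(v))]
  names(v)[1]
}

#' Construct hypernyms for all gated unknown terms
#'
#' Runs the full inference (cross-tabulation, hypernym scoring with
#' disjunct-neuron correction and neighbor propagation, dominance selection,
#' descriptor fallback) for every unknown term passing the occurrence gate.
#'
#' @param analysis an \code{mm_analysis}.
#' @param map trained \code{mm_infomap}.
#' @param min_occurrences occurrence gate (default 3).
#' @param theta dominance threshold (default 1.5).
#' @param lambda neighbor-propagation weight (default 0.25).
#' @return data.frame(term, taxon_id, taxon_label, descriptor, method,
#'   dominance_ratio, n_docs).
#' @export
infer_hypernyms <- function(analysis, map, min_occurrences = 3L,
                            theta = 1.5, lambda = 0.25) {
  terms <- unknown_terms(analysis, min_occurrences)
  lex <- analysis$lexicon
  gcells <- group_cell_index(analysis, map)
  rows <- lapply(terms, function(u) {
    cross <- cross_tabulate(u, analysis, min_occurrences)
    tab <- score_hypernyms(u, cross, analysis, map, lambda, group_cells = gcells)
    sel <- select_hypernym(tab, theta)
    desc <- if (sel$method == "descriptor_fallback") {
      descriptor_fallback(u, analysis)
    } else NA_character_
    data.frame(
      term = u,
      taxon_id = sel$taxon_id,
      taxon_label = if (is.na(sel$taxon_id)) NA_character_ else
        unname(lex$taxon_label[sel$taxon_id]),
      descriptor = desc,
      method = sel$method,
      dominance_ratio = tab$dominance_ratio,
      n_docs = length(unique(
        analysis$doc_unknowns$doc_id[analysis$doc_unknowns$term == u])),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), taxon_id = character(0),
                      taxon_label = character(0), descriptor = character(0),
                      method = character(0), dominance_ratio = numeric(0),
                      n_docs = integer(0), stringsAsFactors = FALSE)
  }
  out
}

#' Write constructed hypernyms as TSV
#'
#' Columns: unknown_term, constructed_hypernym, associated_descriptor_1.
#'
#' @param hypernyms data.frame from [infer_hypernyms()].
#' @param path output path.
#' @export
write_hypernyms <- function(hypernyms, path) {
  out <- data.frame(unknown_term = hypernyms$term,
                    constructed_hypernym = hypernyms$taxon_label,
                    associated_descriptor_1 = hypernyms$descriptor,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
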