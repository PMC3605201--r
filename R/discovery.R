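# ---- candidate discovery and confidence scoring --------------------------

#' Default qualifying taxonomy-node labels
#'
#' Candidate terms must point (directly or through ancestors / constructed
#' hypernyms) to one of these nodes; subnodes are included transitively.
#'
#' @return character vector of taxon labels.
#' @export
default_qualifying_labels <- function() {
  c("genes", "proteins", "causal agents", "hormones", "phenotypes",
    "metabolic disorders", "diabetes", "obesity", "symptoms")
}

#' Resolve qualifying labels to a transitive taxon set
#'
#' @param lex an \code{mm_lexicon}.
#' @param labels taxon labels (default [default_qualifying_labels()]); labels
#'   absent from the taxonomy are ignored.
#' @return character vector of taxon ids (the named nodes plus all
#'   descendants).
#' @export
qualifying_taxa <- function(lex, labels = default_qualifying_labels()) {
  tax <- lex$taxonomy
  seed <- tax$taxon_id[normalize_text(tax$label) %in% normalize_text(labels)]
  out <- character(0)
  queue <- seed
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur %in% out) next
    out <- c(out, cur)
    queue <- c(queue, tax$taxon_id[tax$parent_id == cur])
  }
  out
}

#' Enumerate candidate terms under the qualifying nodes
#'
#' Known terms qualify when their synonym group's taxon chain intersects the
#' qualifying set; unknown terms qualify through their constructed hypernym.
#' Reference/training terms are retained but flagged.
#'
#' @param analysis an \code{mm_analysis}.
#' @param hypernyms data.frame from [infer_hypernyms()].
#' @param qualifying taxon-id set from [qualifying_taxa()].
#' @param reference_terms character vector of reference terms (flagging only).
#' @return data.frame(term, group_id, taxon_id, origin, is_reference).
#' @export
enumerate_candidates <- function(analysis, hypernyms, qualifying,
                                 reference_terms = character(0)) {
  lex <- analysis$lexicon
  seen_groups <- unique(analysis$doc_groups$group_id)
  seen_groups <- seen_groups[unname(lex$group_sig[seen_groups]) > 0]
  chain_hits <- vapply(seen_groups, function(g) {
    any(taxon_chain(lex$group_taxon[[g]], lex) %in% qualifying)
  }, TRUE)
  known <- data.frame(
    term = unname(lex$group_label[seen_groups[chain_hits]]),
    group_id = seen_groups[chain_hits],
    taxon_id = unname(lex$group_taxon[seen_groups[chain_hits]]),
    origin = "known_lexicon",
    stringsAsFactors = FALSE
  )
  hy <- hypernyms[hypernyms$method == "hypernym" & !is.na(hypernyms$taxon_id), ,
                  drop = FALSE]
  hy_hits <- vapply(hy$taxon_id, function(t) {
    any(taxon_chain(t, lex) %in% qualifying)
  }, TRUE)
  constructed <- data.frame(
    term = hy$term[hy_hits],
    group_id = NA_character_,
    taxon_id = hy$taxon_id[hy_hits],
    origin = rep("constructed_hypernym", sum(hy_hits)),
    stringsAsFactors = FALSE
  )
  out <- rbind(known, constructed)
  ref_groups <- unique(lookup_term(reference_terms, lex))
  ref_groups <- ref_groups[!is.na(ref_groups)]
  out$is_reference <- (!is.na(out$group_id) & out$group_id %in% ref_groups) |
    normalize_text(out$term) %in% normalize_text(reference_terms)
  out <- out[order(out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the evidence subset for a candidate and disease
#'
#' Documents containing the candidate (or any synonym in its group) together
#' with the disease (or any synonym).
#'
#' @param term candidate term (known surface or unknown surface).
#' @param disease disease term.
#' @param analysis an \code{mm_analysis}.
#' @return character vector of doc ids, corpus order.
#' @export
assemble_evidence <- function(term, disease, analysis) {
  docs <- intersect(docs_with_term(term, analysis),
                    docs_with_term(disease, analysis))
  analysis$corpus$doc_id[analysis$corpus$doc_id %in% docs]
}

#' Qualify an evidence subset against a reference model
#'
#' Each evidence document's deviation is its Euclidean distance to the
#' nearest sub-cluster centroid (a document may match any of the reference
#' meanings); the subset qualifies when the fraction of these deviations
#' below \code{tau} reaches the quorum. The reported mean deviation — the
#' confidence-score input — is taken to the single closest sub-cluster (the
#' centroid minimizing the subset's mean distance).
#'
#' @param doc_ids evidence subset (non-empty).
#' @param model an \code{mm_reference_model}.
#' @param vectors,map,basis featurization inputs as in [feature_vectors()].
#' @param tau deviation threshold.
#' @param quorum minimum qualifying fraction (default 0.5; the boundary
#'   fraction itself qualifies).
#' @return list(qualified, mean_deviation, fraction_below, centroid).
#' @export
qualify_candidate <- function(doc_ids, model, vectors, map, basis,
                              tau, quorum = 0.5) {
  FV <- feature_vectors(doc_ids, vectors, map, basis)
  qualify_fv(FV, model, tau, quorum)
}

# core of qualify_candidate on a precomputed feature-vector matrix
qualify_fv <- function(FV, model, tau, quorum = 0.5) {
  D <- vapply(seq_len(nrow(model$centroids)), function(i) {
    sqrt(rowSums((FV - matrix(model$centroids[i, ], nrow(FV),
                              ncol(FV), byrow = TRUE))^2))
  }, numeric(nrow(FV)))
  D <- matrix(D, nrow = nrow(FV))
  # quorum: each document may match any of the reference meanings
  d_nearest <- apply(D, 1, min)
  frac <- mean(d_nearest < tau)
  # confidence input: mean deviation from the closest sub-cluster
  best <- which.min(colMeans(D))
  list(qualified = frac >= quorum, mean_deviation = mean(D[, best]),
       fraction_below = frac, centroid = best)
}

#' Default deviation threshold from a reference model
#'
#' Self-calibrated as the 90th percentile of the model's own member-to-centroid
#' deviations: a subset qualifies when most of its documents sit no farther
#' from a reference meaning than the reference documents themselves.
#'
#' @param model an \code{mm_reference_model}.
#' @param probs quantile (default 0.9).
#' @return tau.
#' @export
calibrate_tau <- function(model, probs = 0.9) {
  unname(stats::quantile(model$member_deviation, probs = probs, names = FALSE))
}

#' Confidence level of a qualified candidate
#'
#' CL = 100 * clip(base * (1 - mean_deviation/d_max) *
#' (1 + beta * log10(1 + doc_count)), 0, 1): strictly decreasing in the mean
#' deviation from the closest reference sub-cluster, nondecreasing in the
#' evidence document count. Setting beta = 0 disables the document-count
#' up-weighting (a documented alternative: the up-weighting inflates generic
#' terms appearing in many documents).
#'
#' @param mean_deviation mean deviation of the evidence subset.
#' @param doc_count number of evidence documents.
#' @param d_max maximum mean deviation over all qualified candidates in the
#'   run.
#' @param base,beta calibration constants (defaults 0.5 and 0.15).
#' @return confidence percent in [0, 100].
#' @export
confidence_level <- function(mean_deviation, doc_count, d_max,
                             base = 0.5, beta = 0.15) {
  if (d_max <= 0) d_max <- 1
  raw <- base * (1 - mean_deviation / d_max) * (1 + beta * log10(1 + doc_count))
  100 * pmin(1, pmax(0, raw))
}

#' Discover and score biomarker/phenotype candidates
#'
#' For every enumerated candidate and every relation x disease category with a
#' reference model: assemble the evidence subset, qualify it against the
#' model, and score qualified candidates with a confidence level. Reference
#' terms are retained, flagged, and reported at CL 100.
#'
#' @param analysis an \code{mm_analysis}.
#' @param vectors content-vector matrix.
#' @param map labeled \code{mm_infomap}.
#' @param basis an \code{mm_concept_basis}.
#' @param models named list of reference models ("relation/disease").
#' @param hypernyms data.frame from [infer_hypernyms()].
#' @param reference_lists named list relation -> disease -> terms (flagging
#'   and CL-100 reporting).
#' @param qualifying_labels taxon labels for candidate enumeration.
#' @param tau deviation threshold; NULL (default) self-calibrates per model
#'   via [calibrate_tau()].
#' @param quorum,base,beta scoring constants (see [qualify_candidate()] and
#'   [confidence_level()]).
#' @param min_docs minimum evidence-subset size (default 2).
#' @return data.frame(term, relation, disease, confidence, n_docs, doc_ids,
#'   mean_deviation, origin, is_reference) sorted by confidence descending.
#' @export
discover_candidates <- function(analysis, vectors, map, basis, models,
                                hypernyms, reference_lists,
                                qualifying_labels = default_qualifying_labels(),
                                tau = NULL, quorum = 0.5,
                                base = 0.5, beta = 0.15, min_docs = 2L) {
  lex <- analysis$lexicon
  qual_taxa <- qualifying_taxa(lex, qualifying_labels)
  all_ref_terms <- unique(unlist(reference_lists, use.names = FALSE))
  cands <- enumerate_candidates(analysis, hypernyms, qual_taxa, all_ref_terms)
  FV_all <- feature_vectors(analysis$corpus$doc_id, vectors, map, basis)
  # evidence subsets are term/disease intersections; precompute both sides
  dis_docs <- lapply(stats::setNames(nm = unique(vapply(models, function(m)
    m$disease, ""))), docs_with_term, analysis = analysis)
  term_docs <- lapply(stats::setNames(nm = unique(cands$term)),
                      docs_with_term, analysis = analysis)
  corpus_order <- analysis$corpus$doc_id
  rows <- list()
  dropped <- 0L
  for (key in names(models)) {
    model <- models[[key]]
    rel <- model$relation
    dis <- model$disease
    tau_m <- if (is.null(tau)) calibrate_tau(model) else tau
    ref_terms_cat <- normalize_text(
      reference_lists[[rel]][[dis]] %||% character(0))
    ref_groups_cat <- unique(lookup_term(ref_terms_cat, lex))
    for (i in seq_len(nrow(cands))) {
      term <- cands$term[i]
      docs <- corpus_order[corpus_order %in%
                             intersect(term_docs[[term]], dis_docs[[dis]])]
      if (length(docs) < min_docs) { dropped <- dropped + 1L; next }
      q <- qualify_fv(FV_all[docs, , drop = FALSE], model, tau_m, quorum)
      if (!q$qualified) { dropped <- dropped + 1L; next }
      is_ref_cat <- (!is.na(cands$group_id[i]) &&
                       cands$group_id[i] %in% ref_groups_cat) ||
        normalize_text(term) %in% ref_terms_cat
      rows[[length(rows) + 1L]] <- data.frame(
        term = term, relation = rel, disease = dis,
        confidence = NA_real_, n_docs = length(docs),
        doc_ids = paste(docs, collapse = ","),
        mean_deviation = q$mean_deviation,
        origin = cands$origin[i],
        is_reference = is_ref_cat,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    message("no candidates qualified (", dropped, " dropped)")
    return(data.frame(term = character(0), relation = character(0),
                      disease = character(0), confidence = numeric(0),
                      n_docs = integer(0), doc_ids = character(0),
                      mean_deviation = numeric(0), origin = character(0),
                      is_reference = logical(0), stringsAsFactors = FALSE))
  }
  d_max <- max(out$mean_deviation)
  out$confidence <- confidence_level(out$mean_deviation, out$n_docs, d_max,
                                     base = base, beta = beta)
  out$confidence[out$is_reference] <- 100
  out <- out[order(-out$confidence, out$term), , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("%d candidate rows qualified, %d dropped", nrow(out), dropped))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the candidate table as TSV
#'
#' Columns term, relationship, object, conf_percent (one decimal), n_docs,
#' doc_ids (first 3 ids, then an ellipsis), sorted by confidence descending
#' with ties broken by term.
#'
#' @param candidates data.frame from [discover_candidates()].
#' @param path output path.
#' @param max_ids how many doc ids to print per row (default 3).
#' @export
write_candidates <- function(candidates, path, max_ids = 3L) {
  fmt_ids <- function(s) {
    ids <- strsplit(s, ",", fixed = TRUE)[[1]]
    if (length(ids) > max_ids) {
      paste0(paste(ids[seq_len(max_ids)], collapse = ","), ",...")
    } else paste(ids, collapse = ",")
  }
  out <- data.frame(
    term = candidates$term,
    relationship = candidates$relation,
    object = candidates$disease,
    conf_percent = sprintf("%.1f", candidates$confidence),
    n_docs = candidates$n_docs,
    doc_ids = vapply(candidates$doc_ids, fmt_ids, "", USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  ord <- order(-as.numeric(out$conf_percent), out$term)
  utils::write.table(out[ord, , drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a candidate TSV back
#'
#' @param path file written by [write_candidates()].
#' @return data.frame with the written columns.
#' @export
read_candidates <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(conf_percent = "numeric"))
}
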