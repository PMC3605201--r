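# ---- reference models (known biomarker/phenotype evidence) ---------------

#' Read a reference term list
#'
#' Plain text, one term per line; additional tab-separated columns are treated
#' as synonyms of the first term.
#'
#' @param path file path.
#' @return character vector of normalized terms (synonyms flattened).
#' @export
read_reference_terms <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  unique(normalize_text(unlist(strsplit(lines, "\t", fixed = TRUE))))
}

# doc ids containing at least one group from `groups`
docs_with_any_group <- function(groups, analysis) {
  groups <- groups[!is.na(groups)]
  dg <- analysis$doc_groups
  unique(dg$doc_id[dg$group_id %in% groups])
}

# terms (or an unknown surface) -> evidence docs; known terms match via their
# whole synonym group, unknown surfaces match verbatim
docs_with_term <- function(term, analysis) {
  gid <- lookup_term(term, analysis$lexicon)
  if (!is.na(gid)) {
    docs_with_any_group(gid, analysis)
  } else {
    du <- analysis$doc_unknowns
    unique(du$doc_id[du$term == normalize_text(term)])
  }
}

#' Retrieve evidence documents for reference terms and a disease
#'
#' Documents containing at least one synonym of a reference term AND at least
#' one synonym of the disease (both resolved through the lexicon's synonym
#' groups).
#'
#' @param reference_terms character vector of reference terms.
#' @param disease disease term (e.g. "diabetes").
#' @param analysis an \code{mm_analysis}.
#' @return character vector of doc ids (corpus order); empty with a warning
#'   when nothing matches.
#' @export
retrieve_evidence <- function(reference_terms, disease, analysis) {
  if (!length(reference_terms)) stop("empty reference term list")
  ref_groups <- unique(lookup_term(reference_terms, analysis$lexicon))
  ref_docs <- docs_with_any_group(ref_groups, analysis)
  dis_docs <- docs_with_term(disease, analysis)
  out <- intersect(ref_docs, dis_docs)
  if (!length(out)) {
    warning("no evidence documents for disease '", disease, "'")
  }
  analysis$corpus$doc_id[analysis$corpus$doc_id %in% out]
}

#' Run-wide concept basis
#'
#' The M concepts (synonym groups) with the highest aggregate descriptor score
#' over the whole collection, together with the min/max scaling fitted over
#' all documents so concept blocks of different subsets stay comparable.
#'
#' @param analysis an \code{mm_analysis}.
#' @param M number of concepts (equal to the number of map main topics).
#' @return list of class \code{mm_concept_basis}: \code{groups}, \code{labels},
#'   \code{score_matrix} (docs x M raw scores), \code{mins}, \code{ranges}.
#' @export
concept_basis <- function(analysis, M) {
  dg <- analysis$doc_groups
  lex <- analysis$lexicon
  sig <- unname(lex$group_sig[dg$group_id])
  H <- stats::setNames(analysis$group_stats$entropy, analysis$group_stats$group_id)
  score <- dg$count * sig / (1 + unname(H[dg$group_id]))
  keep <- sig > 0
  agg <- tapply(score[keep], dg$group_id[keep], sum)
  agg <- sort(agg, decreasing = TRUE)
  if (length(agg) < M) stop("fewer than M scorable concepts in the corpus")
  groups <- names(agg)[seq_len(M)]

  docs <- analysis$corpus$doc_id
  S <- matrix(0, nrow = length(docs), ncol = M,
              dimnames = list(docs, groups))
  sub <- dg[keep & dg$group_id %in% groups, , drop = FALSE]
  if (nrow(sub)) {
    s2 <- sub$count * unname(lex$group_sig[sub$group_id]) /
      (1 + unname(H[sub$group_id]))
    S[cbind(sub$doc_id, sub$group_id)] <- s2
  }
  mins <- apply(S, 2, min)
  ranges <- pmax(apply(S, 2, max) - mins, 1e-12)
  structure(list(groups = groups,
                 labels = unname(lex$group_label[groups]),
                 score_matrix = S, mins = mins, ranges = ranges),
            class = "mm_concept_basis")
}

#' Semantic feature vectors (topic block + concept block)
#'
#' For each document, the M main-topic probabilities followed by the M scaled
#' concept scores: a 2M-component vector (30 when M = 15).
#'
#' @param doc_ids documents to featurize.
#' @param vectors content-vector matrix covering the documents.
#' @param map labeled \code{mm_infomap}.
#' @param basis an \code{mm_concept_basis}.
#' @return matrix (docs x 2M); topic block rows sum to 1, concept block in
#'   [0, 1].
#' @export
feature_vectors <- function(doc_ids, vectors, map, basis) {
  P <- main_topic_matrix(vectors[doc_ids, , drop = FALSE], map)
  C <- basis$score_matrix[doc_ids, , drop = FALSE]
  C <- sweep(sweep(C, 2, basis$mins, "-"), 2, basis$ranges, "/")
  M <- ncol(P)
  out <- cbind(P, C)
  colnames(out) <- c(paste0("topic_", seq_len(M)),
                     paste0("concept_", seq_len(ncol(C))))
  rownames(out) <- doc_ids
  out
}

#' Sub-cluster count rule
#'
#' The number of sub-clusters should not exceed sqrt(n); clamped to [2, 6]
#' (n ~ 50 gives around 5-6 subgroups).
#'
#' @param n number of documents.
#' @return integer k.
#' @export
subcluster_count <- function(n) {
  as.integer(max(2L, min(6L, round(sqrt(n)))))
}

#' Build a reference model for one relation x disease category
#'
#' Average-linkage agglomerative hierarchical clustering (Euclidean distance)
#' of the evidence documents' feature vectors, cut at k = clamp(round(sqrt(n)),
#' 2, 6) sub-clusters; each sub-cluster is summarized by its centroid feature
#' vector, encoding one possible meaning of e.g. "biomarker for diabetes".
#'
#' @param doc_ids evidence documents (n >= 4).
#' @param vectors content-vector matrix.
#' @param map labeled \code{mm_infomap}.
#' @param basis an \code{mm_concept_basis}.
#' @param relation,disease category labels stored on the model.
#' @param k optional sub-cluster count override.
#' @return object of class \code{mm_reference_model}: centroids (k x 2M),
#'   members (list of doc-id vectors), category labels.
#' @export
build_reference_model <- function(doc_ids, vectors, map, basis,
                                  relation = "BiomarkerFor",
                                  disease = "disease", k = NULL) {
  n <- length(doc_ids)
  if (n < 4L) stop("reference subset too small (n = ", n, ", need >= 4)")
  if (is.null(k)) k <- subcluster_count(n)
  FV <- feature_vectors(sort(doc_ids), vectors, map, basis)
  hc <- stats::hclust(stats::dist(FV), method = "average")
  cl <- stats::cutree(hc, k = k)
  members <- split(rownames(FV), cl)
  centroids <- t(vapply(members, function(ids) {
    colMeans(FV[ids, , drop = FALSE])
  }, numeric(ncol(FV))))
  # within-model deviations: each member to its own centroid (for calibration)
  dev <- unlist(lapply(seq_along(members), function(i) {
    sqrt(rowSums((FV[members[[i]], , drop = FALSE] -
                    matrix(centroids[i, ], length(members[[i]]),
                           ncol(FV), byrow = TRUE))^2))
  }))
  structure(list(relation = relation, disease = disease, k = k,
                 centroids = centroids, members = members,
                 member_deviation = unname(dev), n = n),
            class = "mm_reference_model")
}

#' @export
print.mm_reference_model <- function(x, ...) {
  cat("<mm_reference_model>", x$relation, "/", x$disease, ":",
      x$n, "docs in", x$k, "sub-clusters\n")
  invisible(x)
}

#' Build the four relation x disease reference models
#'
#' @param reference_lists named list: relation -> disease -> character vector
#'   of reference terms.
#' @param analysis an \code{mm_analysis}.
#' @param vectors content-vector matrix.
#' @param map labeled \code{mm_infomap}.
#' @param basis an \code{mm_concept_basis}.
#' @return named list of \code{mm_reference_model} ("relation/disease"); empty
#'   categories are dropped with a warning.
#' @export
build_reference_models <- function(reference_lists, analysis, vectors, map,
                                   basis) {
  models <- list()
  for (rel in names(reference_lists)) {
    for (dis in names(reference_lists[[rel]])) {
      docs <- retrieve_evidence(reference_lists[[rel]][[dis]], dis, analysis)
      key <- paste(rel, dis, sep = "/")
      if (length(docs) < 4L) {
        warning("category ", key, " has too few evidence docs (",
                length(docs), "); model skipped")
        next
      }
      models[[key]] <- build_reference_model(docs, vectors, map, basis,
                                             relation = rel, disease = dis)
    }
  }
  models
}
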