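# ---- composite document similarity ---------------------------------------

#' Similarity component weights
#'
#' The composite measure mixes the cosine of the content-space vectors, a
#' capped reciprocal symmetrized Kullback-Leibler distance between main-topic
#' distributions, and a shared synonym/hypernym concept score.
#'
#' @param w_vector,w_topics,w_concepts nonnegative weights summing to 1.
#' @param kl_epsilon floor added to the KL distance before inversion.
#' @param kl_cap cap on the reciprocal (default 1/kl_epsilon).
#' @return list of class \code{mm_sim_weights}.
#' @export
similarity_weights <- function(w_vector = 0.4, w_topics = 0.3, w_concepts = 0.3,
                               kl_epsilon = 1e-3, kl_cap = NULL) {
  if (any(c(w_vector, w_topics, w_concepts) < 0)) stop("weights must be nonnegative")
  if (abs(w_vector + w_topics + w_concepts - 1) > 1e-9) {
    stop("similarity weights must sum to 1")
  }
  if (kl_epsilon <= 0) stop("kl_epsilon must be positive")
  if (is.null(kl_cap)) kl_cap <- 1 / kl_epsilon
  structure(list(w_vector = w_vector, w_topics = w_topics,
                 w_concepts = w_concepts, kl_epsilon = kl_epsilon,
                 kl_cap = kl_cap),
            class = "mm_sim_weights")
}

#' Capped reciprocal symmetrized Kullback-Leibler distance
#'
#' Both distributions are floored at 1e-9 and renormalized; the symmetrized
#' divergence KLsym = (KL(p||q) + KL(q||p)) / 2 is computed in bits, and
#' min(cap, 1 / (eps + KLsym)) returned. Identical distributions score the cap.
#'
#' @param p,q topic probability vectors of equal length.
#' @param eps,cap see [similarity_weights()].
#' @return positive real, symmetric in (p, q).
#' @export
kl_reciprocal <- function(p, q, eps = 1e-3, cap = 1 / eps) {
  if (length(p) != length(q)) stop("topic distributions differ in length")
  p <- pmax(p, 1e-9); p <- p / sum(p)
  q <- pmax(q, 1e-9); q <- q / sum(q)
  klsym <- (sum(p * log2(p / q)) + sum(q * log2(q / p))) / 2
  min(cap, 1 / (eps + klsym))
}

#' Shared-concept score of two documents
#'
#' Counts shared synonym groups, shared direct hypernym taxa, and shared
#' higher-level taxonomy nodes (levels <= shallow_level), weighted alpha, beta,
#' gamma (deeper = weaker), as the cosine of the corresponding weighted
#' indicator vectors; equal term profiles score exactly 1, profiles under
#' disjoint root branches score 0.
#'
#' @param groups_a,groups_b character vectors of synonym-group ids.
#' @param lex an \code{mm_lexicon}.
#' @param alpha,beta,gamma component weights.
#' @param shallow_level maximum taxonomy level counted as "higher node".
#' @return score in [0, 1].
#' @export
common_concept_score <- function(groups_a, groups_b, lex,
                                 alpha = 1, beta = 0.5, gamma = 0.25,
                                 shallow_level = 4L) {
  profile <- function(groups) {
    groups <- unique(groups[!is.na(groups)])
    taxa <- unique(unname(lex$group_taxon[groups]))
    # the universal root (level 1) is shared by everything and carries no
    # signal; shallow nodes are levels 2..shallow_level
    shallow <- unique(unlist(lapply(taxa, function(t) {
      ch <- taxon_chain(t, lex)
      ch[lex$taxon_level[ch] <= shallow_level & lex$taxon_level[ch] >= 2L]
    })))
    list(groups = groups, taxa = taxa, shallow = shallow)
  }
  a <- profile(groups_a); b <- profile(groups_b)
  raw <- function(x, y) {
    alpha * length(intersect(x$groups, y$groups)) +
      beta * length(intersect(x$taxa, y$taxa)) +
      gamma * length(intersect(x$shallow, y$shallow))
  }
  denom <- sqrt(raw(a, a) * raw(b, b))
  if (denom == 0) return(0)
  raw(a, b) / denom
}

#' Composite document similarity
#'
#' w_vector * cosine(v_a, v_b) + w_topics * kl_reciprocal(p_a, p_b)/cap +
#' w_concepts * common_concept_score. Symmetric, bounded in [0, 1], and equal
#' to 1 for documents with identical representations.
#'
#' @param a,b lists with elements \code{vector} (content vector),
#'   \code{topics} (main-topic distribution), \code{groups} (synonym-group
#'   ids of recognized terms).
#' @param lex an \code{mm_lexicon}.
#' @param weights an \code{mm_sim_weights}.
#' @return similarity in [0, 1].
#' @export
document_similarity <- function(a, b, lex, weights = similarity_weights()) {
  na <- sqrt(sum(a$vector^2)); nb <- sqrt(sum(b$vector^2))
  cosine <- if (na > 0 && nb > 0) sum(a$vector * b$vector) / (na * nb) else 0
  klr <- kl_reciprocal(a$topics, b$topics, weights$kl_epsilon, weights$kl_cap)
  ccs <- common_concept_score(a$groups, b$groups, lex)
  weights$w_vector * cosine + weights$w_topics * (klr / weights$kl_cap) +
    weights$w_concepts * ccs
}

#' Document representation for similarity computation
#'
#' Convenience assembler pulling the content vector, main-topic distribution
#' and recognized groups of one document.
#'
#' @param doc_id document id.
#' @param analysis an \code{mm_analysis}.
#' @param vectors content-vector matrix containing the document.
#' @param map labeled \code{mm_infomap}.
#' @return list(vector, topics, groups) for [document_similarity()].
#' @export
doc_representation <- function(doc_id, analysis, vectors, map) {
  dg <- analysis$doc_groups
  list(vector = vectors[doc_id, ],
       topics = main_topics(vectors[doc_id, ], map),
       groups = dg$group_id[dg$doc_id == doc_id])
}
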