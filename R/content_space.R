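# ---- content space -------------------------------------------------------

#' Build the d-dimensional content space
#'
#' Axes are the \code{d} non-glue synonym groups that best discriminate the
#' collection, scored by s(g) = significance(g) * df(g) / (1 + H(g)): frequent
#' but concentrated, highly significant groups win; groups dispersed over many
#' documents (high entropy) are penalized. Significance-0 (glue) groups are
#' never selected.
#'
#' @param analysis an \code{mm_analysis}.
#' @param d number of axes (default 100; reduced with a warning when fewer
#'   eligible groups exist).
#' @return object of class \code{mm_content_space} with \code{axes} (group ids)
#'   and \code{axis_weights}.
#' @export
build_content_space <- function(analysis, d = 100L) {
  st <- analysis$group_stats
  if (!nrow(st)) stop("empty corpus: no recognized groups")
  sig <- analysis$lexicon$group_sig[st$group_id]
  st <- st[sig > 0, , drop = FALSE]
  sig <- sig[sig > 0]
  if (!nrow(st)) stop("no non-glue groups recognized in corpus")
  score <- sig * st$df / (1 + st$entropy)
  ord <- order(-score, st$group_id)
  if (nrow(st) < d) {
    warning(sprintf("only %d eligible groups; reducing d from %d", nrow(st), d))
    d <- nrow(st)
  }
  if (d < 2L) stop("content space needs at least 2 axes")
  take <- ord[seq_len(d)]
  structure(
    list(axes = st$group_id[take],
         axis_weights = unname(score[take])),
    class = "mm_content_space"
  )
}

#' @export
print.mm_content_space <- function(x, ...) {
  cat("<mm_content_space>", length(x$axes), "axes\n")
  invisible(x)
}

#' Project documents into the content space
#'
#' Each component is axis_weight * occurrence count of the axis group in the
#' document, then the vector is L2-normalized (documents with no axis term stay
#' at the origin).
#'
#' @param analysis an \code{mm_analysis}.
#' @param space an \code{mm_content_space}.
#' @param doc_ids documents to project (default: all, in corpus order).
#' @return numeric matrix (docs x d) with doc_ids as rownames.
#' @export
project_documents <- function(analysis, space, doc_ids = NULL) {
  if (is.null(doc_ids)) doc_ids <- analysis$corpus$doc_id
  d <- length(space$axes)
  M <- matrix(0, nrow = length(doc_ids), ncol = d,
              dimnames = list(doc_ids, space$axes))
  dg <- analysis$doc_groups
  dg <- dg[dg$doc_id %in% doc_ids & dg$group_id %in% space$axes, , drop = FALSE]
  if (nrow(dg)) {
    w <- stats::setNames(space$axis_weights, space$axes)
    M[cbind(dg$doc_id, dg$group_id)] <- dg$count * w[dg$group_id]
  }
  nrm <- sqrt(rowSums(M^2))
  nz <- nrm > 0
  M[nz, ] <- M[nz, , drop = FALSE] / nrm[nz]
  M
}

#' Serialize / restore a content space as JSON
#' @param space an \code{mm_content_space}; \code{path} a file path.
#' @rdname content_space_io
#' @export
write_content_space <- function(space, path) {
  jsonlite::write_json(list(axes = space$axes, axis_weights = space$axis_weights),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname content_space_io
#' @export
read_content_space <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(axes = as.character(obj$axes),
                 axis_weights = as.numeric(obj$axis_weights)),
            class = "mm_content_space")
}

# ---- descriptors ---------------------------------------------------------

#' Top descriptors (most relevant keywords) of a document
#'
#' Score = occurrence count * significance / (1 + entropy); glue groups are
#' excluded; ties are broken lexicographically by term label.
#'
#' @param doc_id document id.
#' @param analysis an \code{mm_analysis}.
#' @param k number of descriptors (default 15).
#' @return data.frame(term, group_id, score) in descending score order.
#' @export
top_descriptors <- function(doc_id, analysis, k = 15L) {
  sc <- descriptor_scores(doc_id, analysis)
  utils::head(sc, k)
}

# all descriptor scores of a document (no truncation), descending
descriptor_scores <- function(doc_id, analysis) {
  dg <- analysis$doc_groups
  dg <- dg[dg$doc_id == doc_id, , drop = FALSE]
  lex <- analysis$lexicon
  if (!nrow(dg)) {
    return(data.frame(term = character(0), group_id = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  sig <- unname(lex$group_sig[dg$group_id])
  H <- stats::setNames(analysis$group_stats$entropy, analysis$group_stats$group_id)
  score <- dg$count * sig / (1 + unname(H[dg$group_id]))
  out <- data.frame(term = unname(lex$group_label[dg$group_id]),
                    group_id = dg$group_id, score = score,
                    stringsAsFactors = FALSE)
  out <- out[sig > 0 & score > 0, , drop = FALSE]
  out <- out[order(-out$score, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Main-topic probability distribution of a document
#'
#' pt(m) is a softmax over the squared content-space distance from the document
#' vector to the nearest neuron prototype inside each labeled topic region,
#' with temperature T = mean inter-neuron prototype distance.
#'
#' @param doc_vec a content vector (length d), or a doc id with \code{vectors}.
#' @param map a trained \code{mm_infomap} with topic labels.
#' @param temperature optional override of T.
#' @return numeric vector of length M summing to 1.
#' @export
main_topics <- function(doc_vec, map, temperature = NULL) {
  if (is.null(map$topic_labels)) stop("map has no topic labels; run label_topics()")
  M <- max(map$topic_labels)
  Tm <- if (is.null(temperature)) map$mean_proto_dist else temperature
  if (!is.finite(Tm) || Tm <= 0) Tm <- 1
  d2 <- colSums((t(map$prototypes) - doc_vec)^2)
  dmin <- vapply(seq_len(M), function(m) min(d2[map$topic_labels == m]), 0)
  z <- exp(-dmin / Tm)
  if (sum(z) == 0) z <- rep(1, M)
  z / sum(z)
}

#' Main-topic distributions for a set of documents
#'
#' @param vectors content-vector matrix (docs x d, rownames = doc ids).
#' @param map a labeled \code{mm_infomap}.
#' @return matrix (docs x M), rows summing to 1.
#' @export
main_topic_matrix <- function(vectors, map) {
  t(apply(vectors, 1, main_topics, map = map))
}
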