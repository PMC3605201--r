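# ---- normalization -------------------------------------------------------

#' Normalize free text for lexicon matching
#'
#' Lowercases, strips punctuation (hyphens are kept inside tokens so that
#' truncated forms such as "athero-" survive), and collapses whitespace.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^a-z0-9à-ÿ -]", " ", x)
  x <- gsub("[ ]+", " ", x)
  trimws(x)
}

#' Tokenize normalized text
#'
#' @param x character scalar (normalized or raw; normalization is applied).
#' @return character vector of tokens.
#' @export
tokenize <- function(x) {
  x <- normalize_text(x)
  if (!nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1]]
}

# ---- lexicon construction ------------------------------------------------

new_lexicon <- function(entries, taxonomy) {
  entries$surface <- normalize_text(entries$surface)
  if (any(!nzchar(entries$surface))) stop("lexicon entries with empty surface")
  if (!all(entries$significance %in% 0:4)) {
    stop("entry significance must be an integer rank in 0..4")
  }
  valid_types <- c("noun", "verb", "adjective", "adverb", "name")
  if (!all(entries$word_type %in% valid_types)) {
    bad <- setdiff(unique(entries$word_type), valid_types)
    stop("unknown word_type: ", paste(bad, collapse = ", "))
  }
  # one synonym group per surface+language (longest-match needs a unique hit)
  dup <- duplicated(entries[, c("surface", "language")])
  if (any(dup)) {
    entries <- entries[!dup, , drop = FALSE]
  }

  taxonomy$parent_id[is.na(taxonomy$parent_id)] <- ""
  roots <- taxonomy$taxon_id[taxonomy$parent_id == ""]
  if (length(roots) != 1L) {
    stop("taxonomy must have exactly one root, found ", length(roots))
  }
  if (anyDuplicated(taxonomy$taxon_id)) stop("duplicate taxon_id in taxonomy")
  unknown_parent <- setdiff(setdiff(taxonomy$parent_id, ""), taxonomy$taxon_id)
  if (length(unknown_parent)) {
    stop("taxonomy parent not defined: ", paste(unknown_parent, collapse = ", "))
  }
  if (any(taxonomy$level < 1 | taxonomy$level > 7)) {
    stop("taxonomy levels must lie in 1..7")
  }

  parent_of <- stats::setNames(taxonomy$parent_id, taxonomy$taxon_id)
  # cycle / depth check by walking every node to the root
  for (tid in taxonomy$taxon_id) {
    seen <- character(0)
    cur <- tid
    while (nzchar(cur)) {
      if (cur %in% seen) stop("cycle in taxonomy involving taxon '", cur, "'")
      seen <- c(seen, cur)
      if (length(seen) > 7L) stop("taxonomy deeper than 7 levels at '", tid, "'")
      cur <- parent_of[[cur]]
    }
  }

  # group table: group_id -> taxon, significance (max over members), label
  grp_split <- split(seq_len(nrow(entries)), entries$group_id)
  groups <- data.frame(
    group_id = names(grp_split),
    taxon_id = vapply(grp_split, function(i) entries$taxon_id[i[1]], ""),
    significance = vapply(grp_split, function(i) max(entries$significance[i]), 0),
    stringsAsFactors = FALSE
  )
  # group label: the most significant member, alphabetical tie-break
  groups$label <- vapply(grp_split, function(i) {
    e <- entries[i, , drop = FALSE]
    e <- e[order(-e$significance, e$surface), , drop = FALSE]
    e$surface[1]
  }, "")
  mismatch <- vapply(grp_split, function(i) {
    length(unique(entries$taxon_id[i])) > 1L
  }, TRUE)
  if (any(mismatch)) {
    stop("synonym group linked to multiple taxa: ",
         paste(names(grp_split)[mismatch], collapse = ", "))
  }
  dangling <- setdiff(groups$taxon_id, taxonomy$taxon_id)
  if (length(dangling)) {
    bad <- groups$group_id[groups$taxon_id %in% dangling]
    stop("group(s) linked to unknown taxon: ", paste(bad, collapse = ", "))
  }

  # fast lookup structures
  surface_env <- new.env(parent = emptyenv(), size = max(64L, nrow(entries)))
  for (i in seq_len(nrow(entries))) {
    assign(entries$surface[i], entries$group_id[i], envir = surface_env)
  }
  ntok <- lengths(strsplit(entries$surface, " ", fixed = TRUE))

  structure(
    list(
      entries = entries,
      groups = groups,
      taxonomy = taxonomy,
      root = roots,
      surface_env = surface_env,
      max_phrase_len = max(ntok, 1L),
      parent_of = parent_of,
      taxon_level = stats::setNames(taxonomy$level, taxonomy$taxon_id),
      taxon_label = stats::setNames(taxonomy$label, taxonomy$taxon_id),
      group_taxon = stats::setNames(groups$taxon_id, groups$group_id),
      group_sig = stats::setNames(groups$significance, groups$group_id),
      group_label = stats::setNames(groups$label, groups$group_id)
    ),
    class = "mm_lexicon"
  )
}

#' Load a lexicon and taxonomy from TSV files
#'
#' The entry file has columns \code{surface, word_type, language, significance,
#' group_id}; the taxonomy file has \code{taxon_id, label, level, parent_id}
#' (empty parent for the root). Entries are grouped into synonym groups, each
#' linked to one hypernym taxon in an acyclic tree of depth at most 7.
#'
#' @param entries_path path to the entry TSV (with header).
#' @param taxonomy_path path to the taxonomy TSV (with header).
#' @return an object of class \code{mm_lexicon}.
#' @export
load_lexicon <- function(entries_path, taxonomy_path) {
  entries <- utils::read.delim(entries_path, stringsAsFactors = FALSE,
                               colClasses = "character", quote = "")
  entries$significance <- as.integer(entries$significance)
  # the group->taxon link rides on the entry rows
  if (!"taxon_id" %in% names(entries)) {
    stop("entry file must carry a taxon_id column linking each group to a taxon")
  }
  taxonomy <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE,
                                colClasses = "character", quote = "")
  taxonomy$level <- as.integer(taxonomy$level)
  new_lexicon(entries, taxonomy)
}

#' Write a lexicon back to entry/taxonomy TSV files
#'
#' Inverse of [load_lexicon()] up to row order; used for round-trip checks and
#' to persist generated fixtures.
#'
#' @param lex an \code{mm_lexicon}.
#' @param entries_path,taxonomy_path output paths.
#' @return invisibly, the two paths.
#' @export
write_lexicon <- function(lex, entries_path, taxonomy_path) {
  utils::write.table(lex$entries, entries_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(lex$taxonomy, taxonomy_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(entries_path, taxonomy_path))
}

#' @export
print.mm_lexicon <- function(x, ...) {
  cat("<mm_lexicon>", nrow(x$entries), "entries,",
      nrow(x$groups), "synonym groups,",
      nrow(x$taxonomy), "taxa (root:", x$root, ")\n")
  invisible(x)
}

# ---- lookups -------------------------------------------------------------

#' Resolve a normalized phrase to its synonym group
#'
#' @param phrase character vector of phrases (normalization applied).
#' @param lex an \code{mm_lexicon}.
#' @return character vector of group ids, \code{NA} where absent.
#' @export
lookup_term <- function(phrase, lex) {
  phrase <- normalize_text(phrase)
  vapply(phrase, function(p) {
    if (nzchar(p) && exists(p, envir = lex$surface_env, inherits = FALSE)) {
      get(p, envir = lex$surface_env, inherits = FALSE)
    } else NA_character_
  }, NA_character_, USE.NAMES = FALSE)
}

#' Ancestor chain of a taxon
#'
#' @param taxon_id a taxon id.
#' @param lex an \code{mm_lexicon}.
#' @return character vector of taxon ids from the direct parent up to the root
#'   (empty for the root itself).
#' @export
taxon_ancestors <- function(taxon_id, lex) {
  if (!taxon_id %in% lex$taxonomy$taxon_id) {
    stop("unknown taxon: ", taxon_id)
  }
  out <- character(0)
  cur <- lex$parent_of[[taxon_id]]
  while (nzchar(cur)) {
    out <- c(out, cur)
    cur <- lex$parent_of[[cur]]
  }
  out
}

#' Taxonomy-branch neighbors of a taxon
#'
#' Siblings (same parent), the direct parent, and the direct children; the
#' taxon itself is excluded. Used for hypernym score propagation.
#'
#' @param taxon_id a taxon id.
#' @param lex an \code{mm_lexicon}.
#' @return character vector of neighbor taxon ids.
#' @export
branch_neighbors <- function(taxon_id, lex) {
  if (!taxon_id %in% lex$taxonomy$taxon_id) {
    stop("unknown taxon: ", taxon_id)
  }
  tax <- lex$taxonomy
  parent <- lex$parent_of[[taxon_id]]
  sibs <- tax$taxon_id[tax$parent_id == parent & nzchar(parent)]
  kids <- tax$taxon_id[tax$parent_id == taxon_id]
  out <- unique(c(if (nzchar(parent)) parent, sibs, kids))
  setdiff(out, taxon_id)
}

# direct taxon of a group id (vectorized); NA-safe
group_taxon <- function(group_id, lex) {
  unname(lex$group_taxon[group_id])
}

# taxon chain including the taxon itself
taxon_chain <- function(taxon_id, lex) c(taxon_id, taxon_ancestors(taxon_id, lex))
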