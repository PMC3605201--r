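# ---- corpus readers ------------------------------------------------------

#' Read a document corpus
#'
#' Two on-disk formats are supported: JSON-lines (one object per line with
#' fields \code{id}, \code{source}, \code{title}, \code{body}) and MEDLINE-style
#' flat abstracts (records separated by blank lines with \code{PMID-},
#' \code{TI -}, \code{AB -} field prefixes).
#'
#' @param path input file.
#' @param format "jsonl" or "medline".
#' @return data.frame with columns doc_id, source, title, body, in file order.
#' @export
read_corpus <- function(path, format = c("jsonl", "medline")) {
  format <- match.arg(format)
  docs <- switch(format,
    jsonl = read_corpus_jsonl(path),
    medline = read_corpus_medline(path)
  )
  dup <- unique(docs$doc_id[duplicated(docs$doc_id)])
  if (length(dup)) {
    stop("duplicate doc_id in corpus: ", paste(dup, collapse = ", "))
  }
  message(sprintf("read %d documents from %s", nrow(docs), path))
  docs
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("malformed JSONL record at line ",
                                             i, ": ", conditionMessage(e)))
    if (is.null(rec$id)) stop("missing 'id' in JSONL record at line ", i)
    recs[[i]] <- data.frame(
      doc_id = as.character(rec$id),
      source = if (is.null(rec$source)) "internal" else as.character(rec$source),
      title = if (is.null(rec$title)) "" else as.character(rec$title),
      body = if (is.null(rec$body)) "" else as.character(rec$body),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, recs)
}

read_corpus_medline <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- list()
  cur <- NULL
  field <- ""
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$PMID)) return(NULL)
    data.frame(doc_id = cur$PMID, source = "pubmed",
               title = if (is.null(cur$TI)) "" else cur$TI,
               body = if (is.null(cur$AB)) "" else cur$AB,
               stringsAsFactors = FALSE)
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      r <- flush(cur); if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      cur <- NULL; field <- ""
      next
    }
    m <- regmatches(ln, regexec("^([A-Z]{2,4})\\s*-\\s?(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      field <- m[2]
      if (is.null(cur)) cur <- list()
      cur[[field]] <- paste(c(cur[[field]], m[3]), collapse = " ")
    } else if (grepl("^\\s+", ln) && nzchar(field) && !is.null(cur)) {
      cur[[field]] <- paste(cur[[field]], trimws(ln))
    } else {
      stop("malformed MEDLINE line: ", substr(ln, 1, 60))
    }
  }
  r <- flush(cur); if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  if (!length(recs)) stop("no MEDLINE records found in ", path)
  do.call(rbind, recs)
}

# ---- term recognition ----------------------------------------------------

#' Recognize lexicon terms in one document
#'
#' Scans the title + body token stream with longest-match semantics: at each
#' position the longest phrase present in the lexicon is consumed as one
#' occurrence of its synonym group. Tokens matching nothing are collected as
#' unknown terms (tokens shorter than \code{min_unknown_nchar} characters are
#' treated as noise and dropped).
#'
#' @param doc a one-row corpus data.frame (or list with title/body).
#' @param lex an \code{mm_lexicon}.
#' @param min_unknown_nchar noise floor for unknown tokens.
#' @return list(known = named count vector by group_id,
#'   unknown = named count vector by term).
#' @export
recognize_terms <- function(doc, lex, min_unknown_nchar = 3L) {
  toks <- c(tokenize(doc$title), tokenize(doc$body))
  n <- length(toks)
  known <- character(0)
  unknown <- character(0)
  i <- 1L
  maxlen <- lex$max_phrase_len
  env <- lex$surface_env
  while (i <= n) {
    hit <- FALSE
    for (L in seq.int(min(maxlen, n - i + 1L), 1L)) {
      phrase <- paste(toks[i:(i + L - 1L)], collapse = " ")
      if (exists(phrase, envir = env, inherits = FALSE)) {
        known <- c(known, get(phrase, envir = env, inherits = FALSE))
        i <- i + L
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      if (nchar(toks[i]) >= min_unknown_nchar) unknown <- c(unknown, toks[i])
      i <- i + 1L
    }
  }
  list(
    known = if (length(known)) table_to_counts(known) else integer(0),
    unknown = if (length(unknown)) table_to_counts(unknown) else integer(0)
  )
}

table_to_counts <- function(x) {
  tb <- table(x)
  stats::setNames(as.integer(tb), names(tb))
}

#' Analyze a corpus against a lexicon
#'
#' Runs [recognize_terms()] over every document and aggregates per-term
#' statistics (document frequency, total occurrences, Shannon entropy of the
#' occurrence distribution across documents, in bits).
#'
#' @param corpus corpus data.frame from [read_corpus()].
#' @param lex an \code{mm_lexicon}.
#' @return object of class \code{mm_analysis} with long-format occurrence
#'   tables \code{doc_groups} (doc_id, group_id, count) and \code{doc_unknowns}
#'   (doc_id, term, count) plus aggregated \code{group_stats} and
#'   \code{unknown_stats}.
#' @export
analyze_corpus <- function(corpus, lex) {
  if (!nrow(corpus)) stop("empty corpus")
  kg <- vector("list", nrow(corpus))
  ku <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    rec <- recognize_terms(corpus[i, ], lex)
    if (length(rec$known)) {
      kg[[i]] <- data.frame(doc_id = corpus$doc_id[i],
                            group_id = names(rec$known),
                            count = unname(rec$known),
                            stringsAsFactors = FALSE)
    }
    if (length(rec$unknown)) {
      ku[[i]] <- data.frame(doc_id = corpus$doc_id[i],
                            term = names(rec$unknown),
                            count = unname(rec$unknown),
                            stringsAsFactors = FALSE)
    }
  }
  doc_groups <- do.call(rbind, kg[!vapply(kg, is.null, TRUE)])
  doc_unknowns <- do.call(rbind, ku[!vapply(ku, is.null, TRUE)])
  if (is.null(doc_groups)) {
    doc_groups <- data.frame(doc_id = character(0), group_id = character(0),
                             count = integer(0))
  }
  if (is.null(doc_unknowns)) {
    doc_unknowns <- data.frame(doc_id = character(0), term = character(0),
                               count = integer(0))
  }
  structure(
    list(
      corpus = corpus,
      lexicon = lex,
      doc_groups = doc_groups,
      doc_unknowns = doc_unknowns,
      group_stats = occurrence_stats(doc_groups, "group_id"),
      unknown_stats = occurrence_stats(doc_unknowns, "term")
    ),
    class = "mm_analysis"
  )
}

#' @export
print.mm_analysis <- function(x, ...) {
  cat("<mm_analysis>", nrow(x$corpus), "documents;",
      nrow(x$group_stats), "known groups;",
      nrow(x$unknown_stats), "unknown terms\n")
  invisible(x)
}

# per-term df / total / entropy from a long (doc, key, count) table
occurrence_stats <- function(long, key) {
  if (!nrow(long)) {
    out <- data.frame(key = character(0), df = integer(0), total = integer(0),
                      entropy = numeric(0), stringsAsFactors = FALSE)
    names(out)[1] <- key
    return(out)
  }
  sp <- split(long$count, long[[key]])
  out <- data.frame(
    key = names(sp),
    df = lengths(sp),
    total = vapply(sp, sum, 0L),
    entropy = vapply(sp, shannon_bits, 0),
    stringsAsFactors = FALSE
  )
  names(out)[1] <- key
  rownames(out) <- NULL
  out
}

shannon_bits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy of a term's occurrence distribution over documents
#'
#' H = -sum_d p_d log2 p_d with p_d the share of the term's occurrences falling
#' in document d. Terms spread evenly over many documents have high entropy and
#' low discriminating power.
#'
#' @param term a normalized term (known or unknown) or a group id.
#' @param analysis an \code{mm_analysis}.
#' @return entropy in bits.
#' @export
term_entropy <- function(term, analysis) {
  gid <- lookup_term(term, analysis$lexicon)
  if (!is.na(gid)) {
    row <- analysis$group_stats[analysis$group_stats$group_id == gid, ]
    if (nrow(row)) return(row$entropy[1])
    stop("term '", term, "' is in the lexicon but unseen in this corpus")
  }
  key <- normalize_text(term)
  row <- analysis$unknown_stats[analysis$unknown_stats$term == key, ]
  if (!nrow(row)) {
    # allow direct group-id addressing
    row <- analysis$group_stats[analysis$group_stats$group_id == term, ]
    names(row)[1] <- "term"
  }
  if (!nrow(row)) stop("unseen term: ", term)
  row$entropy[1]
}

#' Unknown terms passing the occurrence gate
#'
#' @param analysis an \code{mm_analysis}.
#' @param min_occurrences minimum corpus-wide occurrence count (default 3).
#' @return sorted character vector of unknown terms.
#' @export
unknown_terms <- function(analysis, min_occurrences = 3L) {
  st <- analysis$unknown_stats
  sort(st$term[st$total >= min_occurrences])
}
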