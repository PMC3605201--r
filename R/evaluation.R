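# ---- benchmark matching and metrics --------------------------------------

#' Normalize a term into a comparison key
#'
#' Lowercases and removes all whitespace and punctuation, so "DM-2", "dm2"
#' and "DM 2" share one key. Idempotent.
#'
#' @param term character vector.
#' @return character vector of keys.
#' @export
normalize_key <- function(term) {
  gsub("[^a-z0-9]", "", tolower(as.character(term)))
}

#' Read a benchmark vocabulary (preferred term + synonyms) from TSV
#'
#' One line per entry: preferred term, then tab-separated synonyms.
#'
#' @param path file path.
#' @param source_label label stored on the object.
#' @return object of class \code{mm_benchmark}: data.frame(term, preferred,
#'   is_preferred).
#' @export
read_benchmark <- function(path, source_label = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  rows <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    data.frame(term = parts, preferred = parts[1],
               is_preferred = seq_along(parts) == 1L,
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  if (anyDuplicated(normalize_key(entries$preferred[entries$is_preferred]))) {
    stop("duplicate preferred terms in benchmark after normalization")
  }
  structure(list(entries = entries, source = source_label),
            class = "mm_benchmark")
}

benchmark_from_list <- function(entries, source_label = "benchmark") {
  # entries: named list preferred -> character vector of synonyms
  rows <- lapply(names(entries), function(p) {
    terms <- unique(c(p, entries[[p]]))
    data.frame(term = terms, preferred = p,
               is_preferred = seq_along(terms) == 1L, stringsAsFactors = FALSE)
  })
  structure(list(entries = do.call(rbind, rows), source = source_label),
            class = "mm_benchmark")
}

# partial match: one key's token set strictly contained in the other's
is_partial_match <- function(tokens_a, tokens_b) {
  sa <- unique(tokens_a); sb <- unique(tokens_b)
  (all(sa %in% sb) && length(sa) < length(sb)) ||
    (all(sb %in% sa) && length(sb) < length(sa))
}

#' Match candidate terms against a benchmark vocabulary
#'
#' Exact matches compare normalized keys; in match_type "all", partial matches
#' (the token set of one term strictly contained in the other's) are added.
#' Counting "preferred" conflates benchmark synonyms to their preferred term
#' before counting matched benchmark entries; counting "all" counts each
#' synonym separately.
#'
#' @param terms character vector of candidate terms.
#' @param benchmark an \code{mm_benchmark}.
#' @param match_type "exact" or "all" (exact + partial).
#' @param counting "preferred" or "all".
#' @return list: \code{pairs} (candidate, benchmark term, kind),
#'   \code{matched_candidates}, \code{matched_benchmark} (preferred terms or
#'   synonyms according to counting), \code{benchmark_total}.
#' @export
match_benchmark <- function(terms, benchmark,
                            match_type = c("all", "exact"),
                            counting = c("preferred", "all")) {
  match_type <- match.arg(match_type)
  counting <- match.arg(counting)
  terms <- unique(terms)
  keys <- normalize_key(terms)
  be <- benchmark$entries
  bkeys <- normalize_key(be$term)
  btoks <- strsplit(normalize_text(be$term), " ", fixed = TRUE)
  ctoks <- strsplit(normalize_text(terms), " ", fixed = TRUE)

  pairs <- list()
  for (i in seq_along(terms)) {
    exact <- which(bkeys == keys[i])
    for (j in exact) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        candidate = terms[i], benchmark_term = be$term[j], kind = "exact",
        stringsAsFactors = FALSE)
    }
    if (match_type == "all") {
      rest <- setdiff(seq_len(nrow(be)), exact)
      part <- rest[vapply(rest, function(j) {
        is_partial_match(ctoks[[i]], btoks[[j]])
      }, TRUE)]
      for (j in part) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          candidate = terms[i], benchmark_term = be$term[j], kind = "partial",
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(candidate = character(0), benchmark_term = character(0),
               kind = character(0), stringsAsFactors = FALSE)
  pref <- stats::setNames(be$preferred, be$term)
  if (counting == "preferred") {
    matched_benchmark <- unique(unname(pref[pairs$benchmark_term]))
    benchmark_total <- length(unique(be$preferred))
  } else {
    matched_benchmark <- unique(pairs$benchmark_term)
    benchmark_total <- nrow(be)
  }
  list(pairs = pairs,
       matched_candidates = unique(pairs$candidate),
       matched_benchmark = matched_benchmark,
       benchmark_total = benchmark_total,
       match_type = match_type, counting = counting)
}

round_half_up <- function(x) floor(x + 0.5)

#' Precision / recall / novelty from match counts
#'
#' precision = 100 * matched / total_outputs; recall = 100 * benchmark_matched
#' / (benchmark_matched + benchmark_missed); novelty = 100 - precision.
#' Report percents are rounded half-up to integers; raw values are retained.
#' Zero denominators yield NA fields rather than errors.
#'
#' @param matched candidate outputs matched by the benchmark.
#' @param total_outputs total candidate outputs.
#' @param benchmark_matched benchmark entries matched by the outputs.
#' @param benchmark_missed benchmark entries not matched.
#' @return list of class \code{mm_metrics}: matched, total_outputs,
#'   benchmark_matched, benchmark_missed, precision, recall, novelty
#'   (integers) and precision_raw, recall_raw, novelty_raw.
#' @export
compute_metrics <- function(matched, total_outputs, benchmark_matched,
                            benchmark_missed) {
  stopifnot(matched >= 0, total_outputs >= 0, benchmark_matched >= 0,
            benchmark_missed >= 0, matched <= total_outputs)
  precision_raw <- if (total_outputs > 0) 100 * matched / total_outputs else NA_real_
  denom <- benchmark_matched + benchmark_missed
  recall_raw <- if (denom > 0) 100 * benchmark_matched / denom else NA_real_
  novelty_raw <- if (is.na(precision_raw)) NA_real_ else 100 - precision_raw
  as_int <- function(x) if (is.na(x)) NA_integer_ else as.integer(round_half_up(x))
  structure(list(
    matched = matched, total_outputs = total_outputs,
    benchmark_matched = benchmark_matched, benchmark_missed = benchmark_missed,
    precision = as_int(precision_raw), recall = as_int(recall_raw),
    novelty = as_int(novelty_raw),
    precision_raw = precision_raw, recall_raw = recall_raw,
    novelty_raw = novelty_raw
  ), class = "mm_metrics")
}

#' @export
print.mm_metrics <- function(x, ...) {
  cat(sprintf("precision = %s%%; recall = %s%%; novelty = %s%%\n",
              x$precision, x$recall, x$novelty))
  invisible(x)
}

#' Evaluate a candidate list against a benchmark
#'
#' @param terms candidate terms.
#' @param benchmark an \code{mm_benchmark}.
#' @param match_type,counting see [match_benchmark()].
#' @return \code{mm_metrics}.
#' @export
evaluate_candidates <- function(terms, benchmark,
                                match_type = c("all", "exact"),
                                counting = c("preferred", "all")) {
  m <- match_benchmark(terms, benchmark, match_type, counting)
  compute_metrics(length(m$matched_candidates), length(unique(terms)),
                  length(m$matched_benchmark),
                  m$benchmark_total - length(m$matched_benchmark))
}

#' Triage candidates against a sorted lexicon dump
#'
#' Each candidate receives exactly one label with precedence exact >
#' left_substring > between_2 (all on normalized keys): exact when the key is
#' present in the dump; left_substring when some dump term extends the
#' candidate as a prefix; otherwise between_2 (the candidate sorts strictly
#' between two dump terms with neither relation).
#'
#' @param terms candidate terms.
#' @param dump character vector of lexicon terms (any order; sorted
#'   internally).
#' @return character vector of labels, one per candidate.
#' @export
triage_match <- function(terms, dump) {
  if (!length(dump)) stop("empty lexicon dump")
  dkeys <- sort(unique(normalize_key(dump)))
  keys <- normalize_key(terms)
  vapply(keys, function(k) {
    if (k %in% dkeys) return("exact")
    hit <- dkeys[startsWith(dkeys, k)]
    if (length(hit)) return("left_substring")
    "between_2"
  }, "", USE.NAMES = FALSE)
}

#' Count / percent distribution of triage labels
#'
#' @param labels character vector of labels (or a named count vector).
#' @param levels optional label order for the report.
#' @return data.frame(label, count, percent) with integer percents rounded
#'   half-up.
#' @export
distribution_report <- function(labels,
                                levels = c("exact", "left_substring",
                                           "between_2")) {
  if (is.numeric(labels)) {
    counts <- labels
    if (is.null(names(counts))) names(counts) <- levels[seq_along(counts)]
  } else {
    counts <- table(factor(labels, levels = union(levels, unique(labels))))
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  total <- sum(counts)
  data.frame(label = names(counts), count = unname(counts),
             percent = as.integer(round_half_up(100 * unname(counts) / total)),
             stringsAsFactors = FALSE)
}

#' Benchmark match-scoring summary
#'
#' Reproduces the match-scoring arithmetic used when comparing a candidate
#' list against a curated biomarker knowledge base: precision, recall and
#' novelty from the match/miss counts, plus the share of candidates judged
#' testable hypotheses and the share confirmed on pathway maps.
#'
#' @param total total candidate records.
#' @param benchmark_matches candidates matching known benchmark entries.
#' @param missed known benchmark entries missed.
#' @param testable candidates judged new testable hypotheses.
#' @param pathway_confirmed testable candidates confirmed on pathway maps.
#' @return list: precision, recall, novelty, testable_share, confirmed_share
#'   (integer percents).
#' @export
match_scoring_summary <- function(total, benchmark_matches, missed, testable,
                                  pathway_confirmed) {
  if (benchmark_matches > total || testable > total || pathway_confirmed > total) {
    stop("inconsistent counts: components exceed total")
  }
  m <- compute_metrics(benchmark_matches, total, benchmark_matches, missed)
  list(precision = m$precision, recall = m$recall, novelty = m$novelty,
       testable_share = as.integer(round_half_up(100 * testable / total)),
       confirmed_share = as.integer(round_half_up(100 * pathway_confirmed / total)))
}
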