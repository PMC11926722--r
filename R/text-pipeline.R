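#' Sentiment lexicon
#'
#' A transparent dictionary scorer: three pairwise-disjoint sets of lowercase
#' terms (negative, positive, stopwords). Terms ending in `*` are prefix
#' stems (e.g. `regn*` matches `regnet`), following the usual dictionary
#' convention of word-count text analysis tools. The lexicon scorer is a
#' pluggable stand-in for any external sentiment classifier: documents
#' labelled by another model can be fed to [aggregate_panel()] directly.
#'
#' @param negative_terms,positive_terms,stopwords character vectors of
#'   lowercase terms without whitespace.
#' @return a `lexicon` object.
#' @export
lexicon <- function(negative_terms, positive_terms, stopwords = character(0)) {
  sets <- list(negative_terms = unique(as.character(negative_terms)),
               positive_terms = unique(as.character(positive_terms)),
               stopwords = unique(as.character(stopwords)))
  for (nm in names(sets)) {
    s <- sets[[nm]]
    if (any(grepl("\\s", s))) stop(nm, " must not contain whitespace")
    if (any(s != tolower(s))) stop(nm, " must be lowercase")
  }
  base <- lapply(sets, function(s) sub("\\*$", "", s))
  if (length(intersect(base$negative_terms, base$positive_terms)) ||
      length(intersect(base$negative_terms, base$stopwords)) ||
      length(intersect(base$positive_terms, base$stopwords)))
    stop("negative_terms, positive_terms and stopwords must be pairwise disjoint")
  structure(sets, class = "lexicon")
}

#' @rdname lexicon
#' @param path CSV with columns `term,class`, `class` one of
#'   `negative`, `positive`, `stopword`.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("term", "class") %in% names(df)))
    stop("lexicon CSV needs columns term, class")
  lexicon(df$term[df$class == "negative"], df$term[df$class == "positive"],
          df$term[df$class == "stopword"])
}

#' @rdname lexicon
#' @details `default_lexicon()` loads the small synthetic German lexicon
#'   shipped with the package (weather- and flood-related vocabulary); it is
#'   a demonstration stand-in, not a validated sentiment dictionary.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon_de_synthetic.csv",
                           package = "climsent", mustWork = TRUE))
}

#' Clean raw document text
#'
#' Normalizes a raw document to lowercase words only: URLs, user handles
#' (`@name`), HTML tags, digits, punctuation and other non-alphabetic symbols
#' are removed; the `#` of a hashtag is dropped but the bare word kept
#' (unless `drop_hashtag_words = TRUE`, which removes the whole token); runs
#' of whitespace collapse to single spaces. The function is idempotent:
#' `clean_text(clean_text(x)) == clean_text(x)`.
#'
#' @param raw character vector of raw texts.
#' @param drop_hashtag_words drop the whole hashtag token instead of only
#'   the `#` marker.
#' @return character vector of cleaned texts.
#' @examples
#' clean_text("Hochwasser!! @amt http://x.co <b>5</b>")
#' @export
clean_text <- function(raw, drop_hashtag_words = FALSE) {
  if (!is.character(raw)) stop("clean_text expects character input")
  x <- tolower(raw)
  x <- gsub("https?://\\S+|www\\.\\S+", " ", x, perl = TRUE)
  x <- gsub("<[^>]*>", " ", x, perl = TRUE)
  x <- gsub("@\\S+", " ", x, perl = TRUE)
  x <- if (drop_hashtag_words) gsub("#\\S+", " ", x, perl = TRUE)
       else gsub("#", " ", x, fixed = TRUE)
  x <- gsub("[^\\p{L}\\s]", " ", x, perl = TRUE)
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

#' Tokenize cleaned text and remove stopwords
#'
#' Whitespace tokenization of already-cleaned text, dropping tokens that
#' appear in the lexicon's stopword set (exact matches; stopword stems are
#' not expanded). Token order is preserved.
#'
#' @param cleaned a single cleaned string (output of [clean_text()]).
#' @param lex a [lexicon()].
#' @return character vector of tokens.
#' @export
tokenize_and_filter <- function(cleaned, lex = default_lexicon()) {
  stopifnot(is.character(cleaned), length(cleaned) == 1L)
  toks <- strsplit(trimws(cleaned), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  toks[!toks %in% lex$stopwords]
}

# Count how many tokens match a term set; terms ending in '*' match as
# prefixes when stem = TRUE.
match_terms <- function(tokens, terms, stem = TRUE) {
  if (length(tokens) == 0L) return(0L)
  is_stem <- grepl("\\*$", terms)
  hits <- tokens %in% terms[!is_stem]
  if (stem && any(is_stem)) {
    for (st in sub("\\*$", "", terms[is_stem]))
      hits <- hits | startsWith(tokens, st)
  }
  sum(hits)
}

#' Label the sentiment of a token list
#'
#' Majority dictionary rule: count matches against the negative and positive
#' term sets (prefix-stem matching for `*` entries when `stem = TRUE`); the
#' label is `"negative"` if negative matches outnumber positive ones,
#' `"positive"` in the opposite case, `"neutral"` on ties (including the
#' empty token list).
#'
#' @param tokens character vector of filtered tokens.
#' @param lex a [lexicon()].
#' @param stem enable prefix matching for `*` terms.
#' @return one of `"negative"`, `"positive"`, `"neutral"`.
#' @export
score_sentiment <- function(tokens, lex = default_lexicon(), stem = TRUE) {
  n_neg <- match_terms(tokens, lex$negative_terms, stem)
  n_pos <- match_terms(tokens, lex$positive_terms, stem)
  if (n_neg > n_pos) "negative" else if (n_pos > n_neg) "positive" else "neutral"
}

#' Label a data frame of documents
#'
#' Runs [clean_text()], [tokenize_and_filter()] and [score_sentiment()] over
#' a document table, adding a `label` column. Documents already carrying a
#' `label` column are passed through untouched, which is how externally
#' classified corpora enter the pipeline.
#'
#' @param docs data.frame with columns `doc_id`, `text`, `timestamp`,
#'   `region` (and optionally `label`).
#' @param lex a [lexicon()].
#' @param stem enable prefix matching for `*` terms.
#' @param filter optional predicate `function(text) logical` applied to the
#'   raw text (e.g. a language filter); documents failing it are dropped.
#' @return `docs` with a `label` column.
#' @export
label_documents <- function(docs, lex = default_lexicon(), stem = TRUE,
                            filter = NULL) {
  stopifnot(is.data.frame(docs))
  if (!is.null(filter)) docs <- docs[vapply(docs$text, filter, logical(1)), , drop = FALSE]
  if ("label" %in% names(docs)) return(docs)
  cleaned <- clean_text(docs$text)
  docs$label <- vapply(cleaned, function(s)
    score_sentiment(tokenize_and_filter(s, lex), lex, stem), character(1),
    USE.NAMES = FALSE)
  docs
}

#' Weekly regional sentiment panel
#'
#' The response/exposure pair of the risk model: `ntw` (weekly negative
#' document counts) and `ttw` (weekly total document counts) as
#' `n_regions x n_weeks` integer matrices with `0 <= ntw <= ttw` cell-wise,
#' on a complete 7-day week grid.
#'
#' @param ntw,ttw nonnegative integer matrices with region ids as row names.
#' @param week_start Date vector of week starts (step 7 days).
#' @return a `sentiment_panel`.
#' @export
sentiment_panel <- function(ntw, ttw, week_start) {
  ntw <- as.matrix(ntw); ttw <- as.matrix(ttw)
  week_start <- stopifnot_date(week_start)
  if (!identical(dim(ntw), dim(ttw))) stop("ntw and ttw must have identical dimensions")
  if (ncol(ntw) != length(week_start)) stop("weeks must match week_start")
  if (length(week_start) > 1 && any(diff(as.numeric(week_start)) != 7))
    stop("week_start must increase in steps of exactly 7 days")
  if (anyNA(ntw) || anyNA(ttw) || any(ntw < 0) || any(ttw < 0))
    stop("counts must be nonnegative and complete")
  if (any(ntw > ttw)) stop("ntw must not exceed ttw in any cell")
  storage.mode(ntw) <- "integer"; storage.mode(ttw) <- "integer"
  structure(list(ntw = ntw, ttw = ttw, week_start = week_start,
                 region_ids = rownames(ntw) %||%
                   sprintf("R%02d", seq_len(nrow(ntw)))),
            class = "sentiment_panel")
}

#' @export
print.sentiment_panel <- function(x, ...) {
  cat(sprintf("sentiment_panel: %d regions x %d weeks; total documents %.0f, negative %.0f (%.1f%%)\n",
              nrow(x$ntw), ncol(x$ntw), sum(as.numeric(x$ttw)),
              sum(as.numeric(x$ntw)),
              100 * sum(as.numeric(x$ntw)) / max(1, sum(as.numeric(x$ttw)))))
  invisible(x)
}

#' Aggregate labelled documents into a weekly regional panel
#'
#' Counts documents into 7-day bins anchored at `week_origin`: week index
#' `floor((timestamp - week_origin) / 7 days) + 1`. `ttw` counts all unique
#' documents per region-week, `ntw` those labelled `"negative"`. Documents
#' sharing a `doc_id` are exact duplicates and counted once (first
#' occurrence). Documents outside the week grid are skipped and their number
#' reported via the `"skipped"` attribute and a message; documents in
#' unknown regions are an error. Cells without documents are 0/0.
#'
#' @param docs data.frame with columns `doc_id`, `label`, `timestamp`
#'   (Date or ISO date string), `region`.
#' @param graph a [region_graph()] defining the region set.
#' @param week_origin start of week 1.
#' @param n_weeks number of weeks in the grid.
#' @return a [sentiment_panel()].
#' @export
aggregate_panel <- function(docs, graph, week_origin = "2019-01-01",
                            n_weeks = 187L) {
  stopifnot(is.data.frame(docs), inherits(graph, "region_graph"))
  need <- c("doc_id", "label", "timestamp", "region")
  if (!all(need %in% names(docs)))
    stop("docs needs columns ", paste(need, collapse = ", "))
  origin <- stopifnot_date(week_origin)
  n_weeks <- as.integer(n_weeks)
  docs <- docs[!duplicated(docs$doc_id), , drop = FALSE]
  ridx <- match(docs$region, graph$region_ids)
  if (anyNA(ridx))
    stop("unknown region(s): ",
         paste(unique(docs$region[is.na(ridx)]), collapse = ", "))
  ts <- stopifnot_date(docs$timestamp)
  widx <- as.integer(floor(as.numeric(ts - origin) / 7)) + 1L
  inwin <- widx >= 1L & widx <= n_weeks
  skipped <- sum(!inwin)
  if (skipped > 0)
    message("aggregate_panel: skipped ", skipped, " document(s) outside the week grid")
  n <- n_regions(graph)
  ttw <- matrix(0L, n, n_weeks, dimnames = list(graph$region_ids, NULL))
  ntw <- ttw
  if (any(inwin)) {
    ij <- cbind(ridx[inwin], widx[inwin])
    for (k in seq_len(nrow(ij))) ttw[ij[k, 1], ij[k, 2]] <- ttw[ij[k, 1], ij[k, 2]] + 1L
    neg <- inwin & docs$label == "negative"
    if (any(neg)) {
      ij <- cbind(ridx[neg], widx[neg])
      for (k in seq_len(nrow(ij))) ntw[ij[k, 1], ij[k, 2]] <- ntw[ij[k, 1], ij[k, 2]] + 1L
    }
  }
  out <- sentiment_panel(ntw, ttw, origin + 7 * (seq_len(n_weeks) - 1L))
  attr(out, "skipped") <- skipped
  out
}

#' Read / write a sentiment panel as tidy CSV
#'
#' Columns `region,week_start,ntw,ttw`, one row per region-week.
#'
#' @param panel a `sentiment_panel`.
#' @param path file path.
#' @export
write_panel_csv <- function(panel, path) {
  n <- nrow(panel$ntw); TT <- ncol(panel$ntw)
  df <- data.frame(region = rep(panel$region_ids, each = TT),
                   week_start = rep(panel$week_start, n),
                   ntw = as.vector(t(panel$ntw)),
                   ttw = as.vector(t(panel$ttw)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "week_start", "ntw", "ttw")
  if (!all(need %in% names(df))) stop("panel CSV needs columns ",
                                      paste(need, collapse = ", "))
  regions <- unique(df$region)
  weeks <- sort(unique(stopifnot_date(df$week_start)))
  ntw <- matrix(0L, length(regions), length(weeks), dimnames = list(regions, NULL))
  ttw <- ntw
  i <- match(df$region, regions); j <- match(stopifnot_date(df$week_start), weeks)
  ntw[cbind(i, j)] <- df$ntw
  ttw[cbind(i, j)] <- df$ttw
  sentiment_panel(ntw, ttw, weeks)
}

#' Read documents from CSV or newline-delimited JSON
#'
#' @param path file ending in `.csv` or `.ndjson`/`.jsonl` with fields
#'   `doc_id,text,timestamp,region` (a `label` field is honoured if present).
#' @return a data.frame of documents.
#' @export
read_documents <- function(path) {
  if (grepl("\\.(ndjson|jsonl)$", path)) {
    rows <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
    docs <- do.call(rbind, lapply(rows, as.data.frame))
  } else {
    docs <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("doc_id", "text", "timestamp", "region")
  if (!all(need %in% names(docs)))
    stop("documents need fields ", paste(need, collapse = ", "))
  docs
}
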