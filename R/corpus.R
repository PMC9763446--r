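#' @importFrom stats pnorm p.adjust cor rnorm rbinom runif sd var setNames uniroot quantile
#' @importFrom utils head modifyList write.table read.delim
NULL

#' Construct a sentence corpus
#'
#' A `text_corpus` holds one labeled instance per sentence: the raw text, its
#' deterministic tokenization, and the binary endpoint label
#' (`"positive"`/`"negative"`). It is the unit of data every downstream stage
#' (classifier, entity recognition, do-contrast) consumes.
#'
#' @param id character vector of unique instance identifiers.
#' @param text character vector of raw sentences.
#' @param label character vector, `"positive"` or `"negative"`.
#' @param source_record optional character vector, e.g. the drug-record id the
#'   sentence came from.
#' @param source_section optional character vector naming the source section.
#' @return An object of class `text_corpus`: a list with `instances`
#'   (data.frame of id, text, label, source_record, source_section), `tokens`
#'   (list of character vectors, parallel to `instances`), and `n`.
#' @export
new_corpus <- function(id, text, label,
                       source_record = NA_character_,
                       source_section = NA_character_) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("instance ids must be unique")
  if (length(text) != length(id) || length(label) != length(id))
    stop("id, text and label must have equal length")
  bad <- !label %in% c("positive", "negative")
  if (any(bad))
    stop("labels must be 'positive' or 'negative'; got: ",
         paste(unique(label[bad]), collapse = ", "))
  inst <- data.frame(
    id = id, text = as.character(text), label = as.character(label),
    source_record = rep_len(as.character(source_record), length(id)),
    source_section = rep_len(as.character(source_section), length(id)),
    stringsAsFactors = FALSE
  )
  structure(list(instances = inst,
                 tokens = lapply(inst$text, tokenize_text),
                 n = nrow(inst)),
            class = "text_corpus")
}

#' @export
print.text_corpus <- function(x, ...) {
  np <- sum(x$instances$label == "positive")
  cat(sprintf("<text_corpus> %d instances (%d positive, %.3f positive rate)\n",
              x$n, np, if (x$n) np / x$n else NA_real_))
  invisible(x)
}

#' Subset a corpus by instance index
#'
#' @param corpus a `text_corpus`.
#' @param idx integer or logical index into the instances.
#' @return A `text_corpus` with the selected instances, order preserved.
#' @export
corpus_subset <- function(corpus, idx) {
  stopifnot(inherits(corpus, "text_corpus"))
  structure(list(instances = corpus$instances[idx, , drop = FALSE],
                 tokens = corpus$tokens[idx],
                 n = length(corpus$tokens[idx])),
            class = "text_corpus")
}

#' Tokenize text for corpus statistics and gazetteer matching
#'
#' Lowercases and splits on runs of non-alphanumeric characters, keeping
#' numerals. The rule is deterministic so that lexicon surface forms and
#' corpus text normalize identically.
#'
#' @param x a character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_text <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  toks <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# Abbreviations whose trailing period never ends a sentence.
.abbrev_guard <- c("dr", "mr", "mrs", "ms", "prof", "fig", "figs", "vs",
                   "e.g", "i.e", "et al", "al", "etc", "approx", "no", "st")

#' Split a document into sentences
#'
#' Rule-based segmentation: a boundary is a run of `.`, `!` or `?` followed by
#' whitespace and an upper-case letter, digit, or opening quote/parenthesis.
#' Decimal numbers (no whitespace after the period) never split, and a small
#' set of common abbreviations ("Fig.", "e.g.", "et al.", ...) is guarded.
#'
#' @param document_text a character scalar; may be empty.
#' @return Character vector of sentences whose concatenation (up to
#'   whitespace) covers the input. Empty input yields `character(0)`.
#' @export
split_sentences <- function(document_text) {
  stopifnot(is.character(document_text), length(document_text) == 1L)
  txt <- trimws(document_text)
  if (!nzchar(txt)) return(character(0))
  m <- gregexpr("[.!?]+(?=\\s+[\"'(]?[A-Z0-9])", txt, perl = TRUE)[[1]]
  if (m[1] == -1L) return(txt)
  ends <- as.integer(m) + attr(m, "match.length") - 1L
  # guard: drop boundaries whose preceding word is a known abbreviation
  keep <- vapply(ends, function(e) {
    prefix <- substr(txt, 1L, e - 1L)
    last <- regmatches(prefix, regexpr("[A-Za-z.]+$", prefix))
    !(length(last) == 1L && tolower(last) %in% .abbrev_guard)
  }, logical(1))
  ends <- ends[keep]
  if (!length(ends)) return(txt)
  starts <- c(1L, ends + 1L)
  ends <- c(ends, nchar(txt))
  out <- trimws(substring(txt, starts, ends))
  out[nzchar(out)]
}

#' Label sentences by record-level likelihood category
#'
#' Each sentence carries the likelihood category of the drug record it was
#' extracted from (A well known, B known/highly likely, C probable,
#' D possible, E unlikely, X unknown). Sentences from category A or B records
#' are endpoint-positive; all others are negative. Sentences that state the
#' likelihood score itself are expected to be excluded upstream via
#' `exclude`.
#'
#' @param sentences data.frame with columns `text` and `category` (one of
#'   A,B,C,D,E,X), optionally `source_record`, `source_section`, and a logical
#'   `exclude` flag (rows flagged TRUE are dropped before labeling).
#' @param id_prefix prefix for generated instance ids.
#' @return A `text_corpus`.
#' @export
label_instances <- function(sentences, id_prefix = "s") {
  stopifnot(is.data.frame(sentences),
            all(c("text", "category") %in% names(sentences)))
  if (!is.null(sentences$exclude))
    sentences <- sentences[!isTRUE_vec(sentences$exclude), , drop = FALSE]
  cat_up <- toupper(as.character(sentences$category))
  bad <- !cat_up %in% c("A", "B", "C", "D", "E", "X")
  if (any(bad))
    stop("unknown likelihood category: ",
         paste(unique(cat_up[bad]), collapse = ", "))
  label <- ifelse(cat_up %in% c("A", "B"), "positive", "negative")
  new_corpus(
    id = sprintf("%s%05d", id_prefix, seq_len(nrow(sentences))),
    text = sentences$text, label = label,
    source_record = sentences$source_record %||% NA_character_,
    source_section = sentences$source_section %||% NA_character_
  )
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Term frequency-inverse document frequency of one term in one document
#'
#' `tf(t, d)` is the count of `t` in `d` divided by the length of `d`;
#' `idf(t) = log(N / (df + 1))` with `N` the number of documents in the
#' corpus and `df` the number containing `t`. The score is their product.
#' The logarithm base defaults to the natural log and is configurable. Note
#' the `df + 1` smoothing makes the idf (and hence the score) negative for a
#' term present in every document.
#'
#' @param term a single token (normalized).
#' @param doc_tokens character vector, the document's token sequence.
#' @param corpus a non-empty `text_corpus` providing `N` and `df`.
#' @param log_base base for the idf logarithm (default `exp(1)`).
#' @return The tf-idf score, a real number.
#' @export
tfidf_score <- function(term, doc_tokens, corpus, log_base = exp(1)) {
  stopifnot(inherits(corpus, "text_corpus"), corpus$n > 0L)
  if (length(doc_tokens) == 0L) stop("empty document")
  tf <- sum(doc_tokens == term) / length(doc_tokens)
  if (tf == 0) return(0)
  df <- sum(vapply(corpus$tokens, function(tk) term %in% tk, logical(1)))
  tf * log(corpus$n / (df + 1), base = log_base)
}

#' Corpus-level token and tf-idf statistics
#'
#' Summarizes the corpus the way one profiles an extracted sentence set:
#' vocabulary size, mean and standard deviation of sentence length in
#' tokens, and the top terms ranked by their maximum tf-idf over documents.
#'
#' @param corpus a non-empty `text_corpus`.
#' @param top_k number of top terms to report (default 10).
#' @param log_base base for the idf logarithm.
#' @return A list of class `tfidf_report`: `vocabulary_size`, `length_mean`,
#'   `length_sd`, `top_terms` (data.frame term/score sorted by score
#'   descending).
#' @export
corpus_stats <- function(corpus, top_k = 10L, log_base = exp(1)) {
  stopifnot(inherits(corpus, "text_corpus"), corpus$n > 0L)
  lens <- lengths(corpus$tokens)
  vocab <- unique(unlist(corpus$tokens, use.names = FALSE))
  dtm <- corpus_dtm(corpus, vocab)
  n <- corpus$n
  df <- Matrix::colSums(dtm > 0)
  idf <- log(n / (df + 1), base = log_base)
  tf <- dtm / pmax(lens, 1L)
  # max tf-idf per term across documents; negative idf handled via min tf
  score_max <- apply_col_extreme(tf, idf)
  ord <- order(score_max, decreasing = TRUE)
  top <- head(ord, top_k)
  structure(list(
    vocabulary_size = length(vocab),
    length_mean = mean(lens),
    length_sd = stats::sd(lens),
    top_terms = data.frame(term = vocab[top], score = score_max[top],
                           stringsAsFactors = FALSE)
  ), class = "tfidf_report")
}

# For each column (term) return max over documents of tf * idf.
apply_col_extreme <- function(tf, idf) {
  cmax <- sapply(seq_along(idf), function(j) {
    col <- tf[, j]
    if (idf[j] >= 0) max(col) * idf[j] else min(col) * idf[j]
  })
  as.numeric(cmax)
}

# Sparse document-term count matrix over a fixed vocabulary.
corpus_dtm <- function(corpus, vocab) {
  toks <- corpus$tokens
  ji <- lapply(seq_along(toks), function(i) {
    j <- match(toks[[i]], vocab)
    j <- j[!is.na(j)]
    if (!length(j)) return(NULL)
    tab <- table(j)
    cbind(i = i, j = as.integer(names(tab)), x = as.integer(tab))
  })
  m <- do.call(rbind, ji)
  if (is.null(m))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(toks), length(vocab))))
  Matrix::sparseMatrix(i = m[, "i"], j = m[, "j"], x = m[, "x"],
                       dims = c(length(toks), length(vocab)),
                       dimnames = list(NULL, vocab))
}

#' Stratified train/test split
#'
#' Splits the corpus preserving the class ratio: for each label the training
#' count is `floor(class_n * train_fraction)` and the remainder goes to the
#' test set, with membership sampled uniformly under the given seed. On a
#' 14,361-sentence corpus with 3,578 positives at fraction 0.9 this yields
#' the 12,924 / 1,437 train/test sizes of a 9:1 stratified split.
#'
#' @param corpus a `text_corpus` with both classes present.
#' @param train_fraction real in (0, 1), default 0.9.
#' @param seed integer seed; fixed seed gives identical membership.
#' @return A list of class `split_result`: `train`, `test` (corpora),
#'   `train_fraction`, and `per_class_counts` (data.frame label/train/test).
#' @export
stratified_split <- function(corpus, train_fraction = 0.9, seed = 1L) {
  stopifnot(inherits(corpus, "text_corpus"),
            train_fraction > 0, train_fraction < 1)
  lab <- corpus$instances$label
  tab <- table(lab)
  if (length(tab) < 2L) stop("both classes must be present")
  if (any(tab < 2L)) stop("each class needs at least 2 instances")
  rng_local(seed, {
    train_idx <- integer(0)
    for (cl in names(tab)) {
      idx <- which(lab == cl)
      n_train <- floor(length(idx) * train_fraction)
      train_idx <- c(train_idx, sample(idx, n_train))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(corpus$n), train_idx)
  counts <- data.frame(
    label = names(tab),
    train = vapply(names(tab), function(cl) sum(lab[train_idx] == cl), 0L),
    test = vapply(names(tab), function(cl) sum(lab[test_idx] == cl), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(train = corpus_subset(corpus, train_idx),
                 test = corpus_subset(corpus, test_idx),
                 train_fraction = train_fraction,
                 per_class_counts = counts),
            class = "split_result")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
rng_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Read / write a corpus as JSON lines
#'
#' One JSON object per line with fields `id`, `text`, `label`, and optional
#' `source_record` / `source_section`; missing optional fields are tolerated.
#'
#' @param path file path.
#' @return `read_corpus` returns a `text_corpus`; `write_corpus` invisibly
#'   returns `path`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  get_fld <- function(f, default = NA_character_)
    vapply(recs, function(r) as.character(r[[f]] %||% default), character(1))
  new_corpus(id = get_fld("id"), text = get_fld("text"),
             label = get_fld("label"),
             source_record = get_fld("source_record"),
             source_section = get_fld("source_section"))
}

#' @rdname read_corpus
#' @param corpus a `text_corpus` to serialize.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "text_corpus"))
  inst <- corpus$instances
  lines <- vapply(seq_len(nrow(inst)), function(i) {
    rec <- as.list(inst[i, , drop = FALSE])
    rec <- rec[!vapply(rec, function(v) is.na(v), logical(1))]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a tf-idf report as a tab-separated term/score table
#'
#' @param report a `tfidf_report` from [corpus_stats()].
#' @param path file path.
#' @export
write_tfidf_report <- function(report, path) {
  stopifnot(inherits(report, "tfidf_report"))
  utils::write.table(report$top_terms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
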