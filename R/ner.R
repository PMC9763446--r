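#' Build an entity lexicon
#'
#' A gazetteer mapping surface forms (normalized with the corpus tokenizer)
#' to entity ids and categories. Several surface forms may map to the same
#' entity id (synonyms). The gazetteer fills the role of a neural biomedical
#' NER service for the causal engine, which only needs per-instance mention
#' sets.
#'
#' @param surface_form character vector of surface forms (free text; each is
#'   tokenized internally).
#' @param entity_id character vector of entity identifiers.
#' @param category character vector in `{"drug", "gene", "disease"}`.
#' @return An object of class `entity_lexicon`: data.frame with columns
#'   `form` (normalized, space-joined tokens), `n_tokens`, `entity_id`,
#'   `category`.
#' @export
new_lexicon <- function(surface_form, entity_id, category) {
  stopifnot(length(surface_form) == length(entity_id),
            length(entity_id) == length(category))
  bad <- !category %in% c("drug", "gene", "disease")
  if (any(bad)) stop("category must be drug, gene or disease")
  toks <- lapply(surface_form, tokenize_text)
  if (any(lengths(toks) == 0L)) stop("empty surface form after normalization")
  lex <- data.frame(
    form = vapply(toks, paste, character(1), collapse = " "),
    n_tokens = lengths(toks),
    entity_id = as.character(entity_id),
    category = as.character(category),
    stringsAsFactors = FALSE
  )
  lex <- lex[!duplicated(lex$form), , drop = FALSE]
  structure(lex, class = c("entity_lexicon", "data.frame"))
}

#' Read / write a lexicon as tab-separated (surface_form, entity_id, category)
#'
#' @param path file path.
#' @export
read_lexicon <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         col.names = c("surface_form", "entity_id", "category"))
  new_lexicon(d$surface_form, d$entity_id, d$category)
}

#' @rdname read_lexicon
#' @param lexicon an `entity_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(
    data.frame(surface_form = lexicon$form, entity_id = lexicon$entity_id,
               category = lexicon$category),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# n-grams of a token vector as space-joined strings, with start positions
token_ngrams <- function(tokens, n) {
  L <- length(tokens)
  if (L < n) return(character(0))
  if (n == 1L) return(tokens)
  vapply(seq_len(L - n + 1L),
         function(s) paste(tokens[s:(s + n - 1L)], collapse = " "),
         character(1))
}

#' Extract entity mentions from a tokenized instance
#'
#' Matches lexicon surface forms as contiguous token subsequences
#' (case-insensitivity comes from the shared tokenizer). Overlapping matches
#' are resolved longest-match-wins: a token span claimed by a longer form is
#' unavailable to shorter forms. Duplicate mentions collapse to one entity id
#' (per-instance set semantics).
#'
#' @param tokens character vector of instance tokens (or an `Instance`-like
#'   list with a `tokens` element).
#' @param lexicon an `entity_lexicon`.
#' @return Character vector of distinct entity ids (empty if no match).
#' @export
extract_entities <- function(tokens, lexicon) {
  if (is.list(tokens) && !is.null(tokens$tokens)) tokens <- tokens$tokens
  stopifnot(is.character(tokens), inherits(lexicon, "entity_lexicon"))
  L <- length(tokens)
  if (L == 0L || nrow(lexicon) == 0L) return(character(0))
  covered <- logical(L)
  hits <- character(0)
  for (n in sort(unique(lexicon$n_tokens), decreasing = TRUE)) {
    if (L < n) next
    forms_n <- lexicon[lexicon$n_tokens == n, , drop = FALSE]
    grams <- token_ngrams(tokens, n)
    m <- match(grams, forms_n$form)
    for (s in which(!is.na(m))) {
      span <- s:(s + n - 1L)
      if (any(covered[span])) next
      covered[span] <- TRUE
      hits <- c(hits, forms_n$entity_id[m[s]])
    }
  }
  unique(hits)
}

#' Corpus-wide entity occurrence map
#'
#' Unions per-instance extractions over the corpus. Frequency counts the
#' number of instances containing the entity at least once (not raw
#' mentions), because the do-contrast partitions instances by presence.
#'
#' @param corpus a `text_corpus`.
#' @param lexicon an `entity_lexicon`.
#' @return An object of class `entity_occurrence`: list with `instances`
#'   (named list entity_id -> character vector of instance ids), `frequency`
#'   (named integer vector), `category` (named character vector), `n_corpus`.
#' @export
build_occurrence <- function(corpus, lexicon) {
  stopifnot(inherits(corpus, "text_corpus"), inherits(lexicon, "entity_lexicon"))
  per_inst <- lapply(corpus$tokens, extract_entities, lexicon = lexicon)
  ids <- corpus$instances$id
  ent <- unlist(per_inst, use.names = FALSE)
  inst <- rep(ids, lengths(per_inst))
  sets <- split(inst, ent)
  cat_map <- lexicon$category[!duplicated(lexicon$entity_id)]
  names(cat_map) <- lexicon$entity_id[!duplicated(lexicon$entity_id)]
  structure(list(instances = sets,
                 frequency = setNames(lengths(sets), names(sets)),
                 category = cat_map[names(sets)],
                 n_corpus = corpus$n),
            class = "entity_occurrence")
}

#' @export
print.entity_occurrence <- function(x, ...) {
  cat(sprintf("<entity_occurrence> %d entities over %d instances\n",
              length(x$instances), x$n_corpus))
  invisible(x)
}

#' Filter entities by corpus frequency
#'
#' Keeps entities mentioned in strictly more than `min_exclusive` instances.
#' The strict inequality means an entity at exactly the threshold is
#' dropped.
#'
#' @param occ an `entity_occurrence`.
#' @param min_exclusive non-negative count, default 50.
#' @return A filtered `entity_occurrence`.
#' @export
frequency_filter <- function(occ, min_exclusive = 50L) {
  stopifnot(inherits(occ, "entity_occurrence"), min_exclusive >= 0)
  keep <- names(occ$frequency)[occ$frequency > min_exclusive]
  structure(list(instances = occ$instances[keep],
                 frequency = occ$frequency[keep],
                 category = occ$category[keep],
                 n_corpus = occ$n_corpus),
            class = "entity_occurrence")
}

#' Write an occurrence map as tab-separated (entity_id, category, frequency)
#'
#' @param occ an `entity_occurrence`.
#' @param path file path.
#' @export
write_occurrence <- function(occ, path) {
  utils::write.table(
    data.frame(entity_id = names(occ$frequency),
               category = as.character(occ$category),
               frequency = as.integer(occ$frequency)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
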