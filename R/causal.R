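#' Partition predicted probabilities by entity presence
#'
#' The do-operator is operationalized observationally: instances mentioning
#' the entity form the DO group (`s1`), all others the NOT-DO group (`s2`).
#' Their predicted endpoint probabilities are the two samples the z-test
#' compares.
#'
#' @param entity an entity id present in `occ`.
#' @param occ an `entity_occurrence` over the scored corpus.
#' @param predictions named numeric vector, instance id -> probability,
#'   covering the corpus.
#' @return A list of class `do_partition` with `entity`, `s1`, `s2`.
#' @export
do_partition <- function(entity, occ, predictions) {
  stopifnot(inherits(occ, "entity_occurrence"))
  if (!entity %in% names(occ$instances)) stop("entity not in occurrence map")
  members <- occ$instances[[entity]]
  if (!all(members %in% names(predictions)))
    stop("predictions do not cover the corpus")
  in_do <- names(predictions) %in% members
  s1 <- as.numeric(predictions[in_do])
  s2 <- as.numeric(predictions[!in_do])
  if (length(s1) == 0L)
    stop("entity '", entity, "' untestable: empty DO group")
  if (length(s2) == 0L)
    stop("entity '", entity, "' untestable: empty NOT-DO group")
  structure(list(entity = entity, s1 = s1, s2 = s2), class = "do_partition")
}

#' One-tailed two-sample z-test
#'
#' Tests whether the DO-group mean exceeds the NOT-DO-group mean:
#' \eqn{z = (\bar s_1 - \bar s_2) / \sqrt{v_1/n_1 + v_2/n_2}} with unbiased
#' sample variances, and upper-tail standard-normal p-value
#' \eqn{P(Z > z)}.
#'
#' @param s1,s2 numeric vectors of probabilities.
#' @param min_group minimum group size for the normal approximation,
#'   default 5.
#' @return A list with `z` and `p_value`.
#' @export
z_test_one_tailed <- function(s1, s2, min_group = 5L) {
  if (length(s1) < min_group || length(s2) < min_group)
    stop("group smaller than min_group (", min_group, ")")
  se2 <- stats::var(s1) / length(s1) + stats::var(s2) / length(s2)
  if (!is.finite(se2) || se2 <= 0) stop("zero pooled standard error")
  z <- (mean(s1) - mean(s2)) / sqrt(se2)
  list(z = z, p_value = stats::pnorm(z, lower.tail = FALSE))
}

#' Multiplicity adjustment of p-values
#'
#' Benjamini-Hochberg step-up by default; `"holm"` and `"bonferroni"` are
#' also accepted. Adjusted values are monotone, order-preserving, and lie in
#' `[p_i, 1]`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method one of `"BH"`, `"holm"`, `"bonferroni"`.
#' @return Numeric vector of adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("BH", "holm", "bonferroni")) {
  method <- match.arg(method)
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Difference between DO and NOT-DO mean probabilities
#'
#' @param mean_do,mean_not_do means in `[0, 1]`.
#' @return `mean_do - mean_not_do`.
#' @export
probability_difference <- function(mean_do, mean_not_do) {
  stopifnot(all(mean_do >= 0 & mean_do <= 1),
            all(mean_not_do >= 0 & mean_not_do <= 1))
  mean_do - mean_not_do
}

#' Entity-conditioned causal screening over a scored corpus
#'
#' For every entity in the (already frequency-filtered) occurrence map,
#' partitions the prediction table into DO / NOT-DO groups, applies the
#' one-tailed z-test, adjusts the p-values for multiplicity, and flags
#' entities with adjusted p below `alpha` as enriched causal terms.
#' Entities that cannot be tested (a group empty or below `min_group`, or a
#' degenerate standard error) are reported with a skip reason, never
#' silently dropped. A raw z-threshold mode (`threshold_mode = "z"`,
#' default threshold 1.645) is available for pseudocode-style screening
#' without the p-value route.
#'
#' @param corpus the scored `text_corpus` (used for its size and id set).
#' @param predictions named numeric vector, id -> probability.
#' @param occ a frequency-filtered `entity_occurrence`.
#' @param alpha significance level on adjusted p-values, default 0.05.
#' @param min_group minimum per-group size, default 5.
#' @param method multiplicity adjustment method, default `"BH"`.
#' @param threshold_mode `"adjusted_p"` (default) or `"z"`.
#' @param z_threshold raw z cutoff used when `threshold_mode = "z"`.
#' @return A list of class `causal_table`: `records` (data.frame with one
#'   row per testable entity: entity, category, n_do, n_not_do, z, p_value,
#'   adjusted_p, mean_do, mean_not_do, probability_difference, enriched),
#'   `skipped` (data.frame entity/reason), `enriched` (character vector of
#'   enriched entity ids), `alpha`, `method`.
#' @export
infer_causal_terms <- function(corpus, predictions, occ, alpha = 0.05,
                               min_group = 5L, method = "BH",
                               threshold_mode = c("adjusted_p", "z"),
                               z_threshold = 1.645) {
  stopifnot(inherits(occ, "entity_occurrence"))
  threshold_mode <- match.arg(threshold_mode)
  entities <- sort(names(occ$instances))
  if (length(entities) == 0L) stop("empty occurrence map")
  if (inherits(corpus, "text_corpus") &&
      !setequal(names(predictions), corpus$instances$id))
    stop("predictions do not cover the corpus")

  rows <- list(); skipped <- list()
  for (e in entities) {
    part <- tryCatch(do_partition(e, occ, predictions), error = identity)
    if (inherits(part, "error")) {
      skipped[[e]] <- conditionMessage(part); next
    }
    zt <- tryCatch(z_test_one_tailed(part$s1, part$s2, min_group = min_group),
                   error = identity)
    if (inherits(zt, "error")) {
      skipped[[e]] <- conditionMessage(zt); next
    }
    m1 <- mean(part$s1); m2 <- mean(part$s2)
    rows[[e]] <- data.frame(
      entity = e, category = unname(occ$category[e]),
      n_do = length(part$s1), n_not_do = length(part$s2),
      z = zt$z, p_value = zt$p_value,
      mean_do = m1, mean_not_do = m2,
      probability_difference = probability_difference(m1, m2),
      stringsAsFactors = FALSE
    )
  }
  records <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  if (is.null(records))
    records <- data.frame(entity = character(0), category = character(0),
                          n_do = integer(0), n_not_do = integer(0),
                          z = numeric(0), p_value = numeric(0),
                          mean_do = numeric(0), mean_not_do = numeric(0),
                          probability_difference = numeric(0))
  if (nrow(records)) {
    records$adjusted_p <- adjust_pvalues(records$p_value, method = method)
    records$enriched <- if (threshold_mode == "adjusted_p")
      records$adjusted_p < alpha else records$z > z_threshold
    # report sorted by z descending within category, ties by entity id
    records <- records[order(records$category, -records$z, records$entity), ,
                       drop = FALSE]
    rownames(records) <- NULL
    records <- records[, c("entity", "category", "n_do", "n_not_do", "z",
                           "p_value", "adjusted_p", "mean_do", "mean_not_do",
                           "probability_difference", "enriched")]
  } else {
    records$adjusted_p <- numeric(0); records$enriched <- logical(0)
  }
  structure(list(
    records = records,
    skipped = data.frame(entity = names(skipped),
                         reason = unlist(skipped) %||% character(0),
                         row.names = NULL, stringsAsFactors = FALSE),
    enriched = records$entity[records$enriched],
    alpha = alpha, method = method, threshold_mode = threshold_mode
  ), class = "causal_table")
}

#' @export
print.causal_table <- function(x, ...) {
  cat(sprintf("<causal_table> %d tested, %d enriched (alpha %.3g, %s), %d skipped\n",
              nrow(x$records), length(x$enriched), x$alpha, x$method,
              nrow(x$skipped)))
  invisible(x)
}

#' Rank enriched terms by z score
#'
#' Enriched entities ranked by z descending; ties broken lexicographically
#' by entity id so repeated runs rank deterministically.
#'
#' @param table a `causal_table`.
#' @return Character vector of entity ids, highest z first.
#' @export
ranked_terms <- function(table) {
  stopifnot(inherits(table, "causal_table"))
  rec <- table$records[table$records$enriched, , drop = FALSE]
  rec$entity[order(-rec$z, rec$entity)]
}

#' Write / read a causal table as tab-separated text
#'
#' Columns: entity, category, z_score, p_value, adjusted_p, prob_do,
#' prob_not_do, prob_difference, n_do, n_not_do, enriched.
#'
#' @param table a `causal_table`.
#' @param path file path.
#' @export
write_causal_table <- function(table, path) {
  r <- table$records
  out <- data.frame(entity = r$entity, category = r$category, z_score = r$z,
                    p_value = r$p_value, adjusted_p = r$adjusted_p,
                    prob_do = r$mean_do, prob_not_do = r$mean_not_do,
                    prob_difference = r$probability_difference,
                    n_do = r$n_do, n_not_do = r$n_not_do,
                    enriched = r$enriched)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_causal_table
#' @export
read_causal_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  records <- data.frame(entity = as.character(d$entity), category = d$category,
                        n_do = d$n_do, n_not_do = d$n_not_do, z = d$z_score,
                        p_value = d$p_value, adjusted_p = d$adjusted_p,
                        mean_do = d$prob_do, mean_not_do = d$prob_not_do,
                        probability_difference = d$prob_difference,
                        enriched = as.logical(d$enriched),
                        stringsAsFactors = FALSE)
  structure(list(records = records,
                 skipped = data.frame(entity = character(0),
                                      reason = character(0)),
                 enriched = records$entity[records$enriched],
                 alpha = NA_real_, method = NA_character_,
                 threshold_mode = "adjusted_p"),
            class = "causal_table")
}
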