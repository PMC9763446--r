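#' Percentage-of-overlapped-terms (POT) curve across repeated runs
#'
#' For each cut `L` from 1 to `l_max`, POT(L) is the number of terms common
#' to every run's top-`L` ranked list, divided by `L`. A run shorter than
#' `L` contributes its full list as its top-`L`. POT quantifies how stable
#' the head of the enriched-term ranking is across repeated pipeline runs
#' that differ only in random seed.
#'
#' @param runs list (length >= 2) of character vectors: ranked enriched
#'   terms, highest z first, no duplicates within a run.
#' @param l_max largest cut, default 30.
#' @return Named numeric vector, `L = 1..l_max` -> POT in `[0, 1]`.
#' @export
pot_curve <- function(runs, l_max = 30L) {
  stopifnot(is.list(runs), length(runs) >= 2L, l_max >= 1L)
  if (any(lengths(runs) == 0L)) stop("empty run")
  if (any(vapply(runs, anyDuplicated, 0L) > 0L))
    stop("ranked lists must not contain duplicates")
  pot <- vapply(seq_len(l_max), function(L) {
    tops <- lapply(runs, function(r) head(r, L))
    length(Reduce(intersect, tops)) / L
  }, numeric(1))
  setNames(pot, seq_len(l_max))
}

#' Average POT over the curve
#'
#' @param curve named numeric vector from [pot_curve()].
#' @return Arithmetic mean of the POT values.
#' @export
average_pot <- function(curve) {
  if (!length(curve)) stop("empty POT curve")
  mean(as.numeric(curve))
}

#' Venn commonality of enriched-term sets
#'
#' Intersection-over-union of the runs' enriched sets: the fraction of all
#' distinct enriched terms that every run agrees on (the center of the Venn
#' diagram over its total).
#'
#' @param term_sets list (length >= 2) of character vectors.
#' @return Real in `[0, 1]`.
#' @export
venn_commonality <- function(term_sets) {
  stopifnot(is.list(term_sets), length(term_sets) >= 2L)
  uni <- Reduce(union, term_sets)
  if (!length(uni)) stop("empty union")
  length(Reduce(intersect, term_sets)) / length(uni)
}

#' Robustness report over repeated causal runs
#'
#' @param tables list (length >= 2) of `causal_table` objects from repeated
#'   runs differing only in seed.
#' @param l_max largest POT cut, default 30.
#' @return A list of class `robustness_report`: `pot_curve`, `average_pot`,
#'   `commonality`, `n_runs`, `run_sizes`.
#' @export
robustness_report <- function(tables, l_max = 30L) {
  stopifnot(is.list(tables), length(tables) >= 2L,
            all(vapply(tables, inherits, logical(1), "causal_table")))
  runs <- lapply(tables, ranked_terms)
  if (any(lengths(runs) == 0L))
    stop("a run has no enriched terms; POT undefined")
  curve <- pot_curve(runs, l_max = l_max)
  structure(list(pot_curve = curve, average_pot = average_pot(curve),
                 commonality = venn_commonality(runs),
                 n_runs = length(runs), run_sizes = lengths(runs)),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("<robustness_report> %d runs; average POT %.3f; commonality %.3f\n",
              x$n_runs, x$average_pot, x$commonality))
  invisible(x)
}

#' Write a robustness report as tab-separated curve plus summary line
#'
#' @param report a `robustness_report`.
#' @param path file path.
#' @export
write_robustness_report <- function(report, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# average_pot\t%.6f\tcommonality\t%.6f\truns\t%d",
                     report$average_pot, report$commonality, report$n_runs),
             con)
  utils::write.table(
    data.frame(L = as.integer(names(report$pot_curve)),
               pot = as.numeric(report$pot_curve)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
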