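#' Clinical categories of the knowledge-based causal tree
#'
#' The seven causal-factor categories of the ACG clinical guideline used to
#' organize enriched terms for idiosyncratic drug-induced liver injury
#' (iDILI) diagnosis.
#'
#' @export
acg_categories <- function() {
  c("Liver Enzymes", "Concomitant diseases", "History of other liver disorder",
    "Physical findings", "Laboratory results", "Symptoms and signs",
    "Clinical outcome")
}

#' Default severity bands for clinical-outcome terms
#'
#' Ordinal mapping from matched tree terms to a 1-5 severity band. The
#' mapping is a configurable clinical prior, not a fitted quantity: terms
#' naming liver failure map to the top band, structural liver damage to the
#' middle, and skin/jaundice findings to the low bands; anything unmapped
#' contributes the lowest band.
#'
#' @return Named integer vector, entity id -> band in 1..5.
#' @export
default_severity_map <- function() {
  c(acute_liver_failure = 5L, hepatic_failure = 5L, liver_failure = 4L,
    cirrhosis = 3L, sinusoidal_obstruction_syndrome = 3L,
    jaundice = 2L, hypersensitivity = 2L, skin_rash = 1L, rash = 1L)
}

#' Build the knowledge-based causal tree from enriched terms
#'
#' Assigns every enriched term of a causal table to one clinical category
#' (or explicitly to `"unassigned"`), producing per-category term lists
#' sorted by z descending. The tree also carries the R-score thresholds
#' used for DILI-pattern classification.
#'
#' @param table a `causal_table`.
#' @param category_assignments named character vector, entity id ->
#'   category in [acg_categories()] or `"unassigned"`; must cover every
#'   enriched term.
#' @param r_thresholds numeric `c(cholestatic_below = 2, hepatocellular_above = 5)`.
#' @param severity_map named integer vector, entity id -> severity band
#'   (default [default_severity_map()]).
#' @return A list of class `causal_tree`: `category_map` (named list of
#'   entity-id vectors, z-descending), `unassigned`, `lab_rules`,
#'   `severity_map`, `terms` (all tree terms).
#' @export
build_causal_tree <- function(table, category_assignments,
                              r_thresholds = c(cholestatic_below = 2,
                                               hepatocellular_above = 5),
                              severity_map = default_severity_map()) {
  stopifnot(inherits(table, "causal_table"))
  enr <- table$records[table$records$enriched, , drop = FALSE]
  known <- c(acg_categories(), "unassigned")
  bad <- !category_assignments %in% known
  if (any(bad))
    stop("unknown category: ",
         paste(unique(category_assignments[bad]), collapse = ", "))
  missing <- setdiff(enr$entity, names(category_assignments))
  if (length(missing))
    stop("enriched terms without a category assignment: ",
         paste(missing, collapse = ", "))
  enr <- enr[order(-enr$z, enr$entity), , drop = FALSE]
  assigned_cat <- category_assignments[enr$entity]
  category_map <- lapply(acg_categories(), function(cl)
    enr$entity[assigned_cat == cl])
  names(category_map) <- acg_categories()
  structure(list(category_map = category_map,
                 unassigned = enr$entity[assigned_cat == "unassigned"],
                 lab_rules = r_thresholds,
                 severity_map = severity_map,
                 terms = enr$entity[assigned_cat != "unassigned"]),
            class = "causal_tree")
}

#' @export
print.causal_tree <- function(x, ...) {
  cat(sprintf("<causal_tree> %d terms in %d categories (%d unassigned)\n",
              length(x$terms), sum(lengths(x$category_map) > 0),
              length(x$unassigned)))
  invisible(x)
}

#' Remove drug entities from the enriched set of a causal table
#'
#' Causal screening over drug-centric text enriches some drug names whose
#' association with the endpoint is definitional (e.g. dose-dependent
#' hepatotoxins) rather than idiosyncratic; these are excluded before tree
#' building, with the reason recorded.
#'
#' @param table a `causal_table`.
#' @param drug_ids character vector of entity ids to exclude.
#' @param reason recorded exclusion reason.
#' @return The `causal_table` with those entities un-flagged; excluded ids
#'   and the reason are appended to `table$exclusions`. Excluding an id
#'   that is not enriched is a no-op with a warning.
#' @export
exclude_drug_entities <- function(table, drug_ids,
                                  reason = "drug entity excluded from causal factors") {
  stopifnot(inherits(table, "causal_table"))
  not_enriched <- setdiff(drug_ids, table$enriched)
  if (length(not_enriched))
    warning("not enriched, nothing to exclude: ",
            paste(not_enriched, collapse = ", "))
  hit <- table$records$entity %in% intersect(drug_ids, table$enriched)
  table$records$enriched[hit] <- FALSE
  table$enriched <- setdiff(table$enriched, drug_ids)
  table$exclusions <- rbind(
    table$exclusions,
    if (any(hit)) data.frame(entity = table$records$entity[hit],
                             reason = reason, stringsAsFactors = FALSE)
  )
  table
}

#' R score from liver enzyme values
#'
#' The ratio ALT/AST used here to assign the DILI pattern. (The clinical
#' standard R value divides ULN-normalized ALT by ULN-normalized ALP; the
#' plain ALT/AST ratio is this pipeline's default, and
#' [r_score_uln()] provides the ULN-normalized alternative.)
#'
#' @param alt serum alanine transaminase (U/L), positive.
#' @param ast serum aspartate transaminase (U/L), positive.
#' @return `alt / ast`.
#' @export
r_score <- function(alt, ast) {
  if (any(ast <= 0)) stop("AST must be positive")
  if (any(alt < 0)) stop("ALT must be non-negative")
  alt / ast
}

#' @rdname r_score
#' @param alp serum alkaline phosphatase (U/L), positive.
#' @param alt_uln,alp_uln upper limits of normal for ALT and ALP.
#' @export
r_score_uln <- function(alt, alp, alt_uln = 40, alp_uln = 120) {
  if (any(alp <= 0)) stop("ALP must be positive")
  (alt / alt_uln) / (alp / alp_uln)
}

#' Classify DILI pattern from the R score
#'
#' `r > 5` is hepatocellular, `r < 2` cholestatic, and the mixed class
#' covers `2 <= r <= 5`: the boundary values, which strict inequalities
#' would leave unassigned, are folded into mixed so the rule is total.
#'
#' @param r numeric R score(s), non-negative.
#' @param thresholds numeric `c(cholestatic_below, hepatocellular_above)`.
#' @return Character vector in
#'   `{"hepatocellular", "mixed", "cholestatic"}`.
#' @export
classify_pattern <- function(r, thresholds = c(cholestatic_below = 2,
                                               hepatocellular_above = 5)) {
  if (any(r < 0)) stop("R score must be non-negative")
  lo <- thresholds[[1]]; hi <- thresholds[[2]]
  ifelse(r > hi, "hepatocellular", ifelse(r < lo, "cholestatic", "mixed"))
}

#' Construct a patient case-report record
#'
#' @param id patient identifier.
#' @param report_text free-text case report.
#' @param alt,ast serum enzyme values (U/L), or `NA` when missing.
#' @param expert_pattern optional expert DILI pattern label.
#' @param expert_severity optional expert severity label `"1+"`..`"5+"`.
#' @return A list of class `patient_record`.
#' @export
patient_record <- function(id, report_text, alt = NA_real_, ast = NA_real_,
                           expert_pattern = NA_character_,
                           expert_severity = NA_character_) {
  if (!is.na(alt) && alt <= 0) stop("ALT must be positive when present")
  if (!is.na(ast) && ast <= 0) stop("AST must be positive when present")
  if (!is.na(expert_pattern) &&
      !expert_pattern %in% c("hepatocellular", "mixed", "cholestatic"))
    stop("unknown expert pattern")
  structure(list(id = as.character(id), report_text = report_text,
                 alt = alt, ast = ast, expert_pattern = expert_pattern,
                 expert_severity = expert_severity),
            class = "patient_record")
}

#' Stratify a patient with the causal tree
#'
#' Computes the R score and DILI pattern from the labs, matches the case
#' report against the tree's terms per clinical category (via the shared
#' gazetteer), and assigns a severity bucket as the maximum severity band
#' among matched terms (lowest band when nothing matches). When labs are
#' missing the pattern is omitted but term matching still runs.
#'
#' @param patient a `patient_record`.
#' @param tree a `causal_tree`.
#' @param lexicon the `entity_lexicon` used for matching.
#' @return A list of class `stratification_result`: `id`, `r`, `pattern`,
#'   `matched_terms` (named list category -> entity ids), `severity_bucket`.
#' @export
stratify_patient <- function(patient, tree, lexicon) {
  stopifnot(inherits(patient, "patient_record"), inherits(tree, "causal_tree"),
            inherits(lexicon, "entity_lexicon"))
  has_labs <- !is.na(patient$alt) && !is.na(patient$ast)
  r <- if (has_labs) r_score(patient$alt, patient$ast) else NA_real_
  pattern <- if (has_labs) classify_pattern(r, tree$lab_rules) else NA_character_
  mentions <- extract_entities(tokenize_text(patient$report_text), lexicon)
  matched <- lapply(tree$category_map, intersect, x = mentions)
  matched_flat <- unlist(matched, use.names = FALSE)
  bands <- tree$severity_map[matched_flat]
  severity <- if (length(bands) && any(!is.na(bands)))
    max(bands, na.rm = TRUE) else 1L
  structure(list(id = patient$id, r = r, pattern = pattern,
                 matched_terms = matched,
                 severity_bucket = as.integer(severity)),
            class = "stratification_result")
}

#' Stratify a cohort and tabulate the results
#'
#' @param patients list of `patient_record`s.
#' @param tree a `causal_tree`.
#' @param lexicon an `entity_lexicon`.
#' @return data.frame with one row per patient: id, r, pattern,
#'   severity_bucket, n_matched, expert_pattern, expert_severity.
#' @export
stratify_cohort <- function(patients, tree, lexicon) {
  rows <- lapply(patients, function(p) {
    s <- stratify_patient(p, tree, lexicon)
    data.frame(id = s$id, r = s$r, pattern = s$pattern,
               severity_bucket = s$severity_bucket,
               n_matched = length(unlist(s$matched_terms)),
               expert_pattern = p$expert_pattern,
               expert_severity = p$expert_severity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pearson concordance between two quantitative stratifications
#'
#' @param x,y numeric vectors of equal length >= 3, both nonconstant.
#' @return Pearson correlation coefficient.
#' @export
concordance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  stats::cor(x, y, method = "pearson")
}

#' Read / write patient records as JSON lines
#'
#' Fields: id, report_text, alt, ast, expert_pattern, expert_severity;
#' optional fields may be absent.
#'
#' @param path file path.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop("patient file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    r <- jsonlite::fromJSON(ln)
    patient_record(id = r$id, report_text = r$report_text,
                   alt = as.numeric(r$alt %||% NA),
                   ast = as.numeric(r$ast %||% NA),
                   expert_pattern = r$expert_pattern %||% NA_character_,
                   expert_severity = r$expert_severity %||% NA_character_)
  })
}

#' @rdname read_patients
#' @param patients list of `patient_record`s.
#' @export
write_patients <- function(patients, path) {
  lines <- vapply(patients, function(p) {
    rec <- unclass(p)
    rec <- rec[!vapply(rec, function(v) length(v) == 1 && is.na(v), logical(1))]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
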