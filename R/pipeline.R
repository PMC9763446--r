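#' Configuration for a full pipeline run
#'
#' Wires the stages (simulate or load, split, fit, predict, entity
#' recognition, causal screening with repeated seeds, robustness, tree
#' building, cohort stratification) into one reproducible run.
#'
#' @param corpus_path,lexicon_path optional paths to a JSON-lines corpus and
#'   tab-separated lexicon; when `NULL` the synthetic generator supplies
#'   both (with ground truth).
#' @param generator a [generator_config()] used when simulating.
#' @param alpha significance level on adjusted p-values.
#' @param freq_threshold strict frequency floor for entities.
#' @param min_group minimum per-group size for the z-test.
#' @param adjust_method multiplicity adjustment method.
#' @param train_fraction stratified split fraction.
#' @param seed master seed; classifier seeds for the repeated runs are
#'   derived from it.
#' @param n_runs number of repeated classifier runs for robustness
#'   (default 3, varying only the classifier seed).
#' @param l_max POT curve cut, default 30.
#' @param n_patients synthetic cohort size for the stratification stage.
#' @param classifier_config optional [training_config()]; its seed is
#'   overridden per run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(corpus_path = NULL, lexicon_path = NULL,
                       generator = generator_config(),
                       alpha = 0.05, freq_threshold = 50L, min_group = 5L,
                       adjust_method = "BH", train_fraction = 0.9,
                       seed = 1L, n_runs = 3L, l_max = 30L,
                       n_patients = 175L,
                       classifier_config = training_config()) {
  stopifnot(alpha > 0, alpha < 1, n_runs >= 1)
  structure(list(corpus_path = corpus_path, lexicon_path = lexicon_path,
                 generator = generator, alpha = alpha,
                 freq_threshold = as.integer(freq_threshold),
                 min_group = as.integer(min_group),
                 adjust_method = adjust_method,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 n_runs = as.integer(n_runs), l_max = as.integer(l_max),
                 n_patients = as.integer(n_patients),
                 classifier_config = classifier_config),
            class = "run_config")
}

#' Run the full causal-screening pipeline
#'
#' Executes preprocess, split, fit, predict, entity recognition, causal
#' screening (repeated `n_runs` times varying only the classifier seed),
#' robustness evaluation, drug-entity exclusion and tree building, and
#' synthetic-cohort stratification. All artifacts plus a manifest (seeds,
#' parameters, package version) are written under `out_dir`. A rerun with
#' the same config is identical except timestamps.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, created if absent.
#' @return Invisibly, a list with the in-memory stage results: `corpus`,
#'   `split`, `models`, `predictions` (first run), `occurrence`, `tables`
#'   (one `causal_table` per run), `robustness`, `tree`, `stratification`,
#'   `truth` (when simulated), `recovery` (when simulated).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("ctrun")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  truth <- NULL
  if (is.null(config$corpus_path)) {
    sim <- stage("simulate", {
      gen <- config$generator; gen$seed <- config$seed
      generate_corpus(gen)
    })
    corpus <- sim$corpus; lexicon <- sim$lexicon; truth <- sim$truth
  } else {
    corpus <- stage("load-corpus", read_corpus(config$corpus_path))
    if (is.null(config$lexicon_path)) stop("stage 'load-lexicon' failed: no lexicon path")
    lexicon <- stage("load-lexicon", read_lexicon(config$lexicon_path))
  }
  write_corpus(corpus, file.path(out_dir, "corpus.jsonl"))
  write_lexicon(lexicon, file.path(out_dir, "lexicon.tsv"))

  split <- stage("split", stratified_split(corpus, config$train_fraction,
                                           seed = config$seed))
  occ <- stage("ner", frequency_filter(build_occurrence(corpus, lexicon),
                                       config$freq_threshold))
  write_occurrence(occ, file.path(out_dir, "occurrence.tsv"))

  run_seeds <- config$seed + seq_len(config$n_runs) - 1L
  models <- list(); tables <- list(); preds1 <- NULL
  for (k in seq_len(config$n_runs)) {
    cc <- config$classifier_config; cc$seed <- run_seeds[k]
    model <- stage("fit", fit_text_classifier(split$train, cc))
    preds <- stage("predict", predict_corpus(model, corpus))
    if (k == 1L) {
      preds1 <- preds
      write_predictions(preds, file.path(out_dir, "predictions.tsv"))
      save_classifier(model, file.path(out_dir, "classifier.json"))
    }
    tab <- stage("causal", infer_causal_terms(
      corpus, preds, occ, alpha = config$alpha,
      min_group = config$min_group, method = config$adjust_method))
    write_causal_table(tab, file.path(out_dir, sprintf("causal_run%d.tsv", k)))
    models[[k]] <- model; tables[[k]] <- tab
  }

  robustness <- if (config$n_runs >= 2L)
    stage("robustness", robustness_report(tables, l_max = config$l_max))
  else NULL
  if (!is.null(robustness))
    write_robustness_report(robustness, file.path(out_dir, "robustness.tsv"))

  # tree over the first run's enriched terms: drugs are excluded, remaining
  # entities mapped to clinical factor categories by lexicon category
  tab1 <- tables[[1]]
  drug_ids <- names(occ$category)[occ$category == "drug"]
  tab1x <- stage("tree", {
    tabx <- if (length(intersect(drug_ids, tab1$enriched)))
      exclude_drug_entities(tab1, intersect(drug_ids, tab1$enriched)) else tab1
    tabx
  })
  assignments <- setNames(
    ifelse(occ$category[tab1x$records$entity] == "disease",
           "Concomitant diseases",
           ifelse(occ$category[tab1x$records$entity] == "gene",
                  "Laboratory results", "unassigned")),
    tab1x$records$entity)
  tree <- stage("tree", build_causal_tree(tab1x, assignments))

  cohort <- stage("cohort", generate_cohort(config$n_patients,
                                            seed = config$seed))
  strat <- stage("stratify", stratify_cohort(cohort, example_clinical_tree(),
                                             clinical_lexicon()))
  utils::write.table(strat, file.path(out_dir, "stratification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  recovery <- if (!is.null(truth)) recovery_metrics(tab1$enriched, truth)
  manifest <- list(
    package_version = as.character(utils::packageVersion("causaltext")),
    r_version = R.version.string,
    seed = config$seed, run_seeds = run_seeds, alpha = config$alpha,
    freq_threshold = config$freq_threshold, min_group = config$min_group,
    adjust_method = config$adjust_method,
    train_fraction = config$train_fraction,
    n_runs = config$n_runs, l_max = config$l_max,
    simulated = is.null(config$corpus_path),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(corpus = corpus, split = split, models = models,
                 predictions = preds1, occurrence = occ, tables = tables,
                 robustness = robustness, tree = tree,
                 stratification = strat, truth = truth,
                 recovery = recovery, out_dir = out_dir))
}
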