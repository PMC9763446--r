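#' Configuration for the synthetic corpus generator
#'
#' The generator emulates a sentence corpus extracted from drug-safety
#' records: sentence lengths are truncated-normal with mean 26.84 and SD
#' 15.58 tokens, filler tokens follow a Zipf law (natural-text frequency
#' profile), biomedical entities are planted as surface-form token spans,
#' and the endpoint label follows a logistic structural model
#' \eqn{y_i \sim Bernoulli(\sigma(b + \sum_e \beta_e 1[e \in x_i]))}.
#' The intercept `base_logit` is solved numerically (exact enumeration over
#' the planted-entity inclusion distribution) so the marginal positive rate
#' equals `target_positive_rate` (default 0.249). Entity inclusion
#' probabilities default to 0.03, so at the default 5,000 sentences every
#' entity's corpus frequency comfortably exceeds the screening floor of 50.
#'
#' @param n_sentences number of sentences, default 5000.
#' @param length_mean,length_sd sentence length distribution in tokens
#'   (defaults 26.84, 15.58); lengths are rounded and floored at 3.
#' @param filler_vocab_size Zipf filler vocabulary size, default 2000.
#' @param entity_counts named integer vector of entities per category,
#'   default `c(drug = 10, gene = 10, disease = 40)`.
#' @param n_causal number of planted causal entities (ignored when
#'   `effect_map` given), default 10, spread across categories.
#' @param effect_size logit-scale effect of each planted entity, default 4.
#' @param effect_map optional named numeric vector entity id -> beta,
#'   overriding `n_causal`/`effect_size`.
#' @param entity_inclusion_prob scalar or named vector of per-entity
#'   inclusion probabilities in (0, 1), default 0.03.
#' @param target_positive_rate marginal endpoint rate, default 0.249.
#' @param base_logit optional fixed intercept; when `NULL` (default) it is
#'   solved from `target_positive_rate`.
#' @param seed integer seed; the corpus is byte-identical per seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_sentences = 5000L,
                             length_mean = 26.84, length_sd = 15.58,
                             filler_vocab_size = 2000L,
                             entity_counts = c(drug = 10L, gene = 10L,
                                               disease = 40L),
                             n_causal = 10L, effect_size = 4,
                             effect_map = NULL,
                             entity_inclusion_prob = 0.03,
                             target_positive_rate = 0.249,
                             base_logit = NULL, seed = 1L) {
  stopifnot(n_sentences >= 1, length_sd >= 0, filler_vocab_size >= 10,
            all(entity_counts >= 0), sum(entity_counts) >= 1,
            all(entity_inclusion_prob > 0), all(entity_inclusion_prob < 1),
            target_positive_rate > 0, target_positive_rate < 1)
  ids <- entity_id_set(entity_counts)
  if (is.null(effect_map)) {
    n_causal <- min(n_causal, length(ids))
    # spread planted entities across categories: every k-th id
    planted <- ids[round(seq(1, length(ids), length.out = n_causal))]
    effect_map <- setNames(rep(effect_size, n_causal), planted)
  }
  stray <- setdiff(names(effect_map), ids)
  if (length(stray)) stop("effect_map names not among entities: ",
                          paste(stray, collapse = ", "))
  incl <- if (length(entity_inclusion_prob) == 1L)
    setNames(rep(entity_inclusion_prob, length(ids)), ids)
  else entity_inclusion_prob[ids]
  if (anyNA(incl)) stop("entity_inclusion_prob must cover all entities")
  structure(list(n_sentences = as.integer(n_sentences),
                 length_mean = length_mean, length_sd = length_sd,
                 filler_vocab_size = as.integer(filler_vocab_size),
                 entity_counts = entity_counts,
                 effect_map = effect_map,
                 entity_inclusion_prob = incl,
                 target_positive_rate = target_positive_rate,
                 base_logit = base_logit, seed = as.integer(seed)),
            class = "generator_config")
}

entity_id_set <- function(entity_counts) {
  unlist(lapply(names(entity_counts), function(cat)
    sprintf("%s%02d", cat, seq_len(entity_counts[[cat]]))), use.names = FALSE)
}

# Distribution of the summed planted-entity logit: exact enumeration over
# inclusion patterns of entities with nonzero beta.
planted_logit_distribution <- function(beta, incl) {
  beta <- beta[beta != 0]
  if (!length(beta)) return(data.frame(s = 0, prob = 1))
  if (length(beta) > 20L) stop("exact enumeration limited to 20 planted entities")
  s <- 0; prob <- 1
  for (e in names(beta)) {
    p <- incl[[e]]
    s <- c(s, s + beta[[e]])
    prob <- c(prob * (1 - p), prob * p)
  }
  agg <- tapply(prob, round(s, 10), sum)
  data.frame(s = as.numeric(names(agg)), prob = as.numeric(agg))
}

# Solve the intercept so E[sigmoid(b + S)] hits the target positive rate.
solve_base_logit <- function(config) {
  dist <- planted_logit_distribution(config$effect_map,
                                     config$entity_inclusion_prob)
  f <- function(b) sum(dist$prob * sigmoid(b + dist$s)) -
    config$target_positive_rate
  stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
}

#' Analytic endpoint-probability contrast for each entity
#'
#' Closed-form `P(positive | entity present) - P(positive | absent)` under
#' the generator's logistic structural model, marginalizing the other
#' planted entities exactly. This is the oracle the do-contrast estimates.
#'
#' @param config a `generator_config`.
#' @param base_logit the intercept in use (solved if the config left it NULL).
#' @return Named numeric vector over all entities.
#' @export
analytic_effects <- function(config, base_logit = NULL) {
  b <- base_logit %||% config$base_logit %||% solve_base_logit(config)
  ids <- names(config$entity_inclusion_prob)
  vapply(ids, function(e) {
    others <- config$effect_map[setdiff(names(config$effect_map), e)]
    dist <- planted_logit_distribution(others, config$entity_inclusion_prob)
    be <- if (e %in% names(config$effect_map)) config$effect_map[[e]] else 0
    sum(dist$prob * (sigmoid(b + dist$s + be) - sigmoid(b + dist$s)))
  }, numeric(1))
}

# Surface form for a generated entity id: every fourth entity gets a
# two-token form, and every sixth an extra synonym, so multi-token and
# synonym matching are exercised.
synthetic_surface_forms <- function(ids) {
  forms <- data.frame(surface_form = paste0("x", ids), entity_id = ids,
                      stringsAsFactors = FALSE)
  two_tok <- seq_along(ids) %% 4L == 0L
  forms$surface_form[two_tok] <- paste0("x", ids[two_tok], " syndrome")
  syn <- ids[seq_along(ids) %% 6L == 0L]
  rbind(forms,
        data.frame(surface_form = paste0("syn", syn), entity_id = syn,
                   stringsAsFactors = FALSE))
}

#' Generate a synthetic labeled corpus with planted causal entities
#'
#' See [generator_config()] for the structural model. Entity mentions are
#' inserted as surface-form token spans at random positions (not markup),
#' so gazetteer matching is exercised realistically; the filler budget is
#' reduced by the inserted span lengths to preserve the length
#' distribution. If an inclusion probability times `n_sentences` is below
#' the frequency floor of 50 a warning is issued (the config is infeasible
#' for downstream screening, not invalid).
#'
#' @param config a `generator_config`.
#' @return A list with `corpus` (a `text_corpus`), `lexicon`
#'   (an `entity_lexicon`), and `truth` (class `ground_truth`: `causal_set`,
#'   `beta`, `base_logit`, `marginal_effects`, `config`).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  ids <- names(config$entity_inclusion_prob)
  low <- config$entity_inclusion_prob * config$n_sentences <= 50
  if (any(low))
    warning("expected frequency <= 50 for: ",
            paste(ids[low], collapse = ", "))
  b <- config$base_logit %||% solve_base_logit(config)
  forms <- synthetic_surface_forms(ids)
  cat_of <- rep(names(config$entity_counts), config$entity_counts)
  names(cat_of) <- entity_id_set(config$entity_counts)
  lexicon <- new_lexicon(forms$surface_form, forms$entity_id,
                         cat_of[forms$entity_id])
  # primary (non-synonym) form tokens per entity, used for insertion
  prim <- strsplit(forms$surface_form[match(ids, forms$entity_id)], " ")
  names(prim) <- ids
  zipf <- (1 / seq_len(config$filler_vocab_size))
  zipf <- zipf / sum(zipf)
  filler_words <- sprintf("w%04d", seq_len(config$filler_vocab_size))
  beta_full <- setNames(numeric(length(ids)), ids)
  beta_full[names(config$effect_map)] <- config$effect_map

  rng_local(config$seed, {
    n <- config$n_sentences
    lens <- pmax(3L, as.integer(round(rnorm(n, config$length_mean,
                                            config$length_sd))))
    present <- matrix(runif(n * length(ids)) <
                        rep(config$entity_inclusion_prob, each = n),
                      nrow = n, dimnames = list(NULL, ids))
    logits <- b + as.numeric(present %*% beta_full)
    y <- runif(n) < sigmoid(logits)
    texts <- character(n)
    for (i in seq_len(n)) {
      spans <- prim[ids[present[i, ]]]
      span_tokens <- sum(lengths(spans))
      n_fill <- max(1L, lens[i] - span_tokens)
      # spans are inserted as atomic units so a mention is never split by a
      # later insertion (detection must not depend on sentence length)
      units <- as.list(sample(filler_words, n_fill, replace = TRUE,
                              prob = zipf))
      for (sp in spans) {
        pos <- sample.int(length(units) + 1L, 1L) - 1L
        units <- append(units, list(sp), after = pos)
      }
      texts[i] <- paste(unlist(units), collapse = " ")
    }
  })
  corpus <- new_corpus(id = sprintf("inst%05d", seq_len(config$n_sentences)),
                       text = texts,
                       label = ifelse(y, "positive", "negative"),
                       source_section = "synthetic")
  truth <- structure(list(
    causal_set = names(config$effect_map)[config$effect_map > 0],
    beta = beta_full, base_logit = b,
    marginal_effects = analytic_effects(config, b),
    config = config
  ), class = "ground_truth")
  list(corpus = corpus, lexicon = lexicon, truth = truth)
}

#' Precision and recall of an enriched set against planted ground truth
#'
#' @param enriched character vector of enriched entity ids.
#' @param truth a `ground_truth` with non-empty `causal_set`.
#' @return A list with `precision` (NaN-flagged when `enriched` is empty),
#'   `recall`, `n_true_positive`.
#' @export
recovery_metrics <- function(enriched, truth) {
  stopifnot(inherits(truth, "ground_truth"), length(truth$causal_set) > 0)
  tp <- length(intersect(enriched, truth$causal_set))
  list(precision = if (length(enriched)) tp / length(enriched) else NaN,
       recall = tp / length(truth$causal_set),
       n_true_positive = tp)
}

#' Built-in clinical lexicon for the liver-injury causal tree
#'
#' Surface forms for the enriched clinical terms used by the patient
#' stratification demo (liver enzymes, concomitant diseases, liver-disorder
#' history, physical findings, laboratory results, symptoms/signs, clinical
#' outcomes).
#'
#' @return An `entity_lexicon`.
#' @export
clinical_lexicon <- function() {
  terms <- clinical_term_table()
  new_lexicon(gsub("_", " ", terms$entity_id), terms$entity_id,
              rep("disease", nrow(terms)))
}

clinical_term_table <- function() {
  data.frame(entity_id = c(
    "alkaline_phosphatase", "alt",
    "tuberculosis", "rheumatoid_arthritis",
    "cholestasis", "cholestatic_hepatitis",
    "fever", "pain",
    "lactic_acidosis",
    "hypersensitivity", "skin_rash", "jaundice", "stevens_johnson_syndrome",
    "hepatic_failure", "cirrhosis", "liver_failure",
    "sinusoidal_obstruction_syndrome", "acute_liver_failure"),
    category = c(
      "Liver Enzymes", "Liver Enzymes",
      "Concomitant diseases", "Concomitant diseases",
      "History of other liver disorder", "History of other liver disorder",
      "Physical findings", "Physical findings",
      "Laboratory results",
      "Symptoms and signs", "Symptoms and signs", "Symptoms and signs",
      "Symptoms and signs",
      "Clinical outcome", "Clinical outcome", "Clinical outcome",
      "Clinical outcome", "Clinical outcome"),
    stringsAsFactors = FALSE)
}

#' Example knowledge-based causal tree over clinical terms
#'
#' A ready-made tree whose category map follows the ACG causal-factor
#' categories, for demos and for generating synthetic patient cohorts. The
#' per-category order is fixed (no z scores are attached).
#'
#' @return A `causal_tree`.
#' @export
example_clinical_tree <- function() {
  terms <- clinical_term_table()
  category_map <- split(terms$entity_id, terms$category)[acg_categories()]
  names(category_map) <- acg_categories()
  structure(list(category_map = category_map, unassigned = character(0),
                 lab_rules = c(cholestatic_below = 2, hepatocellular_above = 5),
                 severity_map = default_severity_map(),
                 terms = terms$entity_id),
            class = "causal_tree")
}

# severity band -> a tree term carrying exactly that band
.band_term <- c("1" = "skin_rash", "2" = "jaundice", "3" = "cirrhosis",
                "4" = "liver_failure", "5" = "acute_liver_failure")

#' Generate a synthetic patient cohort with known stratification truth
#'
#' Labs are drawn to cover the three R regimes (hepatocellular R in
#' (5.5, 12), mixed in (2.2, 4.8), cholestatic in (0.3, 1.8); AST
#' log-normal around 80 U/L, ALT = R x AST), and each report embeds a
#' clinical-outcome term whose severity band equals the sampled severity,
#' plus optional lower-band terms and filler prose. Expert labels are set
#' from the generating rules, so a correct stratifier recovers them
#' exactly.
#'
#' @param n_patients cohort size, >= 1.
#' @param tree a `causal_tree` (default [example_clinical_tree()]).
#' @param seed integer seed.
#' @param lexicon lexicon used to spell embedded terms (default
#'   [clinical_lexicon()]).
#' @return List of `patient_record`s with `expert_pattern` and
#'   `expert_severity` filled in; the generating R value is recoverable as
#'   `alt / ast`.
#' @export
generate_cohort <- function(n_patients, tree = example_clinical_tree(),
                            seed = 1L, lexicon = clinical_lexicon()) {
  stopifnot(n_patients >= 1)
  spell <- setNames(gsub("_", " ", names(default_severity_map())),
                    names(default_severity_map()))
  rng_local(seed, {
    patients <- lapply(seq_len(n_patients), function(i) {
      pattern <- sample(c("hepatocellular", "mixed", "cholestatic"), 1L)
      r <- switch(pattern,
                  hepatocellular = runif(1, 5.5, 12),
                  mixed = runif(1, 2.2, 4.8),
                  cholestatic = runif(1, 0.3, 1.8))
      ast <- exp(rnorm(1, log(80), 0.4))
      alt <- r * ast
      band <- sample(1:5, 1L)
      embed <- .band_term[[as.character(band)]]
      extra <- if (band > 1 && runif(1) < 0.5)
        .band_term[[as.character(sample.int(band - 1L, 1L))]] else NULL
      text <- paste0(
        "The patient presented with elevated liver enzymes. ",
        "Examination noted ", spell[[embed]],
        if (!is.null(extra)) paste0(" and ", spell[[extra]]), ". ",
        "Symptoms resolved after withdrawal of the suspect agent.")
      patient_record(id = sprintf("pt%04d", i), report_text = text,
                     alt = alt, ast = ast, expert_pattern = pattern,
                     expert_severity = paste0(band, "+"))
    })
  })
  patients
}

#' Read a generator configuration from a YAML file
#'
#' Accepts the fields of [generator_config()]; unknown fields are rejected.
#'
#' @param path YAML file path.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown generator config fields: ",
                        paste(bad, collapse = ", "))
  if (!is.null(vals$entity_counts))
    vals$entity_counts <- unlist(vals$entity_counts)
  if (!is.null(vals$effect_map)) vals$effect_map <- unlist(vals$effect_map)
  if (!is.null(vals$entity_inclusion_prob) &&
      length(vals$entity_inclusion_prob) > 1L)
    vals$entity_inclusion_prob <- unlist(vals$entity_inclusion_prob)
  do.call(generator_config, vals)
}
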