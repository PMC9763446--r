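make_enriched_table <- function(entities, z = seq(4, by = -0.2,
                                                  length.out = length(entities))) {
  n <- length(entities)
  records <- data.frame(
    entity = entities, category = rep("disease", n), n_do = rep(100L, n),
    n_not_do = rep(900L, n), z = z, p_value = rep(1e-4, n),
    adjusted_p = rep(1e-3, n), mean_do = rep(0.4, n),
    mean_not_do = rep(0.25, n), probability_difference = rep(0.15, n),
    enriched = rep(TRUE, n), stringsAsFactors = FALSE)
  structure(list(records = records,
                 skipped = data.frame(entity = character(0),
                                      reason = character(0)),
                 enriched = entities, alpha = 0.05, method = "BH",
                 threshold_mode = "adjusted_p"),
            class = "causal_table")
}

test_that("tree building assigns every enriched term or marks it unassigned", {
  terms <- clinical_term_table()
  tab <- make_enriched_table(terms$entity_id)
  tree <- build_causal_tree(tab, setNames(terms$category, terms$entity_id))
  expect_setequal(unlist(tree$category_map), terms$entity_id)
  expect_equal(sum(lengths(tree$category_map) > 0), 7L)
  # per-category order follows z descending
  expect_equal(tree$category_map[["Liver Enzymes"]],
               c("alkaline_phosphatase", "alt"))
  # term conservation with an unassigned entity
  asg <- setNames(terms$category, terms$entity_id)
  asg["pain"] <- "unassigned"
  tree2 <- build_causal_tree(tab, asg)
  expect_equal(length(tree2$terms) + length(tree2$unassigned),
               length(tab$enriched))
  expect_true("pain" %in% tree2$unassigned)
  expect_error(build_causal_tree(tab, setNames(rep("Made Up", 18),
                                               terms$entity_id)),
               "unknown category")
  # empty table gives an empty tree
  empty <- make_enriched_table(character(0), z = numeric(0))
  tree3 <- build_causal_tree(empty, c(x = "unassigned"))
  expect_length(unlist(tree3$category_map), 0L)
})

test_that("drug-entity exclusion trims the enriched set with a reason", {
  tab <- make_enriched_table(c(sprintf("term%02d", 1:20),
                               "iron_like", "inh_like", "rif_like", "apap_like"))
  out <- exclude_drug_entities(tab, c("iron_like", "inh_like", "rif_like",
                                      "apap_like"))
  expect_length(out$enriched, 20L)
  expect_equal(nrow(out$exclusions), 4L)
  # empty exclusion set is the identity
  expect_equal(exclude_drug_entities(tab, character(0))$enriched, tab$enriched)
  expect_warning(exclude_drug_entities(tab, "not_there"), "not enriched")
})

test_that("R score and pattern rule partition the lab plane", {
  expect_equal(r_score(300, 50), 6)
  expect_equal(r_score(100, 100), 1)
  expect_equal(r_score(120, 40), 3)
  expect_error(r_score(100, 0), "AST")
  expect_equal(classify_pattern(6), "hepatocellular")
  expect_equal(classify_pattern(1), "cholestatic")
  expect_equal(classify_pattern(c(2, 5)), c("mixed", "mixed"))  # boundaries
  expect_error(classify_pattern(-1), "non-negative")
  # brute-force agreement on random lab pairs
  set.seed(41)
  alt <- runif(10000, 5, 2000); ast <- runif(10000, 5, 800)
  got <- classify_pattern(r_score(alt, ast))
  r <- alt / ast
  brute <- ifelse(r > 5, "hepatocellular", ifelse(r < 2, "cholestatic", "mixed"))
  expect_identical(got, brute)
})

test_that("patient stratification combines labs, tree terms and severity", {
  tree <- example_clinical_tree()
  lex <- clinical_lexicon()
  p <- patient_record("p1", "Course complicated by acute liver failure.",
                      alt = 400, ast = 50)
  s <- stratify_patient(p, tree, lex)
  expect_equal(s$pattern, "hepatocellular")
  expect_equal(s$matched_terms[["Clinical outcome"]], "acute_liver_failure")
  expect_equal(s$severity_bucket, 5L)
  # no tree terms -> lowest bucket, empty matches
  p2 <- patient_record("p2", "Unremarkable course.", alt = 30, ast = 40)
  s2 <- stratify_patient(p2, tree, lex)
  expect_equal(s2$severity_bucket, 1L)
  expect_length(unlist(s2$matched_terms), 0L)
  # missing labs: pattern omitted, matching still performed
  p3 <- patient_record("p3", "Developed jaundice on day 3.")
  s3 <- stratify_patient(p3, tree, lex)
  expect_true(is.na(s3$pattern))
  expect_equal(unlist(s3$matched_terms, use.names = FALSE), "jaundice")
})

test_that("concordance is the Pearson coefficient with guards", {
  x <- c(1, 2, 3)
  expect_equal(concordance(x, x), 1)
  expect_equal(concordance(x, -x), -1)
  expect_equal(concordance(x, c(1, 2, 4)), 3 / sqrt(2 * 14 / 3),
               tolerance = 1e-7)
  expect_error(concordance(x, c(2, 2, 2)), "constant")
})

test_that("patient records round-trip through JSON lines", {
  pats <- generate_cohort(8, seed = 4)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_patients(pats, path)
  back <- read_patients(path)
  expect_equal(vapply(back, `[[`, "", "id"), vapply(pats, `[[`, "", "id"))
  expect_equal(vapply(back, `[[`, 0, "alt"), vapply(pats, `[[`, 0, "alt"),
               tolerance = 1e-12)
  expect_error(patient_record("p", "text", alt = -5, ast = 10), "ALT")
})
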