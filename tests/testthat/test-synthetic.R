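test_that("generator is reproducible and honors its config", {
  cfg <- generator_config(n_sentences = 400, seed = 13)
  a <- suppressWarnings(generate_corpus(cfg))
  b <- suppressWarnings(generate_corpus(cfg))
  expect_identical(a$corpus$instances, b$corpus$instances)
  expect_identical(a$truth$beta, b$truth$beta)
  expect_equal(a$corpus$n, 400L)
  # infeasible frequency floor warns rather than errors
  expect_warning(
    generate_corpus(generator_config(n_sentences = 200, seed = 1)),
    "frequency")
})

test_that("null model hits the configured base rate", {
  cfg <- generator_config(n_sentences = 4000, n_causal = 0,
                          target_positive_rate = 0.249, seed = 17)
  sim <- suppressWarnings(generate_corpus(cfg))
  rate <- mean(sim$corpus$instances$label == "positive")
  se <- sqrt(0.249 * 0.751 / 4000)
  expect_lt(abs(rate - 0.249), 3 * se)
  # with no effects the intercept is the logit of the target rate
  expect_equal(sim$truth$base_logit, qlogis(0.249), tolerance = 1e-9)
})

test_that("corpus-wide positive rate tracks the solved logistic marginal", {
  sim <- default_sim()
  rate <- mean(sim$corpus$instances$label == "positive")
  se <- sqrt(0.249 * 0.751 / sim$corpus$n)
  expect_lt(abs(rate - 0.249), 3 * se)
  st <- corpus_stats(sim$corpus)
  expect_lt(abs(st$length_mean - 26.84), 2)
})

test_that("empirical DO contrast matches the analytic logistic difference", {
  cfg <- generator_config(n_sentences = 20000,
                          entity_counts = c(disease = 10L),
                          effect_map = c(disease01 = 2.0),
                          entity_inclusion_prob = 0.05,
                          target_positive_rate = 0.25, seed = 19)
  sim <- generate_corpus(cfg)
  lab <- sim$corpus$instances$label == "positive"
  has <- vapply(sim$corpus$tokens, function(tk) "xdisease01" %in% tk,
                logical(1))
  emp <- mean(lab[has]) - mean(lab[!has])
  ana <- sim$truth$marginal_effects[["disease01"]]
  se <- sqrt(var(lab[has]) / sum(has) + var(lab[!has]) / sum(!has))
  expect_lt(abs(emp - ana), 3 * se)
  # the non-causal entities have (near) zero analytic effect
  expect_true(all(abs(sim$truth$marginal_effects[
    setdiff(names(sim$truth$marginal_effects), "disease01")]) < 1e-12))
})

test_that("recovery metrics follow the set definitions", {
  truth <- structure(list(causal_set = c("a", "b")), class = "ground_truth")
  m <- recovery_metrics(c("a", "c"), truth)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(recovery_metrics(c("a", "b"), truth)$precision, 1)
  expect_equal(recovery_metrics(c("a", "b"), truth)$recall, 1)
  ten <- structure(list(causal_set = letters[1:9]), class = "ground_truth")
  expect_equal(recovery_metrics(c(letters[1:9], "z"), ten)$precision, 0.9)
  empty <- recovery_metrics(character(0), truth)
  expect_true(is.nan(empty$precision))
  expect_equal(empty$recall, 0)
})

test_that("synthetic cohorts are reproducible and label-consistent", {
  coh1 <- generate_cohort(40, seed = 23)
  coh2 <- generate_cohort(40, seed = 23)
  expect_identical(coh1, coh2)
  expect_length(generate_cohort(1, seed = 1), 1L)
  strat <- stratify_cohort(coh1, example_clinical_tree(), clinical_lexicon())
  expect_equal(strat$pattern, strat$expert_pattern)
  expect_equal(paste0(strat$severity_bucket, "+"), strat$expert_severity)
  # computed R reproduces the generating labs exactly
  alt <- vapply(coh1, `[[`, 0, "alt"); ast <- vapply(coh1, `[[`, 0, "ast")
  expect_equal(strat$r, alt / ast, tolerance = 1e-12)
})

test_that("generator config survives the YAML round trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_sentences: 300", "seed: 5", "effect_size: 2.5",
               "entity_counts:", "  drug: 4", "  gene: 2", "  disease: 6"),
             path)
  cfg <- read_generator_config(path)
  expect_equal(cfg$n_sentences, 300L)
  expect_equal(unname(cfg$entity_counts["disease"]), 6L)
  expect_equal(unname(cfg$effect_map[1]), 2.5)
  writeLines("bogus_field: 1", path)
  expect_error(read_generator_config(path), "unknown generator config")
})
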