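test_that("do-partition splits predictions by entity presence", {
  occ <- structure(list(
    instances = list(ent = "i1", all = c("i1", "i2", "i3")),
    frequency = c(ent = 1L, all = 3L),
    category = c(ent = "disease", all = "disease"), n_corpus = 3L),
    class = "entity_occurrence")
  preds <- c(i1 = 0.9, i2 = 0.2, i3 = 0.3)
  part <- do_partition("ent", occ, preds)
  expect_equal(part$s1, 0.9)
  expect_setequal(part$s2, c(0.2, 0.3))
  expect_equal(length(part$s1) + length(part$s2), 3L)
  # entity present everywhere -> empty NOT-DO group
  expect_error(do_partition("all", occ, preds), "empty NOT-DO")
  expect_error(do_partition("ghost", occ, preds), "not in occurrence")
})

test_that("one-tailed z-test matches the Welch statistic oracle", {
  # worked example
  zt <- z_test_one_tailed(c(0.5, 0.7), c(0.2, 0.4), min_group = 2)
  expect_equal(zt$z, 2.1213203, tolerance = 1e-6)
  expect_equal(zt$p_value, pnorm(2.1213203, lower.tail = FALSE),
               tolerance = 1e-6)
  # symmetric case
  s <- c(0.1, 0.5, 0.9, 0.3, 0.6)
  expect_equal(z_test_one_tailed(s, s)$z, 0)
  expect_equal(z_test_one_tailed(s, s)$p_value, 0.5)
  # zero variance
  expect_error(z_test_one_tailed(rep(0.6, 5), rep(0.6, 5)), "standard error")
  # 1,000 random inputs against an independent implementation (Welch t
  # statistic shares the exact standard-error formula; p from upper tail)
  set.seed(11)
  for (i in 1:1000) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    s1 <- runif(n1); s2 <- runif(n2)
    got <- z_test_one_tailed(s1, s2)
    oracle_z <- unname(t.test(s1, s2, var.equal = FALSE)$statistic)
    expect_equal(got$z, oracle_z, tolerance = 1e-9)
    expect_equal(got$p_value, pnorm(oracle_z, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("multiplicity adjustment reproduces step-up arithmetic", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04),
               tolerance = 1e-12)
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(rep(0.2, 5)), rep(0.2, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  # property: matches the hand step-up oracle on random vectors,
  # is monotone in p, and bounded by [p, 1]
  set.seed(21)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- adjust_pvalues(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15 & adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("probability difference reproduces reported contrasts", {
  expect_equal(probability_difference(0.398, 0.244), 0.154, tolerance = 1e-12)
  expect_equal(probability_difference(0.547, 0.244), 0.303, tolerance = 1e-12)
  expect_equal(probability_difference(0.4, 0.4), 0)
})

test_that("causal screening recovers planted terms and reports skips", {
  scr <- run_screen(generator_config(n_sentences = 2500, seed = 8))
  rec <- recovery_metrics(scr$table$enriched, scr$sim$truth)
  expect_gte(rec$recall, 0.9)
  expect_gte(rec$precision, 0.9)
  expect_true(all(scr$table$records$adjusted_p >= scr$table$records$p_value))
  d <- with(scr$table$records, mean_do - mean_not_do)
  expect_equal(scr$table$records$probability_difference, d, tolerance = 1e-12)
  # invariance to instance order (up to record ordering)
  perm <- sample(scr$sim$corpus$n)
  corp2 <- corpus_subset(scr$sim$corpus, perm)
  occ2 <- frequency_filter(build_occurrence(corp2, scr$sim$lexicon), 50)
  tab2 <- infer_causal_terms(corp2, scr$preds[corp2$instances$id], occ2)
  expect_equal(tab2$records, scr$table$records, tolerance = 1e-12)
  expect_error(infer_causal_terms(scr$sim$corpus, scr$preds,
                                  frequency_filter(scr$occ, 10^6)),
               "empty occurrence")
})

test_that("single testable entity is enriched iff its raw p clears alpha", {
  set.seed(31)
  preds <- setNames(runif(60, 0.1, 0.9), sprintf("i%02d", 1:60))
  mk_occ <- function(members) structure(list(
    instances = list(solo = members),
    frequency = c(solo = length(members)),
    category = c(solo = "disease"), n_corpus = 60L),
    class = "entity_occurrence")
  # strong-looking group: top predictions
  hi <- names(sort(preds, decreasing = TRUE))[1:10]
  tab_hi <- infer_causal_terms(NULL, preds, mk_occ(hi))
  expect_equal(tab_hi$records$adjusted_p, tab_hi$records$p_value)
  expect_equal(tab_hi$records$enriched, tab_hi$records$p_value < 0.05)
  # raw-z threshold mode mirrors the pseudocode screen
  tab_z <- infer_causal_terms(NULL, preds, mk_occ(hi), threshold_mode = "z",
                              z_threshold = 1.645)
  expect_equal(tab_z$records$enriched, tab_z$records$z > 1.645)
})

test_that("causal table round-trips through its tab-separated form", {
  scr <- run_screen(generator_config(n_sentences = 2500, seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_causal_table(scr$table, path)
  back <- read_causal_table(path)
  expect_equal(back$records$entity, scr$table$records$entity)
  expect_equal(back$records$z, scr$table$records$z, tolerance = 1e-6)
  expect_setequal(back$enriched, scr$table$enriched)
})
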