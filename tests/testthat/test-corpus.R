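test_that("sentence splitting handles terminators, decimals and abbreviations", {
  expect_equal(split_sentences("Drug X causes injury. It resolved."),
               c("Drug X causes injury.", "It resolved."))
  expect_equal(split_sentences("No terminator here"), "No terminator here")
  expect_length(split_sentences("Bilirubin was 2.5 mg/dL. ALT rose."), 2L)
  expect_length(split_sentences("See Fig. 2 for details. Values rose."), 2L)
  expect_length(split_sentences(""), 0L)
  # coverage: concatenation reproduces the input up to whitespace
  txt <- "ALT rose to 300 U/L. AST was 50! Was biopsy done? Yes."
  out <- split_sentences(txt)
  expect_equal(gsub("\\s", "", paste(out, collapse = "")),
               gsub("\\s", "", txt))
})

test_that("likelihood-category labeling follows the A/B positive rule", {
  sents <- data.frame(
    text = c("s one", "s two", "s three", "s four"),
    category = c("A", "B", "C", "E"), stringsAsFactors = FALSE)
  corp <- label_instances(sents)
  expect_equal(corp$instances$label,
               c("positive", "positive", "negative", "negative"))
  expect_error(label_instances(data.frame(text = "s", category = "Q")),
               "unknown likelihood category")
  # excluded rows (likelihood-score sentences) are dropped before labeling
  sents$exclude <- c(FALSE, TRUE, FALSE, FALSE)
  expect_equal(label_instances(sents)$n, 3L)
})

test_that("tf-idf matches the closed form and its degenerate cases", {
  corp <- new_corpus(id = c("a", "b", "c"),
                     text = c("alt alt rose", "ast fell low", "alt was high"),
                     label = c("positive", "negative", "negative"))
  # t in 1 of 2 docs with N = 2: idf = log(2/2) = 0
  two <- corpus_subset(corp, 1:2)
  expect_equal(tfidf_score("alt", two$tokens[[1]], two), 0)
  # absent term scores 0 regardless of idf
  expect_equal(tfidf_score("alt", corp$tokens[[2]], corp), 0)
  # hand oracle: tf = 2/3, df = 2 in this corpus -> use single-doc df case
  doc <- c("alt", "alt", "rose")
  solo <- new_corpus(id = c("a", "b", "c"),
                     text = c("alt alt rose", "ast fell low", "ast was high"),
                     label = c("positive", "negative", "negative"))
  expect_equal(tfidf_score("alt", doc, solo), (2 / 3) * log(3 / 2),
               tolerance = 1e-12)
  expect_error(tfidf_score("alt", character(0), corp), "empty document")
  # monotone in within-document term count at fixed df
  s1 <- tfidf_score("alt", c("alt", "x", "y"), solo)
  s2 <- tfidf_score("alt", c("alt", "alt", "y"), solo)
  expect_gt(s2, s1)
})

test_that("corpus statistics report vocabulary and length moments", {
  corp <- new_corpus(id = 1:2, text = c("a b c a b", "a b c a b"),
                     label = c("positive", "negative"))
  st <- corpus_stats(corp)
  expect_equal(st$length_mean, 5)
  expect_equal(st$length_sd, 0)
  expect_equal(st$vocabulary_size, 3L)
})

test_that("stratified split partitions with per-class floor rule", {
  corp <- new_corpus(id = sprintf("i%02d", 1:20),
                     text = rep(c("alt rose", "ast fell"), 10),
                     label = rep(c("positive", "negative"), each = 10))
  sp <- stratified_split(corp, 0.9, seed = 5)
  expect_equal(sp$train$n, 18L)
  expect_equal(sum(sp$train$instances$label == "positive"), 9L)
  expect_equal(sp$test$n, 2L)
  # partition: re-merging reproduces the id multiset
  expect_setequal(c(sp$train$instances$id, sp$test$instances$id),
                  corp$instances$id)
  # determinism
  sp2 <- stratified_split(corp, 0.9, seed = 5)
  expect_identical(sp$train$instances$id, sp2$train$instances$id)
  # degenerate class
  bad <- new_corpus(id = 1:3, text = c("a", "b", "c"),
                    label = c("positive", "negative", "negative"))
  expect_error(stratified_split(bad, 0.9), "at least 2")
})

test_that("corpus JSON-lines round trip preserves instances", {
  corp <- toy_separable_corpus(5)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corp, path)
  back <- read_corpus(path)
  expect_equal(back$instances$id, corp$instances$id)
  expect_equal(back$instances$label, corp$instances$label)
  expect_equal(back$tokens, corp$tokens)
})
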