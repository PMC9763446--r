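# Small in-code fixtures shared across test files.

# toy corpus: positives contain the token "hepatotoxic"
toy_separable_corpus <- function(n_per_class = 30) {
  pos <- sprintf("drug %d was hepatotoxic in the trial cohort", seq_len(n_per_class))
  neg <- sprintf("drug %d was well tolerated in the trial cohort", seq_len(n_per_class))
  new_corpus(id = sprintf("t%03d", seq_len(2 * n_per_class)),
             text = c(pos, neg),
             label = rep(c("positive", "negative"), each = n_per_class))
}

toy_lexicon <- function() {
  new_lexicon(
    surface_form = c("liver failure", "acute liver failure", "jaundice"),
    entity_id = c("liver_failure", "acute_liver_failure", "jaundice"),
    category = c("disease", "disease", "disease"))
}

# default synthetic study corpus, generated once per test run
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_corpus(generator_config(seed = 42L))
    cache
  }
})

# independent step-up oracle for Benjamini-Hochberg (kept free of p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  stepped <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  pmin(adj, 1)[order(o)]
}

run_screen <- function(cfg, freq = 50L, tc_seed = cfg$seed) {
  sim <- generate_corpus(cfg)
  sp <- stratified_split(sim$corpus, 0.9, seed = cfg$seed)
  m <- fit_text_classifier(sp$train, training_config(seed = tc_seed))
  pr <- predict_corpus(m, sim$corpus)
  occ <- frequency_filter(build_occurrence(sim$corpus, sim$lexicon), freq)
  list(sim = sim, split = sp, model = m, preds = pr, occ = occ,
       table = infer_causal_terms(sim$corpus, pr, occ))
}
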