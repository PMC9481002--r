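# Fixtures built in code, plus a cache so expensive generated corpora are
# shared across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

toy_lexicon_path <- function() {
  system.file("extdata", "toy_lexicon.tsv", package = "emonarr")
}

toy_corpus <- function() {
  cached("toy_corpus", read_corpus(
    system.file("extdata", "toy_corpus", package = "emonarr"),
    system.file("extdata", "toy_metadata.tsv", package = "emonarr")))
}

# small fast two-group config with emotion emission and stopwords active;
# any generator_config() argument can be overridden
small_config <- function(...) {
  base <- list(
    n_participants = c(patient = 4, control = 4),
    narrative_rate = matrix(3, 2, 5),
    empty_rate = 0.5,
    sentences_per_narrative = c(patient = 2.5, control = 2.5),
    words_per_sentence = c(patient = 10, control = 10),
    vocab_size = 300,
    stopword_prob = 0.15,
    n_stopwords = 15,
    emission_probs = matrix(0.004, 2, 21)
  )
  do.call(generator_config, utils::modifyList(base, list(...)))
}

small_gen <- function(seed = 11) {
  cached(paste0("small_", seed), generate_corpus(small_config(), seed))
}

cohort_gen <- function(seed = 42) {
  cached(paste0("cohort_", seed), generate_corpus(cohort_preset(), seed))
}

# in-memory corpus from parallel vectors of (id, group, primary, codes, text)
make_corpus <- function(ids, groups, primary, codes, text) {
  md_ids <- unique(ids)
  md <- tibble::tibble(
    id = md_ids,
    group = groups[match(md_ids, ids)],
    gender = NA_character_, marital_status = NA_character_,
    age = NA_real_, days_in_hospital = NA_real_
  )
  ordinal <- unlist(lapply(md_ids, function(p) seq_len(sum(ids == p))))
  new_corpus(md, tibble::tibble(
    id = ids, ordinal = ordinal, primary = primary,
    codes = codes, text = text))
}
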