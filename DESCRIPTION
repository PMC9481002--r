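Package: emonarr
Title: Text Mining of Emotion-Tagged Clinical Interview Narratives
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing interview corpora annotated with
    emotion-tagged discourse units. Parses the ++EMOTION(SUBCODE)++
    narrative dialect, maps tokens onto a 21-subcategory affect lexicon
    rolled up to five primary emotions, computes narrative-complexity
    features (type-token ratio, mean word length, sentence and narrative
    lengths) with Welch two-sample group comparisons, profiles
    emotion-word frequencies by polarity and category, ranks
    group-distinctive words with a two-cell log-likelihood keyness
    statistic, and simulates seeded two-group corpora with exact ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
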