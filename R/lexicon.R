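# Affect taxonomy: 21 subcategory codes rolled up to five primary emotions.
# "Surprise" (PC) is dual: it resolves to HAPPY when the lexicon entry is
# positive and to FEAR when negative. Note that "Grief" keeps its historical
# code PF and negative polarity under SAD even though the P/N prefix
# convention holds everywhere else in the code set.

PRIMARY_EMOTIONS <- c("HAPPY", "SAD", "ANGRY", "FEAR", "DISGUST")

POLARITIES <- c("positive", "negative")

# Table order of the 21 subcategory codes (labels in emotion_taxonomy()).
EMOTION_CODES <- c("PA", "PE", "PD", "PH", "PG", "PB", "PK",
                   "NA", "NB", "NJ", "NH", "PF",
                   "NI", "NC", "NG", "NE",
                   "ND", "NN", "NK", "NL", "PC")

CODE_LABELS <- c(PA = "Joy", PE = "Comfort", PD = "Respect", PH = "Praise",
                 PG = "Trust", PB = "Like", PK = "Wish",
                 "NA" = "Angry", NB = "Upset", NJ = "Disappointed",
                 NH = "Guilty", PF = "Grief",
                 NI = "Panic", NC = "Dread", NG = "Shame", NE = "Depressed",
                 ND = "Hate", NN = "Criticize", NK = "Envious",
                 NL = "Suspect", PC = "Surprise")

# PC is NA here: its primary depends on polarity (see primary_of()).
CODE_PRIMARY <- c(PA = "HAPPY", PE = "HAPPY", PD = "HAPPY", PH = "HAPPY",
                  PG = "HAPPY", PB = "HAPPY", PK = "HAPPY",
                  "NA" = "ANGRY",
                  NB = "SAD", NJ = "SAD", NH = "SAD", PF = "SAD",
                  NI = "FEAR", NC = "FEAR", NG = "FEAR", NE = "FEAR",
                  NL = "FEAR",
                  ND = "DISGUST", NN = "DISGUST", NK = "DISGUST",
                  PC = NA_character_)

#' The 21-subcategory emotion taxonomy
#'
#' Returns the full mapping between the 21 affect-lexicon subcategory codes,
#' their human-readable labels, the five primary emotions they roll up to,
#' and their default polarity. The "Surprise" code `PC` is dual: its primary
#' emotion and polarity are listed as `"FEAR/HAPPY"` and
#' `"negative/positive"` and are resolved per lexicon entry by
#' [primary_of()].
#'
#' @return A tibble with columns `code`, `label`, `primary`, `polarity`,
#'   one row per code, in canonical table order.
#' @seealso [primary_of()], [load_lexicon()]
#' @export
#' @examples
#' emotion_taxonomy()
emotion_taxonomy <- function() {
  tibble::tibble(
    code = EMOTION_CODES,
    label = unname(CODE_LABELS[EMOTION_CODES]),
    primary = ifelse(EMOTION_CODES == "PC", "FEAR/HAPPY",
                     unname(CODE_PRIMARY[EMOTION_CODES])),
    polarity = ifelse(EMOTION_CODES == "PC", "negative/positive",
                      ifelse(CODE_PRIMARY[EMOTION_CODES] == "HAPPY",
                             "positive", "negative"))
  )
}

#' Primary emotion of a subcategory code
#'
#' Maps a subcategory code (and, for the dual code `PC`, a polarity) to one
#' of the five primary emotions. `PC` resolves to `HAPPY` when positive and
#' `FEAR` when negative; every other code has a fixed primary and its
#' polarity argument is ignored.
#'
#' @param code Character vector of subcategory codes.
#' @param polarity Character vector, `"positive"` or `"negative"`; recycled.
#'   Required for `PC` entries.
#' @return Character vector of primary emotions (never `"EMPTY"`).
#' @export
#' @examples
#' primary_of("NC", "negative") # FEAR
#' primary_of("PC", "positive") # HAPPY
primary_of <- function(code, polarity = NULL) {
  if (!is.character(code)) abort_("`code` must be a character vector")
  bad <- setdiff(unique(code), EMOTION_CODES)
  if (length(bad)) abort_("unknown subcategory code(s): %s",
                          paste(bad, collapse = ", "))
  out <- unname(CODE_PRIMARY[code])
  pc <- code == "PC"
  if (any(pc)) {
    if (is.null(polarity))
      abort_("polarity is required to resolve the dual code PC")
    polarity <- rep_len(polarity, length(code))
    badp <- setdiff(unique(polarity[pc]), POLARITIES)
    if (length(badp)) abort_("invalid polarity: %s",
                             paste(badp, collapse = ", "))
    out[pc] <- ifelse(polarity[pc] == "positive", "HAPPY", "FEAR")
  }
  out
}

# codes admissible as subcategories of a primary tag (PC may sit under
# FEAR or HAPPY)
codes_for_primary <- function(primary) {
  fixed <- EMOTION_CODES[!is.na(CODE_PRIMARY[EMOTION_CODES]) &
                           CODE_PRIMARY[EMOTION_CODES] == primary]
  if (primary %in% c("FEAR", "HAPPY")) c(fixed, "PC") else fixed
}

#' Load an affect lexicon
#'
#' Reads a lexicon as a UTF-8 tab-delimited table with header
#' `word code polarity`. Each row assigns a surface word form to one of the
#' 21 subcategory codes with an explicit polarity; the same word may appear
#' under several codes, but `(word, code)` pairs must be unique.
#'
#' @param path Path to the lexicon TSV.
#' @return A tibble with columns `word`, `code`, `polarity`, in file order
#'   (the order matters: [emotion_counts()] attributes multi-code tokens to
#'   their first-listed entry).
#' @export
#' @examples
#' lex <- load_lexicon(system.file("extdata", "toy_lexicon.tsv",
#'                                 package = "emonarr"))
#' nrow(lex)
load_lexicon <- function(path) {
  if (!file.exists(path)) abort_("lexicon file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   colClasses = "character", na.strings = "",
                   fileEncoding = "UTF-8", check.names = FALSE)
  need <- c("word", "code", "polarity")
  if (!identical(names(df), need))
    abort_("lexicon header must be exactly: %s", paste(need, collapse = " "))
  validate_lexicon(tibble::as_tibble(df))
}

# shared validation for loaded and in-memory lexicons
validate_lexicon <- function(lex) {
  if (!all(c("word", "code", "polarity") %in% names(lex)))
    abort_("lexicon must have columns word, code, polarity")
  if (any(is.na(lex$word) | !nzchar(lex$word)))
    abort_("lexicon contains empty words")
  bad <- setdiff(unique(lex$code), EMOTION_CODES)
  if (length(bad)) abort_("unknown subcategory code(s) in lexicon: %s",
                          paste(bad, collapse = ", "))
  badp <- setdiff(unique(lex$polarity), POLARITIES)
  if (length(badp) || anyNA(lex$polarity))
    abort_("lexicon polarity must be 'positive' or 'negative'")
  key <- paste(lex$word, lex$code)
  if (anyDuplicated(key))
    abort_("duplicate (word, code) pair(s): %s",
           paste(unique(key[duplicated(key)]), collapse = ", "))
  tibble::as_tibble(lex[c("word", "code", "polarity")])
}

#' Look up a token in the lexicon
#'
#' Returns every `(code, polarity)` pair the exact surface form maps to, in
#' lexicon order. Matching is exact string equality: no stemming, casefolding
#' or lemmatization is applied.
#'
#' @param word A single token surface form.
#' @param lexicon A lexicon tibble from [load_lexicon()].
#' @return A tibble with columns `code`, `polarity` (zero rows when the word
#'   is not in the lexicon).
#' @export
classify_token <- function(word, lexicon) {
  if (!is_string(word)) abort_("`word` must be a single string")
  lexicon <- validate_lexicon(lexicon)
  hit <- lexicon$word == word
  tibble::as_tibble(lexicon[hit, c("code", "polarity")])
}

# first-listed lexicon entry per word; used for once-per-token attribution
lexicon_first_entry <- function(lexicon) {
  lexicon[!duplicated(lexicon$word), , drop = FALSE]
}
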