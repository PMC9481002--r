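# Sentence segmentation, tokenization and stopword filtering. Tokenizers are
# pluggable so that corpora in languages without whitespace word boundaries
# can go through an external segmenter adapter; the bundled default splits on
# whitespace and drops punctuation-only tokens.

#' Default sentence terminators
#'
#' Full-width Chinese and ASCII sentence-final punctuation.
#' @export
DEFAULT_TERMINATORS <- "。！？.!?"

escape_class_char <- function(ch) {
  ifelse(ch %in% c("^", "]", "\\", "-"), paste0("\\", ch), ch)
}

#' Split text into sentences
#'
#' Sentences are maximal runs ending at a terminator character (a run of
#' terminators is attached to its sentence); trailing text without a
#' terminator forms a final sentence; empty segments are dropped.
#'
#' @param text A single string.
#' @param terminators String whose characters form the terminator set.
#' @return Character vector of sentences.
#' @export
#' @examples
#' segment_sentences("A. B! C")
segment_sentences <- function(text, terminators = DEFAULT_TERMINATORS) {
  if (!is_string(text)) abort_("`text` must be a single string")
  segment_many(text, terminators)[[1]]
}

# vectorized over a character vector of texts; returns a list
segment_many <- function(texts, terminators = DEFAULT_TERMINATORS) {
  if (!is_string(terminators) || !nzchar(terminators))
    abort_("`terminators` must be a non-empty string")
  chars <- strsplit(terminators, "", fixed = TRUE)[[1]]
  cls <- paste0("[", paste(escape_class_char(chars), collapse = ""), "]")
  marked <- gsub(paste0("(", cls, "+)"), "\\1\x01", texts)
  lapply(strsplit(marked, "\x01", fixed = TRUE), function(segs) {
    segs <- trimws(segs)
    segs[nzchar(segs)]
  })
}

# tokenizer registry ---------------------------------------------------------

.tokenizers <- new.env(parent = emptyenv())

#' Register a tokenizer strategy
#'
#' A tokenizer is a function taking one sentence string and returning a
#' character vector of tokens in surface order. Registering under an existing
#' name replaces the previous strategy. The adapter contract is pass-through:
#' whatever token vector the function returns is used unchanged, so output
#' from an external word segmenter can be plugged in directly.
#'
#' @param name Strategy name.
#' @param fn Function of one argument (a sentence) returning a character
#'   vector.
#' @return Invisibly, `name`.
#' @export
register_tokenizer <- function(name, fn) {
  if (!is_string(name)) abort_("tokenizer name must be a single string")
  if (!is.function(fn)) abort_("`fn` must be a function")
  assign(name, fn, envir = .tokenizers)
  invisible(name)
}

resolve_tokenizer <- function(tokenizer) {
  if (is.function(tokenizer)) return(tokenizer)
  if (!is_string(tokenizer)) abort_("`tokenizer` must be a name or function")
  if (!exists(tokenizer, envir = .tokenizers, inherits = FALSE))
    abort_("unregistered tokenizer: %s", tokenizer)
  get(tokenizer, envir = .tokenizers, inherits = FALSE)
}

# default strategy: whitespace split, punctuation-only tokens removed
whitespace_tokenizer <- function(sentence) {
  toks <- strsplit(trimws(sentence), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  toks[!grepl("^[\\p{P}\\p{S}]+$", toks, perl = TRUE)]
}

#' Tokenize one sentence
#'
#' @param sentence A single string.
#' @param tokenizer A registered strategy name or a tokenizer function.
#'   The default `"whitespace"` strategy splits on whitespace and removes
#'   punctuation-only tokens.
#' @return Character vector of tokens.
#' @export
tokenize <- function(sentence, tokenizer = "whitespace") {
  fn <- resolve_tokenizer(tokenizer)
  as.character(fn(sentence))
}

#' Read a stopword list
#'
#' One word per line, UTF-8; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path File path.
#' @return Character vector of stopwords.
#' @export
read_stoplist <- function(path) {
  if (!file.exists(path)) abort_("stoplist file not found: %s", path)
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Remove stopwords from a token vector
#'
#' Exact surface-form matching; token order is preserved. Idempotent.
#'
#' @param tokens Character vector of tokens.
#' @param stoplist Character vector of stopwords.
#' @return Filtered token vector.
#' @export
filter_stopwords <- function(tokens, stoplist) {
  tokens[!(tokens %in% stoplist)]
}

#' Segment and tokenize every narrative of a corpus
#'
#' @param corpus An `emonarr_corpus`.
#' @param tokenizer Tokenizer strategy (see [tokenize()]).
#' @param terminators Sentence terminator set (see [segment_sentences()]).
#' @return A tibble with one row per narrative: `id`, `ordinal`, `primary`,
#'   `n_sentences`, `n_tokens`, and a `tokens` list column of character
#'   vectors in surface order.
#' @export
tokenize_narratives <- function(corpus, tokenizer = "whitespace",
                                terminators = DEFAULT_TERMINATORS) {
  stopifnot(inherits(corpus, "emonarr_corpus"))
  fn <- resolve_tokenizer(tokenizer)
  narr <- corpus$narratives
  sent <- segment_many(narr$text, terminators)
  if (identical(fn, whitespace_tokenizer)) {
    # vectorized fast path for the bundled default strategy
    flat_sent <- unlist(sent, use.names = FALSE)
    tk <- strsplit(trimws(flat_sent), "\\s+")
    narr_of_sent <- rep(seq_along(sent), lengths(sent))
    narr_of_tok <- rep(narr_of_sent, lengths(tk))
    flat <- unlist(tk, use.names = FALSE)
    keep <- nzchar(flat) & !grepl("^[\\p{P}\\p{S}]+$", flat, perl = TRUE)
    toks <- unname(split(flat[keep],
                         factor(narr_of_tok[keep],
                                levels = seq_along(sent))))
  } else {
    toks <- lapply(sent, function(ss)
      as.character(unlist(lapply(ss, fn), use.names = FALSE)))
  }
  tibble::tibble(
    id = narr$id,
    ordinal = narr$ordinal,
    primary = narr$primary,
    n_sentences = lengths(sent),
    n_tokens = lengths(toks),
    tokens = toks
  )
}

#' Whole-corpus token totals by group
#'
#' Reports, per group, the token total with and without stopword filtering
#' (the two corpus sizes conventionally quoted for raw and
#' function-word-removed corpora).
#'
#' @inheritParams tokenize_narratives
#' @param stoplist Character vector of stopwords.
#' @return A tibble with columns `group`, `tokens`, `tokens_filtered`.
#' @export
corpus_token_totals <- function(corpus, stoplist = character(),
                                tokenizer = "whitespace",
                                terminators = DEFAULT_TERMINATORS) {
  tok <- tokenize_narratives(corpus, tokenizer, terminators)
  grp <- corpus$metadata$group[match(tok$id, corpus$metadata$id)]
  groups <- intersect(GROUP_LEVELS, unique(grp))
  res <- lapply(groups, function(g) {
    tk <- unlist(tok$tokens[grp == g], use.names = FALSE)
    tibble::tibble(group = g, tokens = length(tk),
                   tokens_filtered = length(filter_stopwords(tk, stoplist)))
  })
  do.call(rbind, res)
}
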