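# Emotion-word frequency profiles: conditional frequency distributions of
# lexicon words by group, at three aggregation levels. Counting policy for
# tokens carrying several lexicon codes: per-code at the 21-subcategory
# level, once per token (first-listed lexicon entry wins) at the primary5
# and polarity levels, which keeps aggregate conservation exact
# (sum over primaries = sum over polarities = once-per-token emotional
# total, per group).

PROFILE_LEVELS <- c("polarity", "primary5", "sub21")

group_filtered_tokens <- function(corpus, stoplist, tokenizer, terminators) {
  tok <- tokenize_narratives(corpus, tokenizer, terminators)
  grp <- corpus$metadata$group[match(tok$id, corpus$metadata$id)]
  groups <- intersect(GROUP_LEVELS, unique(grp))
  out <- lapply(groups, function(g)
    filter_stopwords(unlist(tok$tokens[grp == g], use.names = FALSE),
                     stoplist))
  names(out) <- groups
  out
}

count_level <- function(tokens, lexicon, level) {
  switch(level,
    sub21 = {
      # a token contributes once per code it maps to
      present <- tokens[tokens %in% lexicon$word]
      wc <- table(present)
      per_row <- as.numeric(wc[lexicon$word])
      per_row[is.na(per_row)] <- 0
      cnt <- vapply(split(per_row, factor(lexicon$code,
                                          levels = EMOTION_CODES)),
                    sum, numeric(1))
      cnt
    },
    primary5 = ,
    polarity = {
      lf <- lexicon_first_entry(lexicon)
      mi <- match(tokens, lf$word)
      hit <- !is.na(mi)
      code <- lf$code[mi[hit]]
      pol <- lf$polarity[mi[hit]]
      if (level == "primary5") {
        prim <- primary_of(code, pol)
        table(factor(prim, levels = PRIMARY_EMOTIONS))
      } else {
        table(factor(pol, levels = POLARITIES))
      }
    }
  )
}

#' Emotion-word frequency table
#'
#' Counts affect-lexicon words per group after stopword filtering, at one of
#' three aggregation levels: `"polarity"` (positive/negative), `"primary5"`
#' (the five primary emotions) or `"sub21"` (the 21 subcategory codes). At
#' `sub21` a token contributes once to every code it maps to; at the
#' aggregated levels each token is attributed exactly once, via its
#' first-listed lexicon entry (with `PC` resolved by that entry's polarity).
#' Both absolute counts and relative counts per 1,000 stopword-filtered
#' tokens are returned, so corpora of unequal size stay comparable.
#'
#' @param corpus An `emonarr_corpus`.
#' @param lexicon Lexicon tibble from [load_lexicon()] (must be non-empty).
#' @param stoplist Character vector of stopwords (default none).
#' @param level Aggregation level.
#' @param tokenizer,terminators Passed to [tokenize_narratives()].
#' @return An object of class `emotion_freq_table`: a list with `level`,
#'   `counts` (tibble `group`, `category`, `count`, `per_1000`) and
#'   `denominators` (named vector of per-group filtered token totals).
#' @export
emotion_counts <- function(corpus, lexicon, stoplist = character(),
                           level = c("sub21", "primary5", "polarity"),
                           tokenizer = "whitespace",
                           terminators = DEFAULT_TERMINATORS) {
  level <- match.arg(level)
  lexicon <- validate_lexicon(lexicon)
  if (!nrow(lexicon)) abort_("the lexicon is empty")
  toks <- group_filtered_tokens(corpus, stoplist, tokenizer, terminators)
  denom <- vapply(toks, length, numeric(1))
  counts <- do.call(rbind, lapply(names(toks), function(g) {
    cnt <- count_level(toks[[g]], lexicon, level)
    tibble::tibble(
      group = g,
      category = names(cnt),
      count = as.numeric(cnt),
      per_1000 = if (denom[[g]] > 0) 1000 * as.numeric(cnt) / denom[[g]]
                 else 0
    )
  }))
  structure(list(level = level, counts = counts, denominators = denom),
            class = "emotion_freq_table")
}

#' @export
print.emotion_freq_table <- function(x, ...) {
  cat(sprintf("<emotion_freq_table> level=%s; denominators: %s\n",
              x$level,
              paste(sprintf("%s=%d", names(x$denominators),
                            as.integer(x$denominators)), collapse = ", ")))
  print(x$counts, n = nrow(x$counts))
  invisible(x)
}

#' Emotion-frequency report at all three levels
#'
#' Convenience wrapper building the polarity, 5-emotion and 21-subcategory
#' tables side by side for both groups, sorted by descending patient count.
#'
#' @inheritParams emotion_counts
#' @return A named list of three tibbles (`polarity`, `primary5`, `sub21`),
#'   each with columns `category`, `count_patient`, `per_1000_patient`,
#'   `count_control`, `per_1000_control`.
#' @export
profile_report <- function(corpus, lexicon, stoplist = character(),
                           tokenizer = "whitespace",
                           terminators = DEFAULT_TERMINATORS) {
  out <- lapply(PROFILE_LEVELS, function(lv) {
    ef <- emotion_counts(corpus, lexicon, stoplist, level = lv,
                         tokenizer = tokenizer, terminators = terminators)
    cn <- ef$counts
    wide <- NULL
    for (g in GROUP_LEVELS) {
      sub <- cn[cn$group == g, c("category", "count", "per_1000")]
      names(sub) <- c("category", paste0("count_", g), paste0("per_1000_", g))
      wide <- if (is.null(wide)) sub else merge(wide, sub, by = "category",
                                                sort = FALSE)
    }
    wide <- tibble::as_tibble(wide)
    if ("count_patient" %in% names(wide))
      wide <- wide[order(-wide$count_patient, wide$category), ]
    wide
  })
  names(out) <- PROFILE_LEVELS
  out
}
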