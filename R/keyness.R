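# Keyness: which words are distinctive of one corpus relative to another.
# The statistic is the two-cell log-likelihood ratio
#
#   -2 ln lambda = 2 * sum_i O_i ln(O_i / E_i),   E_i = N_i * sum(O) / sum(N)
#
# summed over the two corpora only (i = 1, 2), with the x ln x -> 0
# convention for a zero observed cell. This two-cell form is deliberately
# not the four-cell 2x2 G-statistic, which differs numerically; the two-cell
# form is the one used in the corpus-linguistics keyness tradition
# (AntConc-style keyword lists).

#' Two-cell log-likelihood keyness statistic
#'
#' @param a Target-word frequency in corpus 1 (`O_1`).
#' @param b Target-word frequency in corpus 2 (`O_2`).
#' @param n1,n2 Token totals of corpora 1 and 2 (`N_1`, `N_2`).
#' @return The statistic `-2 ln lambda` (vectorized over `a` and `b`);
#'   always finite and `>= 0`, and exactly 0 when `a/n1 == b/n2`.
#' @export
#' @examples
#' ll_statistic(20, 10, 100, 200) # 20 * log(2)
ll_statistic <- function(a, b, n1, n2) {
  if (!all(is.finite(a), is.finite(b), is.finite(n1), is.finite(n2)))
    abort_("all cell values must be finite numbers")
  k <- max(length(a), length(b))
  a <- rep_len(a, k); b <- rep_len(b, k)
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  if (any(n1 <= 0) || any(n2 <= 0)) abort_("corpus totals must be positive")
  if (any(a < 0) || any(b < 0)) abort_("observed frequencies must be >= 0")
  if (any(a > n1) || any(b > n2))
    abort_("observed frequency exceeds its corpus total")
  if (any(a + b == 0)) abort_("no occurrences of the target word (a + b = 0)")
  e1 <- n1 * (a + b) / (n1 + n2)
  e2 <- n2 * (a + b) / (n1 + n2)
  ll <- 2 * (xlogx_ratio(a, e1) + xlogx_ratio(b, e2))
  pmax(ll, 0) # guard against -0/rounding at exact proportionality
}

#' Keyness significance threshold
#'
#' The chi-square (1 df) quantile at cumulative probability `1 - alpha`,
#' truncated or rounded to two decimals. The default (`alpha = 1e-4`,
#' truncation) reproduces the conventional corpus-linguistics cutoff 15.13
#' (the exact quantile is 15.1367...).
#'
#' @param alpha Significance level in (0, 1).
#' @param mode `"truncate"` (default) or `"round"`.
#' @return The threshold, a single number.
#' @export
#' @examples
#' critical_value()            # 15.13
#' critical_value(0.05, "round") # 3.84
critical_value <- function(alpha = 1e-4, mode = c("truncate", "round")) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    abort_("`alpha` must be a single number in (0, 1)")
  q <- qchisq(1 - alpha, df = 1)
  switch(mode, truncate = floor(q * 100) / 100, round = round(q, 2))
}

#' Keyness table for two token streams
#'
#' Ranks every word type by the two-cell log-likelihood statistic. The sign
#' column marks overuse (`"+"`, higher relative frequency in stream 1),
#' underuse (`"-"`) or exact rate equality (`"0"`). Relative frequencies are
#' percentages at full precision (format for display separately); ranking is
#' by descending statistic, ties broken by descending pooled frequency then
#' lexicographically.
#'
#' @param tokens1,tokens2 Character vectors of tokens (both non-empty).
#' @param min_freq Minimum pooled frequency `a + b` for a word to be tested
#'   (default 5; use 1 to include singletons).
#' @param threshold Significance cutoff on the statistic (default
#'   [critical_value()], i.e. 15.13).
#' @return A tibble with columns `word`, `ll`, `freq1`, `rel1`, `freq2`,
#'   `rel2`, `sign`, `significant`; token totals are in attributes `n1`,
#'   `n2`.
#' @export
keyness_table <- function(tokens1, tokens2, min_freq = 5,
                          threshold = critical_value()) {
  if (!length(tokens1) || !length(tokens2))
    abort_("both token streams must be non-empty")
  if (!is.numeric(min_freq) || min_freq < 1)
    abort_("`min_freq` must be >= 1")
  n1 <- length(tokens1)
  n2 <- length(tokens2)
  t1 <- table(tokens1)
  t2 <- table(tokens2)
  vocab <- sort(unique(c(names(t1), names(t2))))
  a <- as.numeric(t1[vocab]); a[is.na(a)] <- 0
  b <- as.numeric(t2[vocab]); b[is.na(b)] <- 0
  keep <- (a + b) >= min_freq
  if (!any(keep)) abort_("no word passes min_freq = %s", min_freq)
  vocab <- vocab[keep]; a <- a[keep]; b <- b[keep]
  ll <- ll_statistic(a, b, n1, n2)
  r1 <- a / n1
  r2 <- b / n2
  res <- tibble::tibble(
    word = vocab,
    ll = ll,
    freq1 = a,
    rel1 = 100 * r1,
    freq2 = b,
    rel2 = 100 * r2,
    sign = ifelse(r1 > r2, "+", ifelse(r1 < r2, "-", "0")),
    significant = ll >= threshold
  )
  res <- res[order(-res$ll, -(res$freq1 + res$freq2), res$word), ]
  attr(res, "n1") <- n1
  attr(res, "n2") <- n2
  attr(res, "threshold") <- threshold
  res
}

#' Per-emotion keyness between groups
#'
#' Restricts each group's token stream to narratives tagged with one primary
#' emotion, then ranks group-distinctive words. Stopwords are retained by
#' default (function words are often the strongest keys); pass a `stoplist`
#' to exclude them.
#'
#' @param corpus An `emonarr_corpus`.
#' @param emotion One of the five primary emotions.
#' @param group_order Character vector of the two groups; stream 1 is the
#'   first. Default `c("patient", "control")`.
#' @param stoplist Optional character vector of stopwords to remove before
#'   counting (default `NULL`: retain).
#' @param min_freq,threshold Passed to [keyness_table()].
#' @param tokenizer,terminators Passed to [tokenize_narratives()].
#' @return An object of class `emotion_keyness`: list with `emotion`,
#'   `groups`, `table` (the [keyness_table()] result) and `more_common` (a
#'   named list of the significant words on each group's side).
#' @export
emotion_keyness <- function(corpus, emotion,
                            group_order = c("patient", "control"),
                            stoplist = NULL, min_freq = 5,
                            threshold = critical_value(),
                            tokenizer = "whitespace",
                            terminators = DEFAULT_TERMINATORS) {
  if (!is_string(emotion) || !(toupper(emotion) %in% PRIMARY_EMOTIONS))
    abort_("`emotion` must be one of %s",
           paste(PRIMARY_EMOTIONS, collapse = ", "))
  emotion <- toupper(emotion)
  if (length(group_order) != 2L || !all(group_order %in% GROUP_LEVELS))
    abort_("`group_order` must be a permutation of %s",
           paste(GROUP_LEVELS, collapse = ", "))
  tok <- tokenize_narratives(corpus, tokenizer, terminators)
  grp <- corpus$metadata$group[match(tok$id, corpus$metadata$id)]
  streams <- lapply(group_order, function(g) {
    sel <- grp == g & tok$primary == emotion
    if (!any(sel))
      abort_("group %s has no narratives of emotion %s", g, emotion)
    tk <- unlist(tok$tokens[sel], use.names = FALSE)
    if (!is.null(stoplist)) tk <- filter_stopwords(tk, stoplist)
    tk
  })
  tab <- keyness_table(streams[[1]], streams[[2]], min_freq = min_freq,
                       threshold = threshold)
  more <- list(
    tab$word[tab$significant & tab$sign == "+"],
    tab$word[tab$significant & tab$sign == "-"]
  )
  names(more) <- group_order
  structure(list(emotion = emotion, groups = group_order, table = tab,
                 more_common = more),
            class = "emotion_keyness")
}

#' @export
print.emotion_keyness <- function(x, ...) {
  cat(sprintf("<emotion_keyness> %s narratives, %s vs %s (n1=%d, n2=%d)\n",
              x$emotion, x$groups[1], x$groups[2],
              attr(x$table, "n1"), attr(x$table, "n2")))
  cat(sprintf("more common in %s: %s\n", x$groups[1],
              paste(x$more_common[[1]], collapse = ", ")))
  cat(sprintf("more common in %s: %s\n", x$groups[2],
              paste(x$more_common[[2]], collapse = ", ")))
  invisible(x)
}
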