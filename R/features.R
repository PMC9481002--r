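# Narrative-complexity ("generic") features, computed per participant over
# that participant's non-EMPTY narratives on unfiltered (stopword-retaining)
# tokens, and compared between groups with Welch's t-test. Min-max
# normalization is a shared affine transform, so raw and normalized
# comparisons yield identical t and p.

#' Per-participant narrative-complexity features
#'
#' For each participant, computed over the concatenation of all their
#' non-EMPTY narratives:
#' * `ttr` — type-token ratio, distinct token forms / total tokens;
#' * `mean_word_length` — total characters / total tokens;
#' * `words_per_sentence` — total tokens / total sentences;
#' * `sentences_per_narrative` — total sentences / narrative count;
#' * `words_per_narrative` — total tokens / narrative count.
#'
#' @param tok Tokenized narratives from [tokenize_narratives()].
#' @return A tibble with one row per participant (columns `id`,
#'   `n_narratives`, plus the five features).
#' @export
participant_features <- function(tok) {
  tok <- tok[tok$primary != "EMPTY", , drop = FALSE]
  if (!nrow(tok)) abort_("no non-EMPTY narratives to compute features on")
  ids <- unique(tok$id)
  rows <- lapply(ids, function(pid) {
    sub <- tok[tok$id == pid, , drop = FALSE]
    tokens <- unlist(sub$tokens, use.names = FALSE)
    n_tok <- length(tokens)
    if (n_tok == 0L)
      abort_("participant %s has no tokens in non-EMPTY narratives", pid)
    n_sent <- sum(sub$n_sentences)
    n_narr <- nrow(sub)
    tibble::tibble(
      id = pid,
      n_narratives = n_narr,
      ttr = length(unique(tokens)) / n_tok,
      mean_word_length = sum(nchar(tokens)) / n_tok,
      words_per_sentence = n_tok / n_sent,
      sentences_per_narrative = n_sent / n_narr,
      words_per_narrative = n_tok / n_narr
    )
  })
  do.call(rbind, rows)
}

#' Per-participant, per-emotion narrative length
#'
#' Words per narrative restricted to narratives tagged with each primary
#' emotion; a participant contributes a row only for emotions they have at
#' least one narrative of.
#'
#' @inheritParams participant_features
#' @return A tibble with columns `id`, `primary`, `n_narratives`,
#'   `words_per_narrative`.
#' @export
emotion_narrative_lengths <- function(tok) {
  tok <- tok[tok$primary != "EMPTY", , drop = FALSE]
  key <- interaction(tok$id, tok$primary, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(tok)), key), function(idx) {
    tibble::tibble(
      id = tok$id[idx[1]],
      primary = tok$primary[idx[1]],
      n_narratives = length(idx),
      words_per_narrative = sum(tok$n_tokens[idx]) / length(idx)
    )
  })
  out <- do.call(rbind, rows)
  out[order(match(out$primary, PRIMARY_EMOTIONS), out$id), ]
}

#' Min-max normalization over a pooled sample
#'
#' `(x - min) / (max - min)`. Applied to the pooled values of both groups, so
#' it is a shared affine transform: Welch's t on the normalized values equals
#' Welch's t on the raw values.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Values rescaled into `[0, 1]`.
#' @export
minmax_normalize <- function(values) {
  if (!is.numeric(values)) abort_("`values` must be numeric")
  if (anyNA(values)) abort_("`values` must not contain NA")
  rng <- range(values)
  if (rng[1] == rng[2])
    abort_("min-max normalization is undefined: all values identical")
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Welch's two-sample t-test
#'
#' Unequal-variance comparison of two group means with Welch-Satterthwaite
#' degrees of freedom and a two-tailed p-value. The sign convention is
#' `t = mean(group1) - mean(group2)` in the argument order given.
#'
#' @param group1,group2 Numeric vectors (each of length >= 2, with nonzero
#'   variance in at least one group).
#' @return A tibble with columns `t`, `df`, `p`, `n1`, `n2`, `mean1`,
#'   `mean2`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(2, 4, 6))
welch_t <- function(group1, group2) {
  if (!is.numeric(group1) || !is.numeric(group2))
    abort_("both groups must be numeric vectors")
  if (length(group1) < 2L || length(group2) < 2L)
    abort_("each group needs at least two values")
  if (var(group1) == 0 && var(group2) == 0)
    abort_("zero variance in both groups: t is undefined")
  ht <- t.test(group1, group2, var.equal = FALSE)
  tibble::tibble(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value,
    n1 = length(group1),
    n2 = length(group2),
    mean1 = mean(group1),
    mean2 = mean(group2)
  )
}

GENERIC_FEATURES <- c("ttr", "mean_word_length", "words_per_sentence",
                      "sentences_per_narrative", "words_per_narrative")

welch_row <- function(x, y) {
  ok <- length(x) >= 2L && length(y) >= 2L &&
    !(var(x) == 0 && var(y) == 0)
  if (ok) {
    w <- welch_t(x, y)
    list(t = w$t, df = w$df, p = w$p, computable = TRUE)
  } else {
    list(t = NA_real_, df = NA_real_, p = NA_real_, computable = FALSE)
  }
}

#' Group comparison of narrative features
#'
#' Builds the generic-feature comparison (one row per feature for the raw
#' values and one for the pooled min-max-normalized values, with group means
#' and Welch's t) and the per-emotion words-per-narrative comparison. Rows
#' where a group has fewer than two participants (or both groups are
#' constant) are marked not computable.
#'
#' @param corpus An `emonarr_corpus` with at least one participant per group.
#' @param tokenizer,terminators Passed to [tokenize_narratives()].
#' @param group_order Character vector of the two groups; the t statistic is
#'   `mean(first) - mean(second)`. Default `c("patient", "control")`.
#' @param p_adjust `"none"` (default) or `"bonferroni"`, applied across the
#'   generic features.
#' @return A list with tibbles `generic` (columns `feature`, `variant`,
#'   `mean1`, `mean2`, `t`, `df`, `p`, `computable`) and `by_emotion`
#'   (columns `emotion`, `n1`, `n2`, `mean1`, `mean2`, `t`, `df`, `p`,
#'   `computable`); the group order is recorded in the `groups` attribute.
#' @export
feature_comparison_table <- function(corpus, tokenizer = "whitespace",
                                     terminators = DEFAULT_TERMINATORS,
                                     group_order = c("patient", "control"),
                                     p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  if (length(group_order) != 2L || !all(group_order %in% GROUP_LEVELS))
    abort_("`group_order` must be a permutation of %s",
           paste(GROUP_LEVELS, collapse = ", "))
  grp_of <- function(ids) corpus$metadata$group[match(ids, corpus$metadata$id)]
  if (!all(group_order %in% corpus$metadata$group))
    abort_("both groups must be present in the corpus")
  tok <- tokenize_narratives(corpus, tokenizer, terminators)
  feats <- participant_features(tok)
  grp <- grp_of(feats$id)

  generic <- do.call(rbind, lapply(GENERIC_FEATURES, function(f) {
    x <- feats[[f]][grp == group_order[1]]
    y <- feats[[f]][grp == group_order[2]]
    raw <- welch_row(x, y)
    pooled <- c(x, y)
    if (length(unique(pooled)) >= 2L) {
      z <- minmax_normalize(pooled)
      zx <- z[seq_along(x)]
      zy <- z[-seq_along(x)]
      norm <- welch_row(zx, zy)
      nmeans <- c(mean(zx), mean(zy))
    } else {
      norm <- list(t = NA_real_, df = NA_real_, p = NA_real_,
                   computable = FALSE)
      nmeans <- c(NA_real_, NA_real_)
    }
    tibble::tibble(
      feature = f,
      variant = c("raw", "normalized"),
      mean1 = c(mean(x), nmeans[1]),
      mean2 = c(mean(y), nmeans[2]),
      t = c(raw$t, norm$t),
      df = c(raw$df, norm$df),
      p = c(raw$p, norm$p),
      computable = c(raw$computable, norm$computable)
    )
  }))
  if (p_adjust == "bonferroni") {
    raw_p <- generic$p[generic$variant == "raw"]
    adj <- stats::p.adjust(raw_p, method = "bonferroni")
    generic$p <- adj[match(generic$feature, GENERIC_FEATURES)]
  }

  lens <- emotion_narrative_lengths(tok)
  lgrp <- grp_of(lens$id)
  by_emotion <- do.call(rbind, lapply(PRIMARY_EMOTIONS, function(e) {
    x <- lens$words_per_narrative[lens$primary == e & lgrp == group_order[1]]
    y <- lens$words_per_narrative[lens$primary == e & lgrp == group_order[2]]
    if (!length(x) && !length(y)) return(NULL)
    w <- welch_row(x, y)
    tibble::tibble(
      emotion = e, n1 = length(x), n2 = length(y),
      mean1 = if (length(x)) mean(x) else NA_real_,
      mean2 = if (length(y)) mean(y) else NA_real_,
      t = w$t, df = w$df, p = w$p, computable = w$computable
    )
  }))
  out <- list(generic = generic, by_emotion = by_emotion)
  attr(out, "groups") <- group_order
  out
}
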