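# Seeded two-group corpus simulator with exact ground-truth bookkeeping.
#
# Every token of a narrative generated under emotion e is drawn from one
# categorical distribution: subcategory code c with probability p[g, c]
# (then uniform over that code's lexicon words), stopword with probability
# q[g], an injected marker word with its configured per-token rate (only in
# narratives matching the marker's emotion), and otherwise a background
# word from a Zipf-distributed vocabulary. Marker mass is taken out of the
# background remainder, so per-code counts are exactly
# Binomial(tokens in non-EMPTY narratives, p[g, c]) given the token total.
# EMPTY narratives emit stopwords/background only: they count toward corpus
# token totals but carry no emotion words, exercising their exclusion path.
#
# Vocabulary words are pseudo-words built from consonant-vowel syllables
# (so the default whitespace tokenizer applies), with per-word length of
# 1 + Poisson(0.5) syllables, fixed per word.

VOWELS <- c("a", "e", "i", "o", "u")
CONSONANTS <- setdiff(letters, VOWELS)

# n distinct CV-syllable pseudo-words; always consonant-initial, so plain
# English marker words starting with a vowel can never collide
make_unique_words <- function(n, syllable_rate = 0.5, exclude = character()) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    k <- 1L + rpois(2L * need + 10L, syllable_rate)
    w <- vapply(k, function(ki)
      paste0(paste0(sample(CONSONANTS, ki, replace = TRUE),
                    sample(VOWELS, ki, replace = TRUE)), collapse = ""),
      character(1))
    out <- setdiff(unique(c(out, w)), exclude)
  }
  out[seq_len(n)]
}

#' Configuration of the synthetic corpus generator
#'
#' All rates are per-group (named by `patient`/`control`) unless noted.
#' Defaults give a small symmetric two-group corpus useful for quick
#' experiments; [cohort_preset()] gives the full study-shaped configuration.
#'
#' @param n_participants Named integer vector, participants per group.
#' @param narrative_rate Groups x 5-emotion matrix of Poisson rates:
#'   narratives per participant per primary emotion.
#' @param empty_rate Poisson rate of EMPTY (emotionless) narratives per
#'   participant.
#' @param sentences_per_narrative Target mean; sentence counts are
#'   `1 + Poisson(mean - 1)` per narrative.
#' @param words_per_sentence Target mean; token counts are
#'   `1 + Poisson(mean - 1)` per sentence.
#' @param vocab_size,zipf_exponent Background vocabulary size and Zipf
#'   rank-frequency exponent.
#' @param stopword_prob Per-token probability of emitting a stopword.
#' @param n_stopwords Size of the generated stoplist.
#' @param words_per_code Lexicon words generated per subcategory code.
#' @param emission_probs Groups x 21-code matrix of per-token emission
#'   probabilities.
#' @param markers Optional tibble with columns `word`, `emotion`, `patient`,
#'   `control`: forced-injection words emitted at the given per-token rate in
#'   narratives of the matching emotion.
#' @param syllable_rate Poisson rate for word length (in 2-character
#'   syllables) minus one.
#' @return A validated object of class `generator_config`.
#' @export
generator_config <- function(n_participants = c(patient = 6, control = 6),
                             narrative_rate = NULL,
                             empty_rate = c(patient = 0.4, control = 0.4),
                             sentences_per_narrative = c(patient = 2.5,
                                                         control = 2.5),
                             words_per_sentence = c(patient = 12,
                                                    control = 12),
                             vocab_size = 500,
                             zipf_exponent = 1.1,
                             stopword_prob = c(patient = 0.15,
                                               control = 0.15),
                             n_stopwords = 20,
                             words_per_code = 2,
                             emission_probs = NULL,
                             markers = NULL,
                             syllable_rate = 0.5) {
  groups <- GROUP_LEVELS
  as_group_vec <- function(x, what) {
    if (length(x) == 1L && is.null(names(x)))
      x <- stats::setNames(rep(x, 2), groups)
    if (!all(groups %in% names(x)))
      abort_("`%s` must be named by %s", what, paste(groups, collapse = ", "))
    x[groups]
  }
  n_participants <- as_group_vec(n_participants, "n_participants")
  empty_rate <- as_group_vec(empty_rate, "empty_rate")
  sentences_per_narrative <- as_group_vec(sentences_per_narrative,
                                          "sentences_per_narrative")
  words_per_sentence <- as_group_vec(words_per_sentence, "words_per_sentence")
  stopword_prob <- as_group_vec(stopword_prob, "stopword_prob")
  if (is.null(narrative_rate))
    narrative_rate <- matrix(4, 2, 5)
  if (is.null(dimnames(narrative_rate)) &&
      all(dim(narrative_rate) == c(2, 5)))
    dimnames(narrative_rate) <- list(groups, PRIMARY_EMOTIONS)
  narrative_rate <- narrative_rate[groups, PRIMARY_EMOTIONS, drop = FALSE]
  if (is.null(emission_probs))
    emission_probs <- matrix(0.003, 2, 21)
  if (is.null(dimnames(emission_probs)) &&
      all(dim(emission_probs) == c(2, 21)))
    dimnames(emission_probs) <- list(groups, EMOTION_CODES)
  emission_probs <- emission_probs[groups, EMOTION_CODES, drop = FALSE]

  if (any(n_participants < 1)) abort_("each group needs >= 1 participant")
  if (any(narrative_rate < 0) || any(empty_rate < 0))
    abort_("narrative rates must be >= 0")
  if (all(rowSums(narrative_rate) == 0))
    abort_("at least one emotion must have a positive narrative rate")
  if (any(sentences_per_narrative < 1) || any(words_per_sentence < 1))
    abort_("sentence/token means must be >= 1")
  if (vocab_size < 21) abort_("vocab_size must be >= 21")
  if (zipf_exponent <= 0) abort_("zipf_exponent must be positive")
  if (any(stopword_prob < 0) || any(stopword_prob >= 1))
    abort_("stopword_prob must be in [0, 1)")
  if (words_per_code < 1) abort_("words_per_code must be >= 1")
  if (any(emission_probs < 0)) abort_("emission probabilities must be >= 0")
  if (!is.null(markers)) {
    markers <- tibble::as_tibble(markers)
    need <- c("word", "emotion", "patient", "control")
    if (!all(need %in% names(markers)))
      abort_("markers need columns %s", paste(need, collapse = ", "))
    if (!all(markers$emotion %in% PRIMARY_EMOTIONS))
      abort_("marker emotions must be primary emotions")
    if (anyDuplicated(markers$word)) abort_("marker words must be unique")
    if (any(markers$patient < 0) || any(markers$control < 0))
      abort_("marker rates must be >= 0")
  }
  # feasibility: code mass + stopword mass + marker mass <= 1 in every
  # narrative context
  for (g in groups) {
    base <- sum(emission_probs[g, ]) + stopword_prob[g]
    mk <- if (is.null(markers)) 0 else {
      by_e <- tapply(markers[[g]], markers$emotion, sum)
      max(c(0, by_e))
    }
    if (base + mk > 1)
      abort_("infeasible config for group %s: %s",
             g, "emission + stopword + marker probabilities exceed 1")
  }
  structure(list(
    n_participants = n_participants,
    narrative_rate = narrative_rate,
    empty_rate = empty_rate,
    sentences_per_narrative = sentences_per_narrative,
    words_per_sentence = words_per_sentence,
    vocab_size = vocab_size,
    zipf_exponent = zipf_exponent,
    stopword_prob = stopword_prob,
    n_stopwords = n_stopwords,
    words_per_code = words_per_code,
    emission_probs = emission_probs,
    markers = markers,
    syllable_rate = syllable_rate
  ), class = "generator_config")
}

#' Study-cohort generator preset
#'
#' Configuration emulating a two-group clinical interview cohort: 34 patients
#' and 24 controls; expected group token totals near 167,795 and 121,372;
#' words per sentence averaging 23.7 (patients) vs 19.5 (controls); sentences
#' per narrative 2.41 vs 4.11; stopword emission matching the quoted raw vs
#' function-word-removed corpus sizes (15.4% / 12.3%); per-code emission of
#' 0.002 with the patient rate doubled for NC, NE, NN, PA, PG and PB (the
#' fear/disgust/happiness inflation direction); 5% EMPTY narratives; and two
#' 10x-ratio marker words injected into SAD narratives ("isolation" on the
#' patient side, "outbreak" on the control side, 0.4% vs 0.04%).
#'
#' @return A `generator_config`.
#' @export
cohort_preset <- function() {
  groups <- GROUP_LEVELS
  n_p <- c(patient = 34, control = 24)
  token_targets <- c(patient = 167795, control = 121372)
  filtered_targets <- c(patient = 141878, control = 106499)
  wps <- c(patient = 23.7, control = 19.5)
  spn <- c(patient = 2.41, control = 4.11)
  empty_frac <- 0.05
  narr_per_participant <- token_targets / n_p / (wps * spn)
  narrative_rate <- matrix(
    rep(narr_per_participant * (1 - empty_frac) / 5, 5), nrow = 2,
    dimnames = list(groups, PRIMARY_EMOTIONS))
  emission <- matrix(0.002, 2, 21, dimnames = list(groups, EMOTION_CODES))
  emission["patient", c("NC", "NE", "NN", "PA", "PG", "PB")] <- 0.004
  generator_config(
    n_participants = n_p,
    narrative_rate = narrative_rate,
    empty_rate = narr_per_participant * empty_frac,
    sentences_per_narrative = spn,
    words_per_sentence = wps,
    vocab_size = 2000,
    zipf_exponent = 1.1,
    stopword_prob = 1 - filtered_targets / token_targets,
    n_stopwords = 40,
    words_per_code = 2,
    emission_probs = emission,
    markers = tibble::tibble(
      word = c("isolation", "outbreak"),
      emotion = "SAD",
      patient = c(0.004, 0.0004),
      control = c(0.0004, 0.004)
    )
  )
}

# modal emitted code among codes admissible for the narrative's primary;
# falls back to the emotion's first code when none was emitted
modal_subcode <- function(codes_vec, emotion) {
  cand <- codes_for_primary(emotion)
  emitted <- codes_vec[!is.na(codes_vec) & codes_vec %in% cand]
  if (!length(emitted)) return(cand[1])
  tb <- table(factor(emitted, levels = cand))
  cand[which.max(tb)]
}

#' Generate a synthetic two-group tagged corpus
#'
#' Deterministic given `seed`. Returns the corpus together with the lexicon
#' and stoplist used to generate it and a `synthetic_truth` object holding
#' exact realized bookkeeping (token totals, per-code emission counts,
#' stopword and marker counts, narrative counts per emotion) against which
#' every downstream statistic can be validated.
#'
#' @param config A [generator_config()].
#' @param seed Integer random seed.
#' @return A list with elements `corpus` (`emonarr_corpus`), `lexicon`
#'   (tibble), `stoplist` (character), `truth` (`synthetic_truth`).
#' @export
generate_corpus <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(as.integer(seed))
  groups <- GROUP_LEVELS
  wpc <- config$words_per_code
  n_lex <- 21L * wpc
  marker_words <- if (is.null(config$markers)) character()
                  else config$markers$word
  pool <- make_unique_words(n_lex + config$n_stopwords + config$vocab_size,
                            config$syllable_rate, exclude = marker_words)
  lex_words <- pool[seq_len(n_lex)]
  lexicon <- tibble::tibble(
    word = lex_words,
    code = rep(EMOTION_CODES, each = wpc),
    polarity = NA_character_
  )
  tax_pol <- ifelse(is.na(CODE_PRIMARY[lexicon$code]), NA,
                    ifelse(CODE_PRIMARY[lexicon$code] == "HAPPY",
                           "positive", "negative"))
  lexicon$polarity <- tax_pol
  # PC is dual: alternate polarities across its entries
  pc <- which(lexicon$code == "PC")
  lexicon$polarity[pc] <- rep(c("negative", "positive"),
                              length.out = length(pc))
  lexicon <- validate_lexicon(lexicon)
  words_by_code <- split(lexicon$word, factor(lexicon$code,
                                              levels = EMOTION_CODES))
  stoplist <- pool[n_lex + seq_len(config$n_stopwords)]
  vocab <- pool[n_lex + config$n_stopwords + seq_len(config$vocab_size)]
  zipf_p <- seq_along(vocab)^(-config$zipf_exponent)

  markers <- config$markers
  n_mark <- if (is.null(markers)) 0L else nrow(markers)
  id_prefix <- c(patient = "pt", control = "ct")

  md_rows <- list()
  narr_rows <- list()
  truth_groups <- list()

  for (g in groups) {
    n_p <- config$n_participants[[g]]
    ids <- sprintf("%s%03d", id_prefix[[g]], seq_len(n_p))
    lam <- config$narrative_rate[g, ]
    K <- matrix(rpois(n_p * 5L, rep(lam, each = n_p)), n_p, 5L)
    ke <- rpois(n_p, config$empty_rate[[g]])
    none <- rowSums(K) == 0L
    K[none, which.max(lam)] <- K[none, which.max(lam)] + 1L

    narr_id <- list()
    narr_emo <- list()
    for (i in seq_len(n_p)) {
      e <- c(rep(PRIMARY_EMOTIONS, K[i, ]), rep("EMPTY", ke[i]))
      e <- if (length(e) > 1L) sample(e) else e
      narr_id[[i]] <- rep(ids[i], length(e))
      narr_emo[[i]] <- e
    }
    narr_id <- unlist(narr_id)
    narr_emo <- unlist(narr_emo)
    n_narr <- length(narr_emo)

    s <- 1L + rpois(n_narr, config$sentences_per_narrative[[g]] - 1)
    sent_narr <- rep(seq_len(n_narr), s)
    tps <- 1L + rpois(sum(s), config$words_per_sentence[[g]] - 1)
    tok_per_narr <- as.integer(rowsum(tps, sent_narr))
    sent_sizes <- split(tps, sent_narr)

    tokens_by_narr <- vector("list", n_narr)
    codes_by_narr <- vector("list", n_narr)
    code_counts <- stats::setNames(numeric(21), EMOTION_CODES)
    stop_count <- 0
    marker_counts <- stats::setNames(numeric(n_mark),
                                     if (n_mark) markers$word else NULL)
    tok_nonempty <- 0

    for (e in unique(narr_emo)) {
      nidx <- which(narr_emo == e)
      cnt <- tok_per_narr[nidx]
      ntok <- sum(cnt)
      p_codes <- if (e == "EMPTY") numeric(21) else config$emission_probs[g, ]
      p_mark <- if (n_mark && e != "EMPTY") {
        ifelse(markers$emotion == e, markers[[g]], 0)
      } else {
        numeric(n_mark)
      }
      q <- config$stopword_prob[[g]]
      p_bg <- 1 - sum(p_codes) - q - sum(p_mark)
      prob <- c(p_codes, q, p_mark, p_bg)
      d <- sample.int(length(prob), ntok, replace = TRUE, prob = prob)
      w <- character(ntok)
      for (j in seq_len(21)) {
        sel <- d == j
        if (any(sel)) w[sel] <- sample(words_by_code[[j]], sum(sel),
                                       replace = TRUE)
      }
      sel <- d == 22L
      if (any(sel)) w[sel] <- sample(stoplist, sum(sel), replace = TRUE)
      if (n_mark) for (j in seq_len(n_mark)) {
        sel <- d == 22L + j
        if (any(sel)) w[sel] <- markers$word[j]
        marker_counts[j] <- marker_counts[j] + sum(sel)
      }
      sel <- d == 22L + n_mark + 1L
      if (any(sel)) w[sel] <- vocab[sample.int(length(vocab), sum(sel),
                                               replace = TRUE, prob = zipf_p)]
      alloc <- factor(rep(nidx, cnt), levels = nidx)
      tokens_by_narr[nidx] <- unname(split(w, alloc))
      codes_by_narr[nidx] <- unname(split(
        ifelse(d <= 21L, EMOTION_CODES[pmin(d, 21L)], NA_character_), alloc))
      code_counts <- code_counts + tabulate(d[d <= 21L], 21L)
      stop_count <- stop_count + sum(d == 22L)
      if (e != "EMPTY") tok_nonempty <- tok_nonempty + ntok
    }

    text <- vapply(seq_len(n_narr), function(k) {
      sizes <- sent_sizes[[k]]
      idx <- rep(seq_along(sizes), sizes)
      sents <- vapply(split(tokens_by_narr[[k]], idx), function(sv)
        paste(c(sv, "."), collapse = " "), character(1))
      paste(sents, collapse = " ")
    }, character(1))
    codes <- lapply(seq_len(n_narr), function(k) {
      if (narr_emo[k] == "EMPTY") character()
      else modal_subcode(codes_by_narr[[k]], narr_emo[k])
    })
    ordinal <- unlist(lapply(ids, function(pid) seq_len(sum(narr_id == pid))))

    narr_rows[[g]] <- tibble::tibble(
      id = narr_id, ordinal = ordinal, primary = narr_emo,
      codes = codes, text = text
    )
    age_mean <- c(patient = 38.82, control = 27.91)[[g]]
    age_sd <- c(patient = 9.95, control = 8.28)[[g]]
    md_rows[[g]] <- tibble::tibble(
      id = ids,
      group = g,
      gender = sample(c("male", "female"), n_p, replace = TRUE),
      marital_status = sample(c("married", "unmarried"), n_p, replace = TRUE),
      age = pmax(18, round(rnorm(n_p, age_mean, age_sd))),
      days_in_hospital = if (g == "patient") rpois(n_p, 17.29)
                         else NA_real_
    )
    truth_groups[[g]] <- list(
      n_participants = n_p,
      narrative_counts = as.list(table(factor(narr_emo,
        levels = c(PRIMARY_EMOTIONS, "EMPTY")))),
      token_total = sum(tok_per_narr),
      token_total_nonempty = tok_nonempty,
      stopword_count = stop_count,
      filtered_token_total = sum(tok_per_narr) - stop_count,
      code_counts = as.list(code_counts),
      marker_counts = as.list(marker_counts)
    )
  }

  corpus <- new_corpus(do.call(rbind, md_rows), do.call(rbind, narr_rows))
  truth <- structure(list(seed = as.integer(seed), config = config,
                          groups = truth_groups),
                     class = "synthetic_truth")
  list(corpus = corpus, lexicon = lexicon, stoplist = stoplist, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> seed", x$seed, "\n")
  for (g in names(x$groups)) {
    tg <- x$groups[[g]]
    cat(sprintf("  %s: %d participants, %d tokens (%d in non-EMPTY, %d %s\n",
                g, tg$n_participants, tg$token_total,
                tg$token_total_nonempty, tg$filtered_token_total,
                "after stopword removal)"))
  }
  invisible(x)
}

#' Write generator ground truth as JSON
#'
#' @param truth A `synthetic_truth`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  cfg_list <- lapply(unclass(cfg), function(x) {
    if (is.matrix(x)) as.data.frame(x) else x
  })
  jsonlite::write_json(
    list(seed = truth$seed, config = cfg_list, groups = truth$groups),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
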