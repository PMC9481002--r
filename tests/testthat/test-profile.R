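lex <- load_lexicon(toy_lexicon_path())

test_that("a repeated lexicon word surfaces at every aggregation level", {
  cps <- make_corpus(
    ids = c("p1", "c1"), groups = c("patient", "control"),
    primary = c("FEAR", "HAPPY"), codes = list("NC", "PA"),
    text = c("dread of dread and dread .", "fine day .")
  )
  sub <- emotion_counts(cps, lex, level = "sub21")$counts
  expect_equal(sub$count[sub$group == "patient" & sub$category == "NC"], 3)
  pri <- emotion_counts(cps, lex, level = "primary5")$counts
  expect_equal(pri$count[pri$group == "patient" & pri$category == "FEAR"], 3)
  pol <- emotion_counts(cps, lex, level = "polarity")$counts
  expect_equal(pol$count[pol$group == "patient" &
                           pol$category == "negative"], 3)
  # no lexicon words at all -> all-zero rows
  expect_true(all(sub$count[sub$group == "control"] == 0))
})

test_that("stopword filtering shrinks the relative-count denominator", {
  cps <- make_corpus("p1", "patient", "FEAR", list("NC"),
                     "the dread of the night .")
  ef <- emotion_counts(cps, lex, stoplist = c("the", "of"), level = "sub21")
  expect_equal(unname(ef$denominators["patient"]), 2)
  expect_equal(ef$counts$per_1000[ef$counts$category == "NC"], 500)
})

test_that("a multi-code word counts per code at sub21 but once when aggregated", {
  # "gloomy" maps to NB (SAD, first listed) and NE (FEAR)
  cps <- make_corpus(
    ids = c("p1", "c1"), groups = c("patient", "control"),
    primary = c("SAD", "SAD"), codes = list("NB", "NB"),
    text = c("gloomy gloomy .", "calm words .")
  )
  sub <- emotion_counts(cps, lex, level = "sub21")$counts
  expect_equal(sub$count[sub$group == "patient" & sub$category == "NB"], 2)
  expect_equal(sub$count[sub$group == "patient" & sub$category == "NE"], 2)
  pri <- emotion_counts(cps, lex, level = "primary5")$counts
  expect_equal(pri$count[pri$group == "patient" & pri$category == "SAD"], 2)
  expect_equal(pri$count[pri$group == "patient" & pri$category == "FEAR"], 0)
})

test_that("counts conserve: primaries, polarities and the emotional total agree", {
  gen <- small_gen()
  pri <- emotion_counts(gen$corpus, gen$lexicon, gen$stoplist,
                        level = "primary5")$counts
  pol <- emotion_counts(gen$corpus, gen$lexicon, gen$stoplist,
                        level = "polarity")$counts
  for (g in c("patient", "control")) {
    expect_equal(sum(pri$count[pri$group == g]),
                 sum(pol$count[pol$group == g]))
  }
  # the generator lexicon has one code per word, so the sub21 table must
  # match the generator's exact per-code emission counts
  sub <- emotion_counts(gen$corpus, gen$lexicon, gen$stoplist,
                        level = "sub21")$counts
  for (g in c("patient", "control")) {
    truth_counts <- unlist(gen$truth$groups[[g]]$code_counts)
    got <- sub$count[sub$group == g]
    names(got) <- sub$category[sub$group == g]
    expect_equal(got[names(truth_counts)], truth_counts)
    # ... and sub21 totals then equal the aggregated totals
    expect_equal(sum(got), sum(pri$count[pri$group == g]))
  }
})

test_that("relative counts are invariant under duplicating a group's participants", {
  base <- make_corpus(
    ids = c("p1", "c1"), groups = c("patient", "control"),
    primary = c("FEAR", "FEAR"), codes = list("NC", "NC"),
    text = c("dread every night .", "calm night .")
  )
  dup <- make_corpus(
    ids = c("p1", "p2", "c1"),
    groups = c("patient", "patient", "control"),
    primary = c("FEAR", "FEAR", "FEAR"),
    codes = list("NC", "NC", "NC"),
    text = c("dread every night .", "dread every night .", "calm night .")
  )
  a <- emotion_counts(base, lex, level = "sub21")
  b <- emotion_counts(dup, lex, level = "sub21")
  pa <- a$counts[a$counts$group == "patient", ]
  pb <- b$counts[b$counts$group == "patient", ]
  expect_equal(pa$per_1000, pb$per_1000)
  expect_equal(pb$count[pb$category == "NC"],
               2 * pa$count[pa$category == "NC"])
})

test_that("patient-inflated codes come out higher in the 21-way profile", {
  gen <- cohort_gen()
  rep3 <- profile_report(gen$corpus, gen$lexicon, gen$stoplist)
  s21 <- rep3$sub21
  inflated <- c("NC", "NE", "NN", "PA", "PG", "PB")
  sel <- s21$category %in% inflated
  expect_true(all(s21$per_1000_patient[sel] > s21$per_1000_control[sel]))
  # the aggregated 5-way direction follows (FEAR, DISGUST, HAPPY higher)
  p5 <- rep3$primary5
  for (e in c("FEAR", "DISGUST", "HAPPY")) {
    expect_gt(p5$per_1000_patient[p5$category == e],
              p5$per_1000_control[p5$category == e])
  }
  # report tables are sorted by descending patient count
  expect_true(all(diff(s21$count_patient) <= 0))
})

test_that("an empty lexicon is rejected", {
  gen <- small_gen()
  empty <- tibble::tibble(word = character(), code = character(),
                          polarity = character())
  expect_error(emotion_counts(gen$corpus, empty), "empty")
})
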