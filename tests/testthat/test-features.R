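test_that("generic features compute the documented ratios on a toy narrative", {
  cps <- make_corpus(
    ids = "p1", groups = "patient", primary = "SAD",
    codes = list("NB"),
    text = "a b . a c ."
  )
  f <- participant_features(tokenize_narratives(cps))
  expect_equal(f$ttr, 3 / 4)          # types a,b,c over 4 tokens
  expect_equal(f$words_per_sentence, 2)
  expect_equal(f$sentences_per_narrative, 2)
  expect_equal(f$words_per_narrative, 4)
  expect_equal(f$mean_word_length, 1)

  # mean word length: tokens of 2 and 3 characters average 2.5
  cps2 <- make_corpus("p1", "patient", "SAD", list("NB"), "ab abc .")
  f2 <- participant_features(tokenize_narratives(cps2))
  expect_equal(f2$mean_word_length, 2.5)
})

test_that("EMPTY narratives are excluded from feature computation", {
  cps <- make_corpus(
    ids = c("p1", "p1"), groups = c("patient", "patient"),
    primary = c("SAD", "EMPTY"), codes = list("NB", character()),
    text = c("a b .", "x y z w .")
  )
  f <- participant_features(tokenize_narratives(cps))
  expect_equal(f$words_per_narrative, 2)
  expect_equal(f$n_narratives, 1L)
})

test_that("min-max normalization rescales into [0,1] with endpoints attained", {
  expect_equal(minmax_normalize(c(1, 3, 5)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0, 0.25, 1)), c(0, 0.25, 1))
  z <- minmax_normalize(rnorm(20))
  expect_true(min(z) == 0 && max(z) == 1)
  expect_error(minmax_normalize(c(2, 2, 2)), "identical")
})

test_that("welch_t matches the closed-form hand evaluation and the oracle", {
  w <- welch_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(w$t, -2 / sqrt(5 / 3), tolerance = 1e-12) # -1.5492
  expect_equal(w$df, 50 / 17, tolerance = 1e-12)         # 2.9412

  set.seed(101)
  for (i in 1:50) {
    x <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    w <- welch_t(x, y)
    o <- welch_oracle(x, y)
    expect_equal(w$t, o$t, tolerance = 1e-9)
    expect_equal(w$df, o$df, tolerance = 1e-9)
    expect_equal(w$p, o$p, tolerance = 1e-9)
  }
})

test_that("welch_t symmetry and degenerate cases behave", {
  x <- c(5, 7, 9, 4)
  y <- c(1, 2, 2, 8, 3)
  a <- welch_t(x, y)
  b <- welch_t(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(c(1), c(1, 2)), "two values")
  expect_error(welch_t(c(2, 2), c(3, 3)), "zero variance")
})

test_that("welch t and p are invariant under pooled min-max normalization", {
  set.seed(202)
  for (i in 1:20) {
    x <- rnorm(10, 5, 2)
    y <- rnorm(8, 6, 1)
    z <- minmax_normalize(c(x, y))
    raw <- welch_t(x, y)
    nrm <- welch_t(z[1:10], z[11:18])
    expect_equal(raw$t, nrm$t, tolerance = 1e-9)
    expect_equal(raw$p, nrm$p, tolerance = 1e-9)
  }
})

test_that("per-emotion narrative lengths reconstruct the overall value", {
  gen <- small_gen()
  tok <- tokenize_narratives(gen$corpus)
  f <- participant_features(tok)
  lens <- emotion_narrative_lengths(tok)
  for (pid in f$id) {
    sub <- lens[lens$id == pid, ]
    overall <- sum(sub$words_per_narrative * sub$n_narratives) /
      sum(sub$n_narratives)
    expect_equal(overall, f$words_per_narrative[f$id == pid])
  }
})

test_that("comparison table marks one-participant groups not computable", {
  cps <- toy_corpus()
  cmp <- feature_comparison_table(cps)
  gen_raw <- cmp$generic[cmp$generic$variant == "raw", ]
  expect_false(any(gen_raw$computable))
  # the group "means" are then the single participant's values
  tok <- tokenize_narratives(cps)
  f <- participant_features(tok)
  expect_equal(gen_raw$mean1[gen_raw$feature == "ttr"],
               f$ttr[f$id == "p1"])
  expect_equal(gen_raw$mean2[gen_raw$feature == "ttr"],
               f$ttr[f$id == "c1"])
})

test_that("raw and normalized comparison rows share t, df and p", {
  gen <- small_gen()
  cmp <- feature_comparison_table(gen$corpus)
  g <- cmp$generic
  for (f in unique(g$feature)) {
    raw <- g[g$feature == f & g$variant == "raw", ]
    nrm <- g[g$feature == f & g$variant == "normalized", ]
    expect_equal(raw$t, nrm$t, tolerance = 1e-9)
    expect_equal(raw$p, nrm$p, tolerance = 1e-9)
    expect_true(all(c(nrm$mean1, nrm$mean2) >= 0 &
                      c(nrm$mean1, nrm$mean2) <= 1))
  }
})

test_that("group order controls the sign convention of t", {
  gen <- small_gen()
  a <- feature_comparison_table(gen$corpus,
                                group_order = c("patient", "control"))
  b <- feature_comparison_table(gen$corpus,
                                group_order = c("control", "patient"))
  expect_equal(a$generic$t, -b$generic$t, tolerance = 1e-12)
  expect_equal(a$generic$p, b$generic$p, tolerance = 1e-12)
})
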