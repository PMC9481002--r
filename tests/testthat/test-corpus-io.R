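test_that("tag lines parse with case and whitespace normalization", {
  t1 <- parse_tag("++HAPPY (PH/PD) ++:")
  expect_identical(t1$primary, "HAPPY")
  expect_identical(t1$codes, c("PH", "PD"))

  t2 <- parse_tag("++EMPTY++")
  expect_identical(t2$primary, "EMPTY")
  expect_identical(t2$codes, character())

  t3 <- parse_tag("++fear( nc )++")
  expect_identical(t3$primary, "FEAR")
  expect_identical(t3$codes, "NC")
})

test_that("malformed or inconsistent tags are rejected with the offender named", {
  expect_error(parse_tag("+HAPPY++"), "malformed")
  expect_error(parse_tag("++HAPPY(PH)"), "malformed")
  expect_error(parse_tag("++JOYFUL++"), "JOYFUL")
  expect_error(parse_tag("++HAPPY(XX)++"), "XX")
  expect_error(parse_tag("++EMPTY(PA)++"), "EMPTY")
  expect_error(parse_tag("++SAD(NA)++"), "NA")      # NA belongs to ANGRY
  expect_error(parse_tag("++HAPPY(PH/PH)++"), "duplicate")
  expect_error(parse_tag("++SAD(NB)++ extra words"), "trailing")
})

test_that("canonical form has no interior spaces and round-trips", {
  expect_identical(format(emotion_tag("HAPPY", c("PH", "PD"))),
                   "++HAPPY(PH/PD)++")
  expect_identical(format(emotion_tag("EMPTY")), "++EMPTY++")

  # parse(canonical(t)) == t for every representable single-code tag,
  # candidate codes taken from the taxonomy table (PC under FEAR and HAPPY)
  tax <- emotion_taxonomy()
  for (p in c("HAPPY", "SAD", "ANGRY", "FEAR", "DISGUST")) {
    codes <- tax$code[tax$primary == p]
    if (p %in% c("FEAR", "HAPPY")) codes <- c(codes, "PC")
    for (cd in codes) {
      tag <- emotion_tag(p, cd)
      expect_identical(parse_tag(format(tag)), tag)
    }
    # and one multi-code tag per primary
    tag <- emotion_tag(p, codes)
    expect_identical(parse_tag(format(tag)), tag)
  }
})

test_that("a minimal well-formed corpus reads into one participant/narrative", {
  d <- withr::local_tempdir()
  dir.create(file.path(d, "corpus"))
  writeLines(c("++SAD(NB)++", "I cried all the way ."),
             file.path(d, "corpus", "p1.txt"))
  writeLines(c("id\tgroup\tgender\tmarital_status\tage\tdays_in_hospital",
               "p1\tpatient\tfemale\tmarried\t38\t17"),
             file.path(d, "meta.tsv"))
  cps <- read_corpus(file.path(d, "corpus"), file.path(d, "meta.tsv"))
  expect_s3_class(cps, "emonarr_corpus")
  expect_identical(nrow(cps$metadata), 1L)
  expect_identical(nrow(cps$narratives), 1L)
  expect_identical(cps$narratives$primary, "SAD")
  expect_identical(cps$narratives$codes[[1]], "NB")
  expect_identical(cps$narratives$text, "I cried all the way .")
})

test_that("degenerate corpus files are rejected", {
  d <- withr::local_tempdir()
  dir.create(file.path(d, "corpus"))
  meta <- c("id\tgroup\tgender\tmarital_status\tage\tdays_in_hospital",
            "p1\tpatient\t\t\t\t")
  writeLines(meta, file.path(d, "meta.tsv"))

  # two tags back-to-back with no intervening text
  writeLines(c("++SAD(NB)++", "++FEAR(NC)++", "text"),
             file.path(d, "corpus", "p1.txt"))
  expect_error(read_corpus(file.path(d, "corpus"), file.path(d, "meta.tsv")),
               "no narrative text")

  # text before the first tag
  writeLines(c("stray text", "++SAD(NB)++", "ok text"),
             file.path(d, "corpus", "p1.txt"))
  expect_error(read_corpus(file.path(d, "corpus"), file.path(d, "meta.tsv")),
               "before the first tag")

  # no tags at all
  writeLines("just words", file.path(d, "corpus", "p1.txt"))
  expect_error(read_corpus(file.path(d, "corpus"), file.path(d, "meta.tsv")),
               "no tags")

  # metadata id without a file / file without metadata
  writeLines(c("++SAD(NB)++", "ok"), file.path(d, "corpus", "p1.txt"))
  writeLines(c(meta, "p2\tpatient\t\t\t\t"), file.path(d, "meta.tsv"))
  expect_error(read_corpus(file.path(d, "corpus"), file.path(d, "meta.tsv")),
               "no corpus file")
  writeLines(meta[1:2], file.path(d, "meta.tsv"))
  writeLines(c("++SAD(NB)++", "ok"), file.path(d, "corpus", "p2.txt"))
  expect_error(read_corpus(file.path(d, "corpus"), file.path(d, "meta.tsv")),
               "no metadata row")
})

test_that("metadata invariants are enforced", {
  d <- withr::local_tempdir()
  dir.create(file.path(d, "corpus"))
  writeLines(c("++SAD(NB)++", "ok"), file.path(d, "corpus", "c1.txt"))
  writeLines(c("id\tgroup\tgender\tmarital_status\tage\tdays_in_hospital",
               "c1\tcontrol\t\t\t\t12"),
             file.path(d, "meta.tsv"))
  expect_error(read_corpus(file.path(d, "corpus"), file.path(d, "meta.tsv")),
               "days_in_hospital")
  writeLines(c("id\tgroup\tgender\tmarital_status\tage\tdays_in_hospital",
               "c1\tvisitor\t\t\t\t"),
             file.path(d, "meta.tsv"))
  expect_error(read_corpus(file.path(d, "corpus"), file.path(d, "meta.tsv")),
               "group")
})

test_that("write/read round-trip is the identity on generated corpora", {
  for (seed in c(11, 12)) {
    gen <- generate_corpus(small_config(), seed)
    d <- withr::local_tempdir()
    write_corpus(gen$corpus, file.path(d, "corpus"),
                 file.path(d, "meta.tsv"))
    back <- read_corpus(file.path(d, "corpus"), file.path(d, "meta.tsv"))
    expect_equal(back$metadata, gen$corpus$metadata)
    expect_equal(back$narratives, gen$corpus$narratives)
    # narrative counts (total and per emotion) preserved
    expect_identical(table(back$narratives$primary),
                     table(gen$corpus$narratives$primary))
  }
})

test_that("the bundled toy corpus reads and round-trips", {
  cps <- toy_corpus()
  expect_identical(sort(cps$metadata$group), c("control", "patient"))
  expect_identical(nrow(cps$narratives), 7L)
  expect_identical(cps$narratives$codes[[which(cps$narratives$primary == "FEAR")]],
                   c("NC", "NI"))
  d <- withr::local_tempdir()
  write_corpus(cps, file.path(d, "corpus"), file.path(d, "meta.tsv"))
  back <- read_corpus(file.path(d, "corpus"), file.path(d, "meta.tsv"))
  expect_equal(back$narratives, cps$narratives)
  expect_equal(back$metadata, cps$metadata)
})
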