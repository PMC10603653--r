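test_that("records validate their three fields", {
  r <- knowledgeRecord("tiger", "big striped cat", "fur:striped")
  expect_s4_class(r, "KnowledgeRecord")
  expect_identical(speciesNames(r), "tiger")

  long <- paste(rep("word", 101), collapse = " ")
  expect_error(knowledgeRecord("tiger", long), "100 words")
  expect_error(knowledgeRecord("", "ok"), "non-empty")
  expect_error(knowledgeRecord("x", "ok", c("fur:striped", "")),
               "empty feature")
  # exactly 100 words is still valid
  expect_s4_class(knowledgeRecord("y", paste(rep("w", 100), collapse = " ")),
                  "KnowledgeRecord")
})

test_that("loading records from JSON validates schema and uniqueness", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0(
    '[{"species_name":"tiger","description":"big striped cat",',
    '"features":["fur:striped"]},',
    '{"species_name":"panda","description":"black and white bear",',
    '"features":["fur:patched","diet:bamboo"]}]'), path)
  recs <- loadKnowledgeRecords(path)
  expect_length(recs, 2)
  expect_identical(recs[[1]]@speciesName, "tiger")
  expect_identical(recs[[2]]@features, c("fur:patched", "diet:bamboo"))

  # missing field named in the error
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"species_name":"tiger","features":[]}]', bad)
  expect_error(loadKnowledgeRecords(bad), "missing field.*description")

  dup <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0(
    '[{"species_name":"tiger","description":"a","features":[]},',
    '{"species_name":"tiger","description":"b","features":[]}]'), dup)
  expect_error(loadKnowledgeRecords(dup), "duplicate.*tiger")

  expect_error(loadKnowledgeRecords(tempfile()), "not found")
})

test_that("assembly yields the ordered 2K+M text set", {
  # K=1, M=0: only a name prompt and a description
  one <- assembleKnowledgeTexts(list(knowledgeRecord("ibis", "a wading bird")))
  expect_length(one@texts, 2)
  expect_identical(textRoles(one), c("name", "description"))
  expect_identical(one@texts[1], "a photo of a ibis")

  # K=2 sharing 3 distinct features in total: 2*2+3 = 7 texts
  recs <- list(
    knowledgeRecord("tiger", "big striped cat", c("fur:striped", "size:large")),
    knowledgeRecord("leopard", "spotted cat", c("fur:spotted", "size:large")))
  ts <- assembleKnowledgeTexts(recs)
  expect_length(ts@texts, 7)
  expect_identical(nSpecies(ts), 2L)
  expect_identical(nFeatures(ts), 3L)
  expect_identical(table(textRoles(ts))[c("feature", "name", "description")],
                   table(c(rep("feature", 3), rep("name", 2),
                           rep("description", 2)))[c("feature", "name",
                                                     "description")])
  expect_identical(classIndex(ts), c(NA_integer_, NA_integer_, NA_integer_,
                                     0L, 1L, 0L, 1L))

  expect_error(assembleKnowledgeTexts(list()), "at least one")
  expect_error(assembleKnowledgeTexts(c(recs, recs[1])), "duplicate")

  # the name template is configurable
  ts2 <- assembleKnowledgeTexts(recs[1], nameTemplate = "%s in the wild")
  expect_identical(ts2@texts[3], "tiger in the wild")
})

test_that("feature pool is the deduplicated first-seen union", {
  withr::local_seed(11)
  for (rep in 1:20) {
    K <- sample(2:6, 1)
    pool <- sprintf("f%02d", 1:12)
    recs <- lapply(seq_len(K), function(i)
      knowledgeRecord(sprintf("sp%d", i), "d",
                      sample(pool, sample(0:5, 1), replace = TRUE)))
    ts <- assembleKnowledgeTexts(recs)
    # brute-force set-union oracle, first-seen order
    expected <- character()
    for (r in recs) for (f in r@features)
      if (!f %in% expected) expected <- c(expected, f)
    expect_identical(ts@texts[seq_along(expected)], expected)
    expect_length(ts@texts, 2L * K + length(expected))
  }
})

test_that("assembly is deterministic and round-trips through file", {
  recs <- tinyRecords(4)
  ts1 <- assembleKnowledgeTexts(recs)
  ts2 <- assembleKnowledgeTexts(recs)
  expect_identical(ts1, ts2)

  path <- withr::local_tempfile(fileext = ".json")
  writeKnowledgeRecords(recs, path)
  expect_identical(assembleKnowledgeTexts(loadKnowledgeRecords(path)), ts1)
})
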