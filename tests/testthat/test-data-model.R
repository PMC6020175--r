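test_that("phi_record validates its tokens and builds a canonical string", {
  phi <- phi_record("r1", c("100", "Meadow", "Street"))
  expect_equal(canonical_address(phi), "100 Meadow Street")
  # canonical string round-trips to the token list under whitespace splitting
  expect_equal(strsplit(canonical_address(phi), " ")[[1]], phi$address_tokens)
  expect_error(phi_record("r1", character()), "non-empty")
  expect_error(phi_record("r1", c("100", "Meadow Street")), "whitespace")
  expect_error(phi_record("r1", c("100", "")), "non-empty")
})

test_that("document validates gold spans against its text", {
  d <- document("d1", "r1", "2016-12-01", "abc", gold_annotations())
  expect_s3_class(d, "deid_document")
  expect_equal(nrow(d$gold), 0L)

  g <- gold_annotations(start = 1L, end = 4L, token = "xyz", source_index = 0L)
  expect_error(document("d2", "r1", "2016-12-01", "abcdef", g),
               "d2.*disagrees")
  g2 <- gold_annotations(start = c(0L, 2L), end = c(3L, 5L),
                         token = c("abc", "cde"), source_index = 0:1)
  expect_error(document("d3", "r1", "2016-12-01", "abcdefg", g2),
               "non-overlapping")
  g3 <- gold_annotations(start = 2L, end = 9L, token = "x", source_index = 0L)
  expect_error(document("d4", "r1", "2016-12-01", "abc", g3), "bounds")
})

test_that("documents survive a JSONL round trip, offsets included", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  g <- gold_annotations(start = c(5L, 9L), end = c(8L, 15L),
                        token = c("100", "Meadow"), source_index = 0:1)
  docs <- list(
    document("d1", "r1", "2016-12-01", "call 100 Meadow now", g),
    document("d2", "r2", "2016-12-02", "nothing here")
  )
  write_documents(docs, tmp)
  back <- read_documents(tmp)
  expect_length(back, 2L)
  expect_equal(back[[1]]$gold, docs[[1]]$gold)
  expect_equal(back[[1]]$text, docs[[1]]$text)
  expect_equal(back[[2]]$date, as.Date("2016-12-02"))
})

test_that("malformed document files fail with located errors", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"d1","record_id":"r1","date":"2016-12-01","text":"abc","gold":[]}',
               "{not json"), tmp)
  expect_error(read_documents(tmp), "line 2")

  tmp2 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(paste0('{"doc_id":"dx","record_id":"r1","date":"2016-12-01",',
                    '"text":"abc","gold":[{"start":0,"end":2,"token":"zz",',
                    '"source_index":0}]}'), tmp2)
  expect_error(read_documents(tmp2), "dx")

  empty <- withr::local_tempfile(fileext = ".jsonl")
  file.create(empty)
  expect_equal(read_documents(empty), list())
})

test_that("PHI records read from CSV tokenize the address field", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,address",
               'r1,"100 Meadow Street"',
               'r2,"Institute of Psychiatry, 16 De Crespigne Park"'), tmp)
  recs <- read_phi_records(tmp)
  expect_equal(recs[[1]]$address_tokens, c("100", "Meadow", "Street"))
  # commas are stripped from token edges
  expect_equal(recs[[2]]$address_tokens,
               c("Institute", "of", "Psychiatry", "16", "De", "Crespigne",
                 "Park"))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,address", "r1,here", "r1,there"), dup)
  expect_error(read_phi_records(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,address", 'r9,","'), bad)
  expect_error(read_phi_records(bad), "empty address")
})

test_that("PHI records read from JSONL keep explicit token lists", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"record_id":"r2","address_tokens":["Institute","of","Psychiatry"]}',
             tmp)
  recs <- read_phi_records(tmp)
  expect_length(recs[[1]]$address_tokens, 3L)
})

test_that("eval_result derives precision and recall with undefined sentinels", {
  r <- eval_result(6969, 271, 1537)
  expect_equal(round(100 * r$precision, 1), 96.3)
  expect_equal(round(100 * r$recall, 1), 81.9)
  z <- eval_result(0, 0, 0)
  expect_true(is.na(z$precision) && is.na(z$recall))
  expect_error(eval_result(-1, 0, 0), "non-negative")
})

test_that("reports print one-decimal percentages and round-trip", {
  rep <- tibble::tibble(
    condition = c("a", "b"),
    tp = c(6969L, 0L), fp = c(271L, 0L), fn = c(1537L, 0L),
    precision = c(6969 / 7240, NA), recall = c(6969 / 8506, NA))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, tmp)
  raw <- readLines(tmp)
  expect_match(raw[2], "6969,271,1537,96.3,81.9")
  # undefined cells stay empty
  expect_match(raw[3], "0,0,0,,$")
  back <- read_report(tmp)
  expect_equal(back$condition, rep$condition)
  expect_equal(back$tp, rep$tp)
  expect_equal(back$precision, rep$precision)
  expect_equal(back$recall, rep$recall)
})
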