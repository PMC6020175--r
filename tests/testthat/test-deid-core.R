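test_that("edit distance matches worked examples", {
  expect_identical(edit_distance("Meadow", "Meagow"), 1L)
  expect_identical(edit_distance("Street", "Streat"), 1L)
  expect_identical(edit_distance("abc", "abc"), 0L)
  expect_identical(edit_distance("", "abcd"), 4L)
})

test_that("edit distance satisfies the metric axioms against an exhaustive oracle", {
  set.seed(99)
  for (rep in 1:120) {
    a <- random_string(sample(0:8, 1))
    b <- random_string(sample(0:8, 1))
    c <- random_string(sample(0:8, 1))
    dab <- edit_distance(a, b)
    expect_identical(dab, oracle_lev(a, b))
    expect_identical(dab, edit_distance(b, a))
    expect_identical(edit_distance(a, a), 0L)
    expect_gte(dab, abs(nchar(a) - nchar(b)))
    expect_lte(dab, max(nchar(a), nchar(b)))
    expect_lte(dab, edit_distance(a, c) + edit_distance(c, b))
  }
})

test_that("similarity is normalised, symmetric in role, and 1 iff equal", {
  expect_equal(lev_similarity("Meadow", "Meagow"), 5 / 6)
  expect_equal(lev_similarity("ab", "xy"), 0)
  expect_equal(lev_similarity("", ""), 1)
  set.seed(7)
  for (rep in 1:25) {
    x <- random_string(sample(1:8, 1))
    expect_equal(lev_similarity(x, x), 1)
  }
})

test_that("scan_token agrees with a brute-force window oracle", {
  set.seed(123)
  texts <- c("xx Meagow xx", "lorem ipsum dolor", "a bb ccc dddd",
             replicate(6, paste(replicate(4, random_string(sample(2:7, 1))),
                                collapse = " ")))
  tokens <- c("Meadow", "Barkingford", "ccc", "abca", "dcba", "badc")
  for (barrier in c(TRUE, FALSE)) {
    for (theta in c(0.6, 0.8)) {
      cfg <- deid_config(theta = theta, whitespace_barrier = barrier)
      for (text in texts) {
        for (token in tokens) {
          got <- scan_token(text, token, cfg)
          want <- oracle_scan(text, token, theta,
                              cfg$width_slack_fraction, barrier = barrier)
          got <- got[order(got$start, got$end), ]
          want <- want[order(want$start, want$end), ]
          expect_equal(nrow(got), nrow(want),
                       info = paste(text, token, theta, barrier))
          expect_equal(got$start, as.integer(want$start))
          expect_equal(got$end, as.integer(want$end))
          expect_equal(got$similarity, want$sim, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("scan_token finds mutated and verbatim tokens, not unrelated text", {
  hits <- scan_token("xx Meagow xx", "Meadow", deid_config(theta = 0.8))
  expect_true(any(hits$start == 3 & hits$end == 9 &
                    abs(hits$similarity - 5 / 6) < 1e-12))
  exact <- scan_token("say Meadow twice", "Meadow", deid_config(theta = 1))
  expect_true(any(exact$similarity == 1))
  expect_equal(nrow(scan_token("lorem ipsum", "Barkingford",
                               deid_config(theta = 0.8))), 0L)
})

test_that("deidentify masks address occurrences and preserves length", {
  phi <- phi_record("r1", c("100", "Meadow", "Street"))
  doc <- document("d1", "r1", "2016-12-01", "Call 100 Meadow Street now")
  m <- deidentify(doc, phi, deid_config(theta = 0.8))
  expect_equal(nchar(m$text), nchar(doc$text))
  # every address token of length >= min_token_length is fully masked
  for (tok in c("100", "Meadow", "Street")) {
    i <- regexpr(tok, doc$text, fixed = TRUE)[1]
    expect_true(all((i - 1):(i + nchar(tok) - 2) %in% m$masked_offsets),
                info = tok)
  }
  expect_false(grepl("Meadow", m$text, fixed = TRUE))
  # with min_token_length 4 the house number is no longer a query
  m4 <- deidentify(doc, phi, deid_config(theta = 0.8, min_token_length = 4))
  expect_true(grepl("100", m4$text, fixed = TRUE))
  # masked offsets hold the mask character
  chars <- strsplit(m$text, "")[[1]]
  expect_true(all(chars[m$masked_offsets + 1] == "X"))
})

test_that("deidentify rejects mismatched records and handles empty text", {
  phi <- phi_record("r1", c("100", "Meadow", "Street"))
  doc <- document("d1", "r2", "2016-12-01", "text")
  expect_error(deidentify(doc, phi), "linkage")
  empty <- document("d0", "r1", "2016-12-01", "")
  m <- deidentify(empty, phi)
  expect_equal(m$text, "")
  expect_equal(nrow(m$spans), 0L)
})

test_that("masking grows with extra PHI tokens and with lower thresholds", {
  set.seed(31)
  for (rep in 1:8) {
    words <- replicate(6, random_string(sample(3:7, 1)))
    text <- paste(words, collapse = " ")
    doc <- document("d", "r", "2016-12-01", text)
    base_tokens <- replicate(2, random_string(sample(3:6, 1)))
    extra <- random_string(sample(3:6, 1))
    phi1 <- phi_record("r", base_tokens)
    phi2 <- phi_record("r", c(base_tokens, extra))
    cfg <- deid_config(theta = 0.6)
    m1 <- deidentify(doc, phi1, cfg)
    m2 <- deidentify(doc, phi2, cfg)
    expect_true(all(m1$masked_offsets %in% m2$masked_offsets))
    lo <- deidentify(doc, phi1, deid_config(theta = 0.4))
    expect_true(all(m1$masked_offsets %in% lo$masked_offsets))
  }
})

test_that("other_phis tokens are masked alongside the address", {
  phi <- phi_record("r1", c("9", "Quarry", "Close"),
                    other_phis = list(last_name = "Pemberton"))
  doc <- document("d1", "r1", "2016-12-01", "Mr Pemberton of Quarry Close")
  m <- deidentify(doc, phi, deid_config(theta = 0.9))
  expect_false(grepl("Pemberton", m$text, fixed = TRUE))
})

test_that("version hash is a deterministic, date-sensitive SHA-256", {
  phi <- phi_record("r1", c("100", "Meadow", "Street"))
  h1 <- version_hash(phi, "2016-12-01")
  h2 <- version_hash(phi, "2016-12-01")
  h3 <- version_hash(phi, "2016-12-02")
  expect_identical(h1, h2)
  expect_false(identical(h1, h3))
  expect_match(h1, "^[0-9a-f]{64}$")
})
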