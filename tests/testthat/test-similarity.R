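test_that("Jaro-Winkler matches an independent implementation", {
  expect_equal(field_similarity("MARTHA", "MARHTA", "text"), 0.961, tolerance = 1e-3)
  expect_equal(field_similarity("MARTHA", "MARHTA", "text"),
               ref_jaro_winkler("MARTHA", "MARHTA"), tolerance = 1e-12)
  set.seed(13)
  chars <- LETTERS
  for (i in 1:300) {
    a <- paste(sample(chars, sample(1:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(chars, sample(1:12, 1), replace = TRUE), collapse = "")
    expect_equal(field_similarity(a, b, "text"), ref_jaro_winkler(a, b),
                 tolerance = 1e-12, info = paste(a, b))
  }
})

test_that("similarity is 1 on identical values and symmetric", {
  set.seed(14)
  for (i in 1:50) {
    a <- paste(sample(LETTERS, sample(2:10, 1), replace = TRUE), collapse = "")
    b <- paste(sample(LETTERS, sample(2:10, 1), replace = TRUE), collapse = "")
    expect_identical(field_similarity(a, a, "text"), 1)
    expect_equal(field_similarity(a, b, "text"), field_similarity(b, a, "text"))
  }
  expect_identical(field_similarity("1980-03-04", "1980-03-04", "date"), 1)
  expect_identical(field_similarity("F", "F", "enum"), 1)
})

test_that("date similarity follows the transposition and one-component rules", {
  expect_equal(field_similarity("1980-03-04", "1980-04-03", "date"), 0.8)
  expect_equal(field_similarity("1980-03-04", "1980-03-07", "date"), 0.8)
  expect_equal(field_similarity("1980-03-04", "1983-03-04", "date"), 0.8)
  expect_equal(field_similarity("1980-03-04", "1981-04-04", "date"), 0)
  expect_equal(field_similarity("1980-03-04", "1955-12-25", "date"), 0)
})

test_that("aggregate score is the weighted mean with missing-field redistribution", {
  expect_equal(aggregate_score(c(a = 1, b = 1), c(a = 1, b = 1)), 1)
  expect_equal(aggregate_score(c(a = 1, b = 0.5), c(a = 1, b = 1)), 0.75)
  expect_equal(aggregate_score(c(a = 0.9, b = NA), c(a = 1, b = 1)), 0.9)
  expect_error(aggregate_score(c(a = NA_real_), c(a = 1)),
               class = "pseudoreg_no_comparable_fields")
})

test_that("increasing any per-field score never decreases the aggregate", {
  set.seed(15)
  w <- c(a = 2, b = 1, c = 0.5)
  for (i in 1:100) {
    s <- stats::runif(3); names(s) <- names(w)
    f <- sample(names(w), 1)
    s2 <- s
    s2[f] <- min(1, s[f] + stats::runif(1, 0, 1 - s[f]))
    expect_gte(aggregate_score(s2, w), aggregate_score(s, w) - 1e-12)
  }
})

test_that("classification respects the block and review thresholds", {
  thr <- c(0.98, 0.85)
  expect_identical(classify_match(1.0, thr), "exact_block")
  expect_identical(classify_match(0.98, thr), "exact_block")
  expect_identical(classify_match(0.90, thr), "review")
  expect_identical(classify_match(0.85, thr), "review")
  expect_identical(classify_match(0.5, thr), "no_match")
  expect_identical(classify_match(c(0.99, 0.86, 0.1), thr),
                   c("exact_block", "review", "no_match"))
})
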