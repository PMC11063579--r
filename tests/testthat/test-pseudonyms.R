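test_that("generated pseudonyms conform to the rendered format", {
  fmt <- pseudonym_format("STU", "BER", body_length = 6L)
  set.seed(1)
  vals <- generate_pseudonym(fmt, character(0), n = 500L)
  expect_true(all(grepl("^STU-BER-[A-HJ-NP-Z2-9]{6}-[0-9A-Z*]$", vals)))
  expect_false(anyDuplicated(vals) > 0)
  for (v in vals[1:20]) expect_true(validate_pseudonym(v, fmt)$ok)
})

test_that("generation is deterministic for a fixed RNG state and existing set", {
  fmt <- default_config()$subject_format
  set.seed(123); a <- generate_pseudonym(fmt, character(0), n = 50L)
  set.seed(123); b <- generate_pseudonym(fmt, character(0), n = 50L)
  expect_identical(a, b)
  set.seed(123); c <- generate_pseudonym(fmt, a[1:10], n = 50L)
  expect_false(any(c %in% a[1:10]))
})

test_that("generation against a growing set never collides", {
  fmt <- default_config()$subject_format
  set.seed(99)
  existing <- character(0)
  for (i in 1:20) {
    new <- generate_pseudonym(fmt, existing, n = 500L)
    expect_false(any(new %in% existing))
    existing <- c(existing, new)
  }
  expect_identical(anyDuplicated(existing), 0L)
})

test_that("an exhausted identifier space raises a capacity error, not a loop", {
  fmt <- pseudonym_format("A", "B", body_length = 1L, alphabet = "AB",
                          check_scheme = "none")
  set.seed(5)
  both <- generate_pseudonym(fmt, character(0), n = 2L)
  expect_setequal(both, c("A-B-A", "A-B-B"))
  expect_error(generate_pseudonym(fmt, both, n = 1L),
               class = "pseudoreg_capacity_error")
  # near capacity the deterministic scan still finds the last free value
  expect_identical(generate_pseudonym(fmt, "A-B-A", n = 1L), "A-B-B")
})

test_that("validation separates structural defects from check-character mismatch", {
  fmt <- default_config()$subject_format
  set.seed(2)
  v <- generate_pseudonym(fmt, character(0))
  expect_true(validate_pseudonym(v, fmt)$ok)

  wrong_sep <- gsub("-", "_", v)
  res <- validate_pseudonym(wrong_sep, fmt)
  expect_false(res$ok)
  expect_false(res$check_mismatch)

  # altering one body character must surface as a check mismatch
  body_pos <- 9L   # inside the body segment "SUB-BER-XXXXXX-C"
  alt <- v
  cur <- substr(alt, body_pos, body_pos)
  repl <- setdiff(strsplit("ABCDEFGH", "")[[1]], cur)[1]
  substr(alt, body_pos, body_pos) <- repl
  res <- validate_pseudonym(alt, fmt)
  expect_false(res$ok)
  expect_true(res$check_mismatch)

  res <- validate_pseudonym("XXX-BER-ABCDEF-2", fmt)
  expect_false(res$ok)
  expect_match(res$defects[1], "prefix")
})
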