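test_that("text normalization strips diacritics, case and stray whitespace", {
  sch <- default_config()$identity_schema
  n <- normalize_identity(list(first_name = "  Anna  Lena ",
                               last_name = "  Müller ",
                               date_of_birth = "1980-3-4", sex = "f"), sch)
  expect_identical(n$first_name, "ANNA LENA")
  expect_identical(n$last_name, "MULLER")
  expect_identical(n$date_of_birth, "1980-03-04")
  expect_identical(n$sex, "F")
})

test_that("normalization is idempotent on generated identities", {
  sch <- default_config()$identity_schema
  ids <- random_identity_df(200, seed = 31)
  for (i in sample(nrow(ids), 50)) {
    once <- normalize_identity(as.list(ids[i, ]), sch)
    twice <- normalize_identity(unclass(once), sch)
    expect_identical(unclass(twice), unclass(once))
  }
})

test_that("impossible calendar dates are rejected", {
  sch <- default_config()$identity_schema
  expect_error(
    normalize_identity(demo_identity(dob = "1980-02-30"), sch),
    class = "pseudoreg_schema_error")
  expect_error(
    normalize_identity(demo_identity(dob = "1980-13-01"), sch),
    class = "pseudoreg_schema_error")
  err <- expect_error(
    normalize_identity(list(first_name = "A", date_of_birth = "x", sex = "F"), sch),
    class = "pseudoreg_schema_error")
  expect_match(conditionMessage(err), "last_name")
})

test_that("quality checks grade errors and warnings as documented", {
  sch <- default_config()$identity_schema
  today <- as.Date("2026-01-15")

  expect_identical(nrow(quality_check(demo_identity(), sch, today)), 0L)

  qc <- quality_check(demo_identity(dob = "2030-01-01"), sch, today)
  expect_true(any(qc$field == "date_of_birth" & qc$severity == "error"))

  qc <- quality_check(demo_identity(last = "X"), sch, today)
  expect_true(any(qc$field == "last_name" & qc$severity == "warning"))

  qc <- quality_check(demo_identity(first = "XXX"), sch, today)
  expect_true(any(qc$field == "first_name" & qc$severity == "warning" &
                    grepl("placeholder", qc$message)))

  qc <- quality_check(demo_identity(dob = "1900-01-01"), sch, today)
  expect_true(any(qc$field == "date_of_birth" & qc$severity == "warning"))

  qc <- quality_check(list(first_name = "", last_name = "Ok",
                           date_of_birth = "1980-01-01", sex = "F"), sch, today)
  expect_true(any(qc$field == "first_name" & qc$severity == "error"))

  # total function: nonsense input yields issues, not conditions
  expect_silent(quality_check(list(date_of_birth = "not-a-date"), sch, today))
})
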