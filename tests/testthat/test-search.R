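test_that("wildcard search honours * and ? on normalized values", {
  fix <- seeded_registry()
  reg <- fix$registry
  res <- search_subjects(reg, list(last_name = "SM*"), mode = "wildcard")
  expect_setequal(
    vapply(res$last_name, function(x) x, character(1), USE.NAMES = FALSE),
    c("Smith", "Smyth"))
  res <- search_subjects(reg, list(last_name = "SM?TH"), mode = "wildcard")
  expect_identical(nrow(res), 2L)
  res <- search_subjects(reg, list(last_name = "Müll*"), mode = "wildcard")
  expect_identical(res$last_name, "Müller")   # diacritics normalized before matching
  res <- search_subjects(reg, list(last_name = "Q*"), mode = "wildcard")
  expect_identical(nrow(res), 0L)
})

test_that("a fuzzy query equal to a registered identity ranks it first with score 1", {
  fix <- seeded_registry()
  res <- search_subjects(fix$registry, demo_identity(), mode = "fuzzy")
  expect_gte(nrow(res), 1L)
  expect_identical(res$subject_pseudonym[1], fix$records[[1]]$pseudonym)
  expect_equal(res$score[1], 1)
  expect_identical(res$classification[1], "exact_block")
})

test_that("empty queries are refused", {
  fix <- seeded_registry()
  expect_error(search_subjects(fix$registry, list()),
               class = "pseudoreg_empty_query")
  expect_error(search_subjects(fix$registry, list(last_name = "  ")),
               class = "pseudoreg_empty_query")
  expect_error(search_subjects(fix$registry, list(last_name = "SM*"), mode = "fuzzy"),
               class = "pseudoreg_empty_query")
})

test_that("results are ranked by score, ties broken by pseudonym", {
  fix <- seeded_registry()
  res <- search_subjects(fix$registry, list(last_name = "*"), mode = "combined")
  expect_identical(nrow(res), 4L)
  expect_true(all(diff(res$score) <= 0))
  ties <- split(res$subject_pseudonym, res$score)
  for (grp in ties) expect_identical(grp, sort(grp))
})

test_that("blocked search equals the brute-force oracle on a small registry", {
  cfg <- default_config()
  reg <- registry_create(cfg)
  ids <- generate_cohort(300, duplicate_rate = 0.08, max_typos = 2,
                         seed = 17)$identities
  bulk_import_subjects(reg, ids, mode = "register_new", actor = "t")

  set.seed(18)
  pool <- generate_cohort(300, duplicate_rate = 0, max_typos = 2, seed = 19)$identities
  for (q in 1:60) {
    if (q %% 3 == 0) {
      src <- as.list(pool[sample(nrow(pool), 1), ])     # unrelated identity
    } else {
      src <- as.list(ids[sample(nrow(ids), 1), ])       # near-registered identity
      f <- sample(c("first_name", "last_name"), 1)
      src[[f]] <- pseudoreg:::apply_text_edit(src[[f]], "substitution")$value
    }
    mode <- sample(c("fuzzy", "combined", "wildcard"), 1)
    if (mode == "wildcard") {
      src <- list(last_name = paste0(substr(src$last_name, 1, 2), "*"))
    }
    got <- sort(search_subjects(reg, src, mode = mode)$subject_pseudonym)
    want <- oracle_search(reg, src, mode, cfg)
    expect_identical(got, want, info = paste("mode", mode, "query", q))
  }
})
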