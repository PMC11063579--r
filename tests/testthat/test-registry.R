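test_that("registration demands a fresh search for the same identity", {
  reg <- registry_create(default_config())
  id <- demo_identity()
  expect_error(register_subject(reg, id, NULL), class = "pseudoreg_missing_search")

  other_proof <- search_subjects(reg, demo_identity(first = "Zoe"))
  expect_error(register_subject(reg, id, other_proof),
               class = "pseudoreg_missing_search")

  proof <- search_subjects(reg, id)
  register_subject(reg, demo_identity(first = "Else", last = "Other",
                                      dob = "1970-01-02"),
                   search_subjects(reg, demo_identity(first = "Else",
                                                      last = "Other",
                                                      dob = "1970-01-02")),
                   actor = "n1")
  # registry changed since `proof` was taken
  expect_error(register_subject(reg, id, proof), class = "pseudoreg_stale_search")
})

test_that("identical identities are always blocked; review needs an explicit override", {
  reg <- registry_create(default_config())
  id <- demo_identity()
  rec <- register_subject(reg, id, search_subjects(reg, id), actor = "n1")
  expect_match(rec$pseudonym, "^SUB-BER-")

  err <- expect_error(
    register_subject(reg, id, search_subjects(reg, id), actor = "n1"),
    class = "pseudoreg_duplicate_blocked")
  expect_match(conditionMessage(err), rec$pseudonym, fixed = TRUE)

  near <- demo_identity(last = "Mueler", dob = "1980-04-03")
  proof <- search_subjects(reg, near)
  expect_identical(proof$classification[1], "review")
  expect_error(register_subject(reg, near, proof),
               class = "pseudoreg_review_required")
  proof <- search_subjects(reg, near)
  rec2 <- register_subject(reg, near, proof, override_review = TRUE, actor = "n2")
  log <- audit_log(reg)
  note <- log$note[log$action == "register_subject" & log$target == rec2$pseudonym]
  expect_match(note, "override_review")
})

test_that("identities failing quality checks cannot be registered", {
  reg <- registry_create(default_config())
  bad <- demo_identity(dob = "2099-01-01")
  expect_error(register_subject(reg, bad, search_subjects(reg, bad)),
               class = "pseudoreg_quality_error")
})

test_that("biosample registration issues one pseudonym per aliquot", {
  fix <- seeded_registry()
  reg <- fix$registry
  subj <- fix$records[[1]]$pseudonym
  recs <- register_biosamples(reg, subj, "BL", "SER", n_aliquots = 3, actor = "lab")
  psns <- vapply(recs, `[[`, character(1), "pseudonym")
  expect_identical(length(unique(psns)), 3L)
  expect_identical(vapply(recs, `[[`, integer(1), "aliquot_index"), 1:3)
  for (p in psns) {
    expect_identical(depseudonymize(reg, p, "t")$subject_pseudonym, subj)
  }
})

test_that("unknown subjects and schedule violations are refused with detail", {
  fix <- seeded_registry()
  reg <- fix$registry
  expect_error(register_biosamples(reg, "SUB-BER-XXXXXX-1", "BL", "SER"),
               class = "pseudoreg_unknown_subject")
  subj <- fix$records[[1]]$pseudonym
  err <- expect_error(register_biosamples(reg, subj, "FU2", "PBMC"),
                      class = "pseudoreg_schedule_violation")
  expect_match(conditionMessage(err), "SER")   # lists the allowed types
  expect_error(register_biosamples(reg, subj, "NOPE", "SER"),
               class = "pseudoreg_schedule_violation")
})

test_that("depseudonymization resolves records and distinguishes transcription errors", {
  fix <- seeded_registry()
  reg <- fix$registry
  subj <- fix$records[[1]]$pseudonym
  rec <- depseudonymize(reg, subj, actor = "pi")
  expect_identical(rec$identity$last_name, "Müller")

  # one altered body character: check fails -> suspected transcription error
  alt <- subj
  pos <- 9L
  cur <- substr(alt, pos, pos)
  substr(alt, pos, pos) <- setdiff(c("A", "B", "C"), cur)[1]
  expect_error(depseudonymize(reg, alt, actor = "pi"),
               class = "pseudoreg_transcription_suspected")

  # structurally broken value: plain not-found
  expect_error(depseudonymize(reg, "WHO-AMI-1", actor = "pi"),
               class = "pseudoreg_not_found")
})

test_that("every depseudonymization appends exactly one audit entry", {
  fix <- seeded_registry()
  reg <- fix$registry
  subj <- fix$records[[2]]$pseudonym
  n0 <- nrow(audit_log(reg))
  depseudonymize(reg, subj, actor = "pi")
  try(depseudonymize(reg, "WHO-AMI-1", actor = "pi"), silent = TRUE)
  log <- audit_log(reg)
  expect_identical(nrow(log), n0 + 2L)
  expect_identical(tail(log$action, 2), c("depseudonymize", "depseudonymize"))
})

test_that("statistics are exactly consistent with the record collections", {
  cfg <- default_config()
  reg <- registry_create(cfg)
  st <- registry_statistics(reg)
  expect_identical(st$subjects_total, 0L)
  expect_identical(st$biosamples_total, 0L)
  expect_true(all(st$per_visit == 0L))

  ids <- list(demo_identity(), demo_identity("Bob", "Stone", "1955-05-05", "M"))
  recs <- lapply(ids, function(id) {
    register_subject(reg, id, search_subjects(reg, id), actor = "n")
  })
  register_biosamples(reg, recs[[1]]$pseudonym, "BL", "SER", n_aliquots = 3)
  st <- registry_statistics(reg)
  expect_identical(st$subjects_total, 2L)
  expect_identical(st$biosamples_total, 3L)
  expect_identical(unname(st$per_visit[["BL"]]), 3L)
  expect_identical(unname(st$per_sample_type[["SER"]]), 3L)
  expect_true(all(diff(st$subjects_monthly$cumulative) >= 0))
})

test_that("backup reminders follow the configured interval", {
  reg <- registry_create(default_config())
  expect_true(backup_due(reg)$due)
  reg$last_backup_at <- format(Sys.time() - 2 * 86400, "%Y-%m-%dT%H:%M:%S+0000",
                               tz = "UTC")
  expect_true(backup_due(reg)$due)
  reg$last_backup_at <- format(Sys.time() - 3600, "%Y-%m-%dT%H:%M:%S+0000",
                               tz = "UTC")
  expect_false(backup_due(reg)$due)
})

test_that("referential integrity holds after random operation sequences", {
  set.seed(77)
  cfg <- default_config()
  reg <- registry_create(cfg)
  subjects <- character(0)
  pool <- random_identity_df(60, seed = 78)
  k <- 0L
  for (step in 1:120) {
    op <- sample(c("subject", "biosample", "lookup"), 1,
                 prob = c(0.4, 0.4, 0.2))
    if (op == "subject" && k < nrow(pool)) {
      k <- k + 1L
      id <- as.list(pool[k, ])
      res <- try(register_subject(reg, id, search_subjects(reg, id), actor = "p"),
                 silent = TRUE)
      if (!inherits(res, "try-error")) subjects <- c(subjects, res$pseudonym)
    } else if (op == "biosample" && length(subjects)) {
      register_biosamples(reg, sample(subjects, 1), "BL", "PLA",
                          n_aliquots = sample(1:3, 1), actor = "p")
    } else if (op == "lookup" && length(subjects)) {
      depseudonymize(reg, sample(subjects, 1), actor = "p")
    }
  }
  b <- reg$state$bios
  for (i in seq_len(b$n)) {
    expect_false(is.na(pseudoreg:::subject_lookup(reg, b$tab$subject_psn[i])))
  }
  s <- reg$state$subj
  expect_identical(anyDuplicated(c(s$tab$psn[seq_len(s$n)], b$tab$psn[seq_len(b$n)])), 0L)
  # audit completeness: one entry per mutating/depseudonymizing operation
  log <- audit_log(reg)
  expect_identical(sum(log$action == "register_subject"), length(subjects))
  expect_identical(sum(log$action == "register_biosample"), b$n)
})

test_that("candidate comparisons grow at most linearly with registry size", {
  cfg <- default_config()
  sizes <- c(1000L, 4000L, 16000L)
  per_reg <- numeric(length(sizes))
  ids_all <- generate_cohort(max(sizes) + 50, duplicate_rate = 0,
                             max_typos = 2, seed = 55)$identities
  reg <- registry_create(cfg)
  done <- 0L
  probe <- as.list(ids_all[max(sizes) + 1L, ])
  for (si in seq_along(sizes)) {
    bulk_import_subjects(reg, ids_all[(done + 1L):sizes[si], ],
                         mode = "register_new", actor = "t")
    done <- sizes[si]
    reset_comparison_count(reg)
    search_subjects(reg, probe, mode = "fuzzy")
    per_reg[si] <- comparison_count(reg)
  }
  # per-search candidate count must scale no worse than the registry size
  ratio <- (per_reg[3] / max(per_reg[1], 1)) / (sizes[3] / sizes[1])
  expect_lte(ratio, 1.5)
  expect_lte(per_reg[3], sizes[3])
})
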