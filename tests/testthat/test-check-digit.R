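test_that("check characters round-trip and match the polynomial definition", {
  set.seed(42)
  chars <- strsplit("0123456789ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1]]
  bodies <- vapply(1:200, function(i) {
    paste(sample(chars, sample(3:12, 1), replace = TRUE), collapse = "")
  }, character(1))
  chk <- compute_check_character(bodies)
  expect_true(all(verify_check_character(paste0(bodies, chk))))
  for (b in bodies[1:40]) {
    expect_identical(compute_check_character(b), ref_iso_check(b))
  }
})

test_that("every single-character substitution changes the required check character", {
  set.seed(7)
  chars <- strsplit("0123456789ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1]]
  for (rep in 1:50) {
    body <- paste(sample(chars, 8, replace = TRUE), collapse = "")
    full <- paste0(body, compute_check_character(body))
    for (pos in 1:nchar(full)) {
      orig <- substr(full, pos, pos)
      for (repl in sample(setdiff(chars, orig), 5)) {
        mutated <- full
        substr(mutated, pos, pos) <- repl
        expect_false(verify_check_character(mutated))
      }
    }
  }
})

test_that("adjacent transpositions that change the string are always rejected", {
  set.seed(8)
  chars <- strsplit("0123456789ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1]]
  n_checked <- 0L
  for (rep in 1:100) {
    body <- paste(sample(chars, 8, replace = TRUE), collapse = "")
    full <- strsplit(paste0(body, compute_check_character(body)), "")[[1]]
    for (i in seq_len(length(full) - 1L)) {
      if (full[i] == full[i + 1L]) next
      sw <- full
      sw[c(i, i + 1L)] <- sw[c(i + 1L, i)]
      expect_false(verify_check_character(paste(sw, collapse = "")))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 500L)
})

test_that("characters outside the scheme alphabet are rejected", {
  expect_error(compute_check_character("AB-C"), class = "pseudoreg_alphabet_error")
  expect_error(compute_check_character("ABC*"), class = "pseudoreg_alphabet_error")
  expect_error(compute_check_character(""), class = "pseudoreg_alphabet_error")
  # '*' is legal only as the check character itself
  expect_true(verify_check_character(paste0("A", compute_check_character("A"))))
})
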