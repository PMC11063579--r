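sample_payloads <- function(n = 5L) {
  lapply(seq_len(n), function(i) {
    pseudoreg:::label_payload(sprintf("SMP-BER-AAA%03d-1", i),
                              sprintf("SUB-BER-BBB%03d-2", i),
                              "Baseline", "Serum")
  })
}

test_that("label payloads resolve visit and type display labels deterministically", {
  fix <- seeded_registry()
  rec <- register_biosamples(fix$registry, fix$records[[1]]$pseudonym,
                             "BL", "SER", actor = "lab")[[1]]
  p1 <- build_label_payload(rec, fix$config)
  p2 <- build_label_payload(rec, fix$config)
  expect_identical(p1, p2)
  expect_identical(p1$visit_label, "Baseline")
  expect_identical(p1$sample_type_label, "Serum")
  expect_identical(p1$biosample_id, rec$pseudonym)
  expect_identical(p1$subject_id, rec$subject_pseudonym)

  broken <- rec; broken$visit_id <- "NOPE"
  expect_error(build_label_payload(broken, fix$config),
               class = "pseudoreg_schedule_violation")
})

test_that("encode/decode round-trips the biosample id for all three symbologies", {
  set.seed(21)
  fmt <- default_config()$biosample_format
  ids <- generate_pseudonym(fmt, character(0), n = 25L)
  for (sym in c("datamatrix", "qr", "code128")) {
    for (id in ids) {
      s <- encode_code(id, sym)
      expect_identical(s$text, id)
      expect_identical(decode_code(s), id, info = paste(sym, id))
    }
  }
})

test_that("symbol payload lengths up to the documented capacity round-trip", {
  set.seed(22)
  for (len in c(1L, 5L, 16L, 30L, 40L)) {
    txt <- paste(sample(c(LETTERS, 0:9, "-"), len, replace = TRUE), collapse = "")
    for (sym in c("datamatrix", "qr", "code128")) {
      expect_identical(decode_code(encode_code(txt, sym)), txt,
                       info = paste(sym, len))
    }
  }
})

test_that("unsupported or empty payloads are refused", {
  expect_error(encode_code("", "qr"), class = "pseudoreg_symbology_error")
  expect_error(encode_code("café", "datamatrix"),
               class = "pseudoreg_symbology_error")
  expect_error(encode_code(strrep("X", 60), "datamatrix"),
               class = "pseudoreg_symbology_error")
})

test_that("corrupting a module breaks the Reed-Solomon syndromes", {
  s <- encode_code("SMP-BER-K7M2QX-4", "qr")
  m <- s$matrix
  m[15, 15] <- !m[15, 15]
  s$matrix <- m
  expect_error(decode_code(s), class = "pseudoreg_symbology_error")

  d <- encode_code("SMP-BER-K7M2QX-4", "datamatrix")
  dm <- d$matrix
  dm[5, 5] <- !dm[5, 5]
  d$matrix <- dm
  expect_error(decode_code(d), class = "pseudoreg_symbology_error")
})

test_that("the QR format word for level M mask 0 matches the published constant", {
  expect_identical(paste(pseudoreg:::qr_format_bits("M", 0L), collapse = ""),
                   "101010000010010")
})

test_that("Code 128 checksum matches hand arithmetic", {
  # value(ch) = ascii - 32; checksum = (104 + sum i * value_i) mod 103
  enc <- pseudoreg:::code128_encode("AB-1")
  vals <- utf8ToInt("AB-1") - 32L
  expect_identical(enc$symbols,
                   c(104L, vals, (104L + sum(vals * seq_along(vals))) %% 103L, 106L))
})

test_that("DataMatrix placement covers every data cell exactly once", {
  for (size in pseudoreg:::DM_SIZES$size) {
    reg_dim <- size - 2L
    pl <- pseudoreg:::dm_placement(reg_dim, reg_dim)
    total_cw <- sum(pseudoreg:::DM_SIZES[pseudoreg:::DM_SIZES$size == size,
                                         c("data_cw", "ecc_cw")])
    filled <- pl$pos > 0L
    expect_lte(sum(!filled), 4L)                       # fixed corner only
    counts <- table(pl$pos[filled])
    expect_true(all(counts == 8L))                     # 8 bits per codeword
    expect_identical(length(counts), as.integer(total_cw))
  }
})

test_that("sheets are laid out row-major with trailing blanks on the last page", {
  pls <- sample_payloads(5L)
  pages <- layout_sheet(pls, rows = 2L, columns = 2L)
  expect_identical(length(pages), 2L)
  expect_identical(sum(!vapply(pages[[2]], is.null, logical(1))), 1L)
  got <- unlist(lapply(pages, function(p) {
    vapply(p, function(c) if (is.null(c)) NA_character_ else c$biosample_id,
           character(1))
  }))
  expect_identical(got[!is.na(got)],
                   vapply(pls, `[[`, character(1), "biosample_id"))

  one <- layout_sheet(pls[1], rows = 2L, columns = 2L, repeat_count = 4L)
  expect_identical(length(one), 1L)
  expect_true(all(vapply(one[[1]], function(c) identical(c, pls[[1]]), logical(1))))

  # conservation: non-blank cells equal the sum of repeat counts
  pages <- layout_sheet(pls, rows = 3L, columns = 3L, repeat_count = 2L)
  n_filled <- sum(unlist(lapply(pages, function(p) !vapply(p, is.null, logical(1)))))
  expect_identical(n_filled, 10L)
})

test_that("rendered sheets are self-contained and reproducible", {
  pls <- sample_payloads(3L)
  pages <- layout_sheet(pls, rows = 2L, columns = 2L)
  html <- render_sheet_html(pages, symbology = "qr")
  # the only URL allowed is the SVG namespace declaration
  stripped <- gsub('xmlns="[^"]*"', "", html)
  expect_false(grepl("http://|https://|src=|href=", stripped))
  for (p in pls) expect_true(grepl(p$biosample_id, html, fixed = TRUE))
  expect_identical(render_sheet_html(pages, symbology = "qr"), html)
  f <- withr::local_tempfile(fileext = ".html")
  render_sheet_html(pages, symbology = "datamatrix", file = f)
  expect_true(file.exists(f))
})

test_that("bulk input parsing keeps good lines and reports bad ones by number", {
  txt <- paste(
    "SMP-1,SUB-1,Baseline,Serum",
    "SMP-2\tSUB-2\tBaseline\tPlasma",
    "broken,line",
    "",
    "SMP-3,SUB-3,Follow-up 1,Serum",
    sep = "\n")
  res <- parse_bulk_input(txt)
  expect_identical(length(res$payloads), 3L)
  expect_identical(res$payloads[[2]]$sample_type_label, "Plasma")
  expect_identical(res$errors$line, 3L)
  expect_identical(parse_bulk_input("")$payloads, list())
})
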