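#' Biosample labels
#'
#' Each vial label carries the biosample pseudonym, the owning subject
#' pseudonym, the visit and the sample type in human-readable form, plus a
#' machine-readable code whose content is exactly the biosample pseudonym.
#' Sheets are laid out row-major on a configurable rows x columns grid and
#' rendered as a single self-contained HTML document (all styling and code
#' graphics inlined as SVG, no external resources), so labels can be
#' printed from any browser on a machine without internet access.
#'
#' @name labels
NULL

#' Build the printable payload for one biosample
#'
#' @param sample a `biosample_record` (from [register_biosamples()] or
#'   [depseudonymize()]), or a list with fields `pseudonym`,
#'   `subject_pseudonym`, `visit_id`, `sample_type`.
#' @param config the [study_config()] used to resolve visit and sample-type
#'   display labels.
#' @return a `label_payload`: list with `biosample_id`, `subject_id`,
#'   `visit_label`, `sample_type_label`.
#' @export
build_label_payload <- function(sample, config) {
  v <- visit_definition(config, sample$visit_id)
  if (is.null(v)) {
    psn_stop("pseudoreg_schedule_violation",
             paste0("visit '", sample$visit_id, "' is not in the study schedule"))
  }
  tl <- sample_type_label(config, sample$sample_type)
  if (is.null(tl)) {
    psn_stop("pseudoreg_schedule_violation",
             paste0("sample type '", sample$sample_type, "' is not configured"))
  }
  structure(list(biosample_id = sample$pseudonym,
                 subject_id = sample$subject_pseudonym,
                 visit_label = v$label, sample_type_label = tl),
            class = "label_payload")
}

label_payload <- function(biosample_id, subject_id, visit_label,
                          sample_type_label) {
  structure(list(biosample_id = biosample_id, subject_id = subject_id,
                 visit_label = visit_label,
                 sample_type_label = sample_type_label),
            class = "label_payload")
}

#' Encode a label payload as a machine-readable symbol
#'
#' The encoded content is exactly the biosample pseudonym, for all three
#' symbologies. [decode_code()] is the matching reference decoder used in
#' round-trip verification.
#'
#' @param payload a `label_payload`, or a plain string to encode.
#' @param symbology `"datamatrix"` (default), `"qr"` or `"code128"`.
#' @return a `pseudoreg_symbol`: the symbology, the encoded text, and the
#'   module matrix (2-D codes) or bar widths (Code 128).
#' @export
encode_code <- function(payload, symbology = c("datamatrix", "qr", "code128")) {
  symbology <- match.arg(symbology)
  text <- if (inherits(payload, "label_payload")) payload$biosample_id else payload
  if (!is_string(text) || !nzchar(text)) {
    psn_stop("pseudoreg_symbology_error", "cannot encode an empty biosample id")
  }
  body <- switch(symbology,
    datamatrix = list(matrix = dm_encode(text)),
    qr = list(matrix = qr_encode(text)),
    code128 = list(widths = code128_encode(text)$widths))
  structure(c(list(symbology = symbology, text = text), body),
            class = "pseudoreg_symbol")
}

#' @rdname encode_code
#' @param symbol a `pseudoreg_symbol`.
#' @export
decode_code <- function(symbol) {
  stopifnot(inherits(symbol, "pseudoreg_symbol"))
  switch(symbol$symbology,
    datamatrix = dm_decode(symbol$matrix),
    qr = qr_decode(symbol$matrix),
    code128 = code128_decode(symbol$widths))
}

#' @export
print.pseudoreg_symbol <- function(x, ...) {
  dim <- if (!is.null(x$matrix)) paste0(nrow(x$matrix), "x", ncol(x$matrix), " modules")
         else paste0(length(x$widths), " bar/space widths")
  cat(sprintf("<%s symbol: '%s', %s>\n", x$symbology, x$text, dim))
  invisible(x)
}

#' Lay out label payloads on printable sheet pages
#'
#' Payloads are placed row-major; `repeat_count` prints adjacent duplicates
#' of each payload (multiple aliquot vials of the same draw). The final
#' page is padded with blank cells.
#'
#' @param payloads list of `label_payload` objects.
#' @param rows,columns grid dimensions per page.
#' @param repeat_count copies of each payload.
#' @return list of pages; each page is a list of length `rows * columns`
#'   whose elements are `label_payload`s or `NULL` (blank cell).
#' @export
layout_sheet <- function(payloads, rows = 8L, columns = 3L, repeat_count = 1L) {
  if (!length(payloads)) {
    psn_stop("pseudoreg_symbology_error", "no label payloads to lay out")
  }
  stopifnot(is_count(rows), is_count(columns), is_count(repeat_count))
  cells <- rep(payloads, each = repeat_count)
  per_page <- rows * columns
  n_pages <- ceiling(length(cells) / per_page)
  lapply(seq_len(n_pages), function(p) {
    idx <- ((p - 1L) * per_page + 1L):(p * per_page)
    page <- lapply(idx, function(i) if (i <= length(cells)) cells[[i]] else NULL)
    attr(page, "rows") <- as.integer(rows)
    attr(page, "columns") <- as.integer(columns)
    page
  })
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Inline SVG for a module matrix (QR / DataMatrix), 2-unit quiet zone.
svg_matrix <- function(m, px = 3L) {
  n <- nrow(m); q <- 2L
  side <- (n + 2L * q) * px
  cells <- which(m, arr.ind = TRUE)
  rects <- sprintf('<rect x="%d" y="%d" width="%d" height="%d"/>',
                   (cells[, 2] - 1L + q) * px, (cells[, 1] - 1L + q) * px, px, px)
  paste0('<svg xmlns="http://www.w3.org/2000/svg" width="', side,
         '" height="', side, '" shape-rendering="crispEdges">',
         '<rect width="100%" height="100%" fill="#fff"/>',
         '<g fill="#000">', paste(rects, collapse = ""), '</g></svg>')
}

# Inline SVG for Code 128 bar widths (10-module quiet zones).
svg_bars <- function(widths, px = 2L, height = 40L) {
  total <- (sum(widths) + 20L) * px
  x <- 10L * px
  parts <- character(0)
  for (i in seq_along(widths)) {
    w <- widths[i] * px
    if (i %% 2L == 1L) {                 # odd runs are bars
      parts <- c(parts, sprintf('<rect x="%d" y="0" width="%d" height="%d"/>',
                                x, w, height))
    }
    x <- x + w
  }
  paste0('<svg xmlns="http://www.w3.org/2000/svg" width="', total,
         '" height="', height, '" shape-rendering="crispEdges">',
         '<rect width="100%" height="100%" fill="#fff"/>',
         '<g fill="#000">', paste(parts, collapse = ""), '</g></svg>')
}

#' Render label pages as a self-contained printable HTML document
#'
#' The document inlines all styling and symbol graphics; it references no
#' external resource, so it can be opened and printed on an offline
#' machine and no label data ever leave the device.
#'
#' @param pages result of [layout_sheet()].
#' @param symbology machine-readable code to draw on each label.
#' @param file optional output path; when given, the document is written
#'   there.
#' @return the HTML document as a single string (invisibly when `file` is
#'   given).
#' @export
render_sheet_html <- function(pages, symbology = c("datamatrix", "qr", "code128"),
                              file = NULL) {
  symbology <- match.arg(symbology)
  cell_html <- function(pl) {
    if (is.null(pl)) return('<td class="cell blank"></td>')
    sym <- encode_code(pl, symbology)
    svg <- if (symbology == "code128") svg_bars(sym$widths) else svg_matrix(sym$matrix)
    paste0('<td class="cell">', svg,
           '<div class="sid">', html_escape(pl$biosample_id), '</div>',
           '<div class="meta">', html_escape(pl$subject_id), '</div>',
           '<div class="meta">', html_escape(pl$visit_label), ' &middot; ',
           html_escape(pl$sample_type_label), '</div></td>')
  }
  page_html <- vapply(pages, function(page) {
    per_row <- attr(page, "columns")
    # infer columns from page length assuming layout_sheet() row-major fill
    ncol_ <- per_row %||% guess_columns(length(page))
    rows <- split(page, ceiling(seq_along(page) / ncol_))
    body <- vapply(rows, function(r) {
      paste0("<tr>", paste(vapply(r, cell_html, character(1)), collapse = ""),
             "</tr>")
    }, character(1))
    paste0('<table class="sheet">', paste(body, collapse = ""), "</table>")
  }, character(1))
  doc <- paste0(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\"/>",
    "<title>Biosample labels</title><style>",
    "body{font-family:monospace;margin:0}",
    "table.sheet{border-collapse:collapse;page-break-after:always;margin:8mm}",
    "td.cell{border:1px dashed #999;padding:4px 8px;text-align:center;",
    "vertical-align:top;width:52mm;height:30mm}",
    ".sid{font-weight:bold;font-size:11px}.meta{font-size:9px}",
    "</style></head><body>",
    paste(page_html, collapse = ""),
    "</body></html>")
  if (!is.null(file)) {
    writeLines(doc, file, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

guess_columns <- function(n) {
  for (c in c(3L, 4L, 2L, 5L, 1L)) if (n %% c == 0L) return(c)
  1L
}

#' Parse pasted bulk label input
#'
#' One label per line, fields separated by tabs or commas:
#' `biosample_id, subject_id, visit_label, sample_type_label`. Malformed
#' lines are collected with their line numbers; well-formed lines are kept.
#'
#' @param text multi-line input as pasted into the bulk field.
#' @return list with `payloads` (list of `label_payload`) and `errors`
#'   (data frame `line`, `message`).
#' @export
parse_bulk_input <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  payloads <- list()
  errors <- data.frame(line = integer(0), message = character(0),
                       stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    sep <- if (grepl("\t", ln, fixed = TRUE)) "\t" else ","
    parts <- trimws(strsplit(ln, sep, fixed = TRUE)[[1]])
    if (length(parts) != 4L || any(!nzchar(parts))) {
      errors <- rbind(errors, data.frame(
        line = i,
        message = paste0("expected 4 non-empty fields, found ", length(parts)),
        stringsAsFactors = FALSE))
      next
    }
    payloads[[length(payloads) + 1L]] <-
      label_payload(parts[1], parts[2], parts[3], parts[4])
  }
  list(payloads = payloads, errors = errors)
}
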