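#' Identity normalization and data-quality checks
#'
#' Raw identity records as typed in at the bedside are noisy: mixed case,
#' stray whitespace, diacritics that differ between keyboards, local date
#' conventions. All record linkage operates on a canonical form instead:
#' text is transliterated to ASCII, upper-cased and whitespace-collapsed;
#' dates are strict ISO 8601; enum codes are upper-cased and checked against
#' the schema. Normalization is idempotent.
#'
#' @name normalization
NULL

normalize_text <- function(x) {
  x <- stringi::stri_trans_general(as.character(x), "Latin-ASCII")
  x <- toupper(x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Strict ISO date parsing; returns "YYYY-MM-DD" or NA for anything that is
# not a real calendar date.
normalize_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  ok <- grepl("^\\d{4}-\\d{1,2}-\\d{1,2}$", x)
  if (any(ok)) {
    parts <- matrix(as.integer(unlist(strsplit(x[ok], "-"))), ncol = 3, byrow = TRUE)
    cand <- sprintf("%04d-%02d-%02d", parts[, 1], parts[, 2], parts[, 3])
    real <- !is.na(as.Date(cand, format = "%Y-%m-%d", optional = TRUE))
    out[ok][real] <- cand[real]
  }
  out
}

# Canonical dates are fixed-width "YYYY-MM-DD", so components come from
# substr, which stays cheap inside the per-candidate linkage scan.
date_components <- function(x) {
  cbind(y = as.integer(substr(x, 1L, 4L)),
        m = as.integer(substr(x, 6L, 7L)),
        d = as.integer(substr(x, 9L, 10L)))
}

#' Normalize an identity record against a schema
#'
#' @param raw named list (or one-row data frame) of raw field values.
#' @param schema an [identity_field_schema()].
#' @return named list of canonical values (class `normalized_identity`);
#'   fields absent from `raw` and not required are returned as `NA`.
#' @examples
#' sch <- default_config()$identity_schema
#' normalize_identity(list(first_name = "  Anna", last_name = " Müller ",
#'                         date_of_birth = "1980-3-4", sex = "f"), sch)
#' @export
normalize_identity <- function(raw, schema) {
  raw <- as.list(raw)
  problems <- character(0)
  out <- list()
  for (f in schema$fields) {
    v <- raw[[f$name]]
    blank <- is.null(v) || length(v) == 0L || is.na(v) || !nzchar(trimws(as.character(v)))
    if (blank) {
      if (f$required) problems <- c(problems, paste0("required field '", f$name, "' is missing or blank"))
      out[[f$name]] <- NA_character_
      next
    }
    v <- as.character(v)
    if (f$kind == "text") {
      out[[f$name]] <- normalize_text(v)
    } else if (f$kind == "date") {
      d <- normalize_date(v)
      if (is.na(d)) {
        problems <- c(problems, paste0("field '", f$name, "': '", v,
                                       "' is not a valid ISO 8601 calendar date"))
        out[[f$name]] <- NA_character_
      } else {
        out[[f$name]] <- d
      }
    } else if (f$kind == "enum") {
      code <- toupper(trimws(v))
      canon <- toupper(trimws(f$enum_values))
      hit <- match(code, canon)
      if (is.na(hit)) {
        problems <- c(problems, paste0("field '", f$name, "': '", v,
                                       "' is not one of ",
                                       paste(f$enum_values, collapse = ", ")))
        out[[f$name]] <- NA_character_
      } else {
        out[[f$name]] <- f$enum_values[hit]
      }
    }
  }
  if (length(problems)) {
    psn_stop("pseudoreg_schema_error",
             paste0("identity does not satisfy the schema:\n",
                    paste0("  - ", problems, collapse = "\n")),
             problems = problems)
  }
  structure(out, class = "normalized_identity")
}

PLACEHOLDER_VALUES <- c("XXX", "XX", "NA", "N/A", "NONE", "UNKNOWN", "TEST",
                        "???", "?", "-", "--", "ANONYMOUS", "NN", "TBD")

#' Data-quality checks on an identity record
#'
#' Total function (never raises): returns a data frame of issues with one
#' row per finding. `error` rows block registration; `warning` rows are
#' advisory (suspicious but possible values such as a birth date more than
#' 110 years ago, single-character names, or placeholder strings).
#'
#' @param identity named list of raw field values.
#' @param schema an [identity_field_schema()].
#' @param today reference date for future/implausible date checks.
#' @return data frame with columns `field`, `severity`, `message`.
#' @export
quality_check <- function(identity, schema, today = Sys.Date()) {
  identity <- as.list(identity)
  issues <- list()
  add <- function(field, severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      field = field, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }
  for (f in schema$fields) {
    v <- identity[[f$name]]
    blank <- is.null(v) || length(v) == 0L || is.na(v) || !nzchar(trimws(as.character(v)))
    if (blank) {
      if (f$required) add(f$name, "error", "required field is missing or blank")
      next
    }
    v <- as.character(v)
    if (f$kind == "date") {
      d <- normalize_date(v)
      if (is.na(d)) {
        add(f$name, "error", paste0("'", v, "' is not a valid calendar date (expected YYYY-MM-DD)"))
      } else {
        dd <- as.Date(d)
        if (dd > today) add(f$name, "error", "date lies in the future")
        if (dd < today - round(110 * 365.25)) {
          add(f$name, "warning", "date is more than 110 years ago")
        }
      }
    } else if (f$kind == "text") {
      nv <- normalize_text(v)
      if (nchar(nv) == 1L) add(f$name, "warning", "single-character value")
      if (nv %in% PLACEHOLDER_VALUES) {
        add(f$name, "warning", paste0("looks like a placeholder value ('", v, "')"))
      }
      if (grepl("\\d", nv)) add(f$name, "warning", "name contains digits")
    } else if (f$kind == "enum") {
      code <- toupper(trimws(v))
      if (!code %in% toupper(trimws(f$enum_values))) {
        add(f$name, "error", paste0("'", v, "' is not one of ",
                                    paste(f$enum_values, collapse = ", ")))
      }
    }
  }
  if (!length(issues)) {
    return(data.frame(field = character(0), severity = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}
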