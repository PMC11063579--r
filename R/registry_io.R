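#' Registry persistence, locking, import and export
#'
#' A registry directory contains `config.yaml`, the record journals
#' `subjects.csv` and `biosamples.csv` (append-friendly: saving appends only
#' rows not yet persisted), the audit journal `audit.tsv`, `meta.json` and,
#' while a writer is active, `lock.json`. All delimited files are RFC 4180
#' CSV/TSV in UTF-8 with a header row and documented stable columns.
#'
#' Only one writer may hold a registry at a time; lock takeover after a
#' crash must be requested explicitly and is never silent. Read-only opens
#' take a consistent snapshot of the durable files without blocking the
#' writer.
#'
#' @name registry_io
NULL

SUBJECT_BASE_COLS <- c("pseudonym")
SUBJECT_TAIL_COLS <- c("extra_properties", "registered_at", "registered_by")
BIOSAMPLE_COLS <- c("pseudonym", "subject_pseudonym", "visit_id", "sample_type",
                    "aliquot_index", "attributes", "registered_at", "registered_by")

subject_export_cols <- function(schema) {
  c(SUBJECT_BASE_COLS, schema_field_names(schema), SUBJECT_TAIL_COLS)
}

subjects_df <- function(reg, rows = NULL) {
  s <- reg$state$subj
  if (is.null(rows)) rows <- seq_len(s$n)
  schema <- reg$config$identity_schema
  out <- data.frame(pseudonym = s$tab$psn[rows], stringsAsFactors = FALSE)
  for (f in schema_field_names(schema)) {
    out[[f]] <- s$tab[[paste0("raw.", f)]][rows]
  }
  extra <- s$tab$extra
  out$extra_properties <- vapply(rows, function(i) {
    x <- extra[[i]]
    if (is.null(x) || !length(x)) "" else as.character(
      jsonlite::toJSON(x, auto_unbox = TRUE))
  }, character(1))
  out$registered_at <- s$tab$reg_at[rows]
  out$registered_by <- s$tab$reg_by[rows]
  out
}

biosamples_df <- function(reg, rows = NULL) {
  b <- reg$state$bios
  if (is.null(rows)) rows <- seq_len(b$n)
  extra <- b$tab$extra
  data.frame(
    pseudonym = b$tab$psn[rows], subject_pseudonym = b$tab$subject_psn[rows],
    visit_id = b$tab$visit_id[rows], sample_type = b$tab$sample_type[rows],
    aliquot_index = as.integer(b$tab$aliquot_index[rows]),
    attributes = vapply(rows, function(i) {
      x <- extra[[i]]
      if (is.null(x) || !length(x)) "" else as.character(
        jsonlite::toJSON(x, auto_unbox = TRUE))
    }, character(1)),
    registered_at = b$tab$reg_at[rows], registered_by = b$tab$reg_by[rows],
    stringsAsFactors = FALSE
  )
}

# -- locking ------------------------------------------------------------------

lock_path <- function(reg_or_path) {
  p <- if (is.character(reg_or_path)) reg_or_path else reg_or_path$path
  file.path(p, "lock.json")
}

acquire_lock <- function(reg, actor, takeover = FALSE, stale_after_hours = 12) {
  lp <- lock_path(reg)
  if (file.exists(lp)) {
    info <- tryCatch(jsonlite::read_json(lp), error = function(e) NULL)
    holder <- info$holder %||% "unknown"
    acquired <- info$acquired_at %||% ""
    age_h <- suppressWarnings(as.numeric(difftime(
      Sys.time(),
      as.POSIXct(acquired, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC"),
      units = "hours")))
    stale <- is.na(age_h) || age_h >= stale_after_hours
    if (!stale) {
      psn_stop("pseudoreg_lock_held",
               sprintf("registry is locked for writing by '%s' since %s",
                       holder, acquired),
               holder = holder, acquired_at = acquired)
    }
    if (!isTRUE(takeover)) {
      psn_stop("pseudoreg_stale_lock",
               sprintf(paste0("registry lock held by '%s' since %s looks stale ",
                              "(> %g h); re-open with takeover = TRUE to take it over"),
                       holder, acquired, stale_after_hours),
               holder = holder, acquired_at = acquired)
    }
  }
  token <- paste0(Sys.getpid(), "-", format(Sys.time(), "%Y%m%d%H%M%OS6"))
  jsonlite::write_json(
    list(holder = actor, acquired_at = utc_now(), pid = Sys.getpid(),
         token = token),
    lp, auto_unbox = TRUE)
  reg$lock_token <- token
  invisible(reg)
}

release_lock <- function(reg) {
  lp <- lock_path(reg)
  if (!is.null(reg$lock_token) && file.exists(lp)) {
    info <- tryCatch(jsonlite::read_json(lp), error = function(e) NULL)
    if (identical(info$token, reg$lock_token)) unlink(lp)
  }
  reg$lock_token <- NULL
  invisible(reg)
}

# -- save / load --------------------------------------------------------------

#' Persist in-memory registry state to its directory
#'
#' Appends the rows registered since the last save to the record journals
#' and rewrites the small metadata file. A registry created with
#' `path = NULL` cannot be saved.
#'
#' @param registry a registry handle in write mode.
#' @return the registry handle, invisibly.
#' @export
registry_save <- function(registry) {
  assert_writable(registry)
  if (is.null(registry$path)) {
    psn_stop("pseudoreg_parse_error", "in-memory registry has no path to save to")
  }
  p <- registry$path
  append_csv <- function(df, file, sep = ",") {
    if (!nrow(df)) {
      if (!file.exists(file)) {
        data.table::fwrite(df, file, sep = sep, quote = "auto", eol = "\n")
      }
      return(invisible())
    }
    data.table::fwrite(df, file, sep = sep, quote = "auto", eol = "\n",
                       append = file.exists(file))
  }
  s <- registry$state$subj
  new_s <- seq_len(s$n)[seq_len(s$n) > registry$persisted$subjects]
  append_csv(subjects_df(registry, new_s), file.path(p, "subjects.csv"))
  registry$persisted$subjects <- s$n

  b <- registry$state$bios
  new_b <- seq_len(b$n)[seq_len(b$n) > registry$persisted$biosamples]
  append_csv(biosamples_df(registry, new_b), file.path(p, "biosamples.csv"))
  registry$persisted$biosamples <- b$n

  a <- registry$state$audit
  new_a <- seq_len(a$n)[seq_len(a$n) > registry$persisted$audit]
  adf <- data.frame(ts = a$tab$ts[new_a], actor = a$tab$actor[new_a],
                    action = a$tab$action[new_a], target = a$tab$target[new_a],
                    note = a$tab$note[new_a], stringsAsFactors = FALSE)
  append_csv(adf, file.path(p, "audit.tsv"), sep = "\t")
  registry$persisted$audit <- a$n

  jsonlite::write_json(
    list(revision = registry$revision,
         last_backup_at = registry$last_backup_at),
    file.path(p, "meta.json"), auto_unbox = TRUE, null = "null")
  invisible(registry)
}

# Vectorized rebuild of the in-memory store from the journals.
load_subjects_into <- function(reg, df) {
  if (!nrow(df)) return(invisible(reg))
  schema <- reg$config$identity_schema
  s <- reg$state$subj
  n <- nrow(df)
  store_grow(s, n)
  idx <- s$n + seq_len(n)
  data.table::set(s$tab, idx, "psn", as.character(df$pseudonym))
  data.table::set(s$tab, idx, "reg_at", as.character(df$registered_at))
  data.table::set(s$tab, idx, "reg_by", as.character(df$registered_by))
  for (f in schema$fields) {
    raw <- as.character(df[[f$name]])
    raw[is.na(raw)] <- NA_character_
    data.table::set(s$tab, idx, paste0("raw.", f$name), raw)
    nc <- normalize_column(raw, f)
    data.table::set(s$tab, idx, paste0("norm.", f$name), nc)
    if (f$kind == "date") {
      data.table::set(s$tab, idx, paste0("dc.", f$name, ".y"),
                      as.integer(substr(nc, 1L, 4L)))
      data.table::set(s$tab, idx, paste0("dc.", f$name, ".m"),
                      as.integer(substr(nc, 6L, 7L)))
      data.table::set(s$tab, idx, paste0("dc.", f$name, ".d"),
                      as.integer(substr(nc, 9L, 10L)))
    }
  }
  ep <- as.character(df$extra_properties %||% rep("", n))
  has_ep <- !is.na(ep) & nzchar(ep)
  if (any(has_ep)) {
    data.table::set(s$tab, idx[has_ep], "extra",
                    lapply(ep[has_ep], jsonlite::fromJSON, simplifyVector = TRUE))
  }
  psns <- s$tab$psn
  for (k in seq_len(n)) s$index[[psns[idx[k]]]] <- idx[k]
  build_blocks(s, schema, idx)
  s$n <- s$n + n
  reg$revision <- reg$revision + n
  invisible(reg)
}

normalize_column <- function(raw, f) {
  out <- rep(NA_character_, length(raw))
  ok <- !is.na(raw) & nzchar(trimws(raw))
  if (!any(ok)) return(out)
  out[ok] <- switch(f$kind,
    text = normalize_text(raw[ok]),
    date = normalize_date(raw[ok]),
    enum = {
      canon <- toupper(trimws(f$enum_values))
      hit <- match(toupper(trimws(raw[ok])), canon)
      ifelse(is.na(hit), NA_character_, f$enum_values[hit])
    })
  out
}

build_blocks <- function(s, schema, idx) {
  for (f in schema$fields) {
    v <- s$tab[[paste0("norm.", f$name)]][idx]
    ok <- !is.na(v) & nzchar(v)
    if (!any(ok)) next
    keysets <- if (f$kind == "text") {
      list(paste0("t|", f$name, "|", substr(v[ok], 1L, 2L)))
    } else if (f$kind == "date") {
      list(paste0("d|", f$name, "|", v[ok]))
    } else {
      list()
    }
    for (keys in keysets) {
      spl <- split(idx[ok], keys)
      for (k in names(spl)) blocks_append_many(s, k, spl[[k]])
    }
  }
}

load_biosamples_into <- function(reg, df) {
  if (!nrow(df)) return(invisible(reg))
  b <- reg$state$bios
  n <- nrow(df)
  store_grow(b, n)
  idx <- b$n + seq_len(n)
  data.table::set(b$tab, idx, "psn", as.character(df$pseudonym))
  data.table::set(b$tab, idx, "subject_psn", as.character(df$subject_pseudonym))
  data.table::set(b$tab, idx, "visit_id", as.character(df$visit_id))
  data.table::set(b$tab, idx, "sample_type", as.character(df$sample_type))
  data.table::set(b$tab, idx, "aliquot_index", as.character(df$aliquot_index))
  data.table::set(b$tab, idx, "reg_at", as.character(df$registered_at))
  data.table::set(b$tab, idx, "reg_by", as.character(df$registered_by))
  at <- as.character(df$attributes %||% rep("", n))
  has_at <- !is.na(at) & nzchar(at)
  if (any(has_at)) {
    data.table::set(b$tab, idx[has_at], "extra",
                    lapply(at[has_at], jsonlite::fromJSON, simplifyVector = TRUE))
  }
  psns <- b$tab$psn
  for (k in seq_len(n)) b$index[[psns[idx[k]]]] <- idx[k]
  b$n <- b$n + n
  reg$revision <- reg$revision + n
  invisible(reg)
}

read_registry_csv <- function(file, sep = ",") {
  if (!file.exists(file)) return(NULL)
  as.data.frame(data.table::fread(file, sep = sep, colClasses = "character",
                                  na.strings = NULL, encoding = "UTF-8"))
}

#' Open an existing registry directory
#'
#' Write mode acquires the exclusive lock (or fails naming the current
#' holder; a stale lock older than `stale_after_hours` can be taken over
#' only with `takeover = TRUE`). Read-only mode loads a consistent snapshot
#' of the durable files without touching the lock.
#'
#' @param path registry directory created by [registry_create()].
#' @param mode `"write"` or `"read_only"`.
#' @param actor identifier recorded as the lock holder / in the audit log.
#' @param takeover explicitly take over a stale lock.
#' @param stale_after_hours age after which a lock is considered stale.
#' @return a registry handle.
#' @export
open_registry <- function(path, mode = c("write", "read_only"),
                          actor = "system", takeover = FALSE,
                          stale_after_hours = 12) {
  mode <- match.arg(mode)
  cfg_file <- file.path(path, "config.yaml")
  if (!file.exists(cfg_file)) {
    psn_stop("pseudoreg_parse_error",
             paste0("not a registry directory (no config.yaml): ", path))
  }
  config <- load_config(cfg_file)
  reg <- make_registry_handle(config, path = path, mode = mode)
  if (mode == "write") {
    acquire_lock(reg, actor = actor, takeover = takeover,
                 stale_after_hours = stale_after_hours)
  }
  sdf <- read_registry_csv(file.path(path, "subjects.csv"))
  if (!is.null(sdf)) load_subjects_into(reg, sdf)
  bdf <- read_registry_csv(file.path(path, "biosamples.csv"))
  if (!is.null(bdf)) load_biosamples_into(reg, bdf)
  adf <- read_registry_csv(file.path(path, "audit.tsv"), sep = "\t")
  if (!is.null(adf) && nrow(adf)) {
    a <- reg$state$audit
    store_grow(a, nrow(adf))
    idx <- seq_len(nrow(adf))
    data.table::set(a$tab, idx, "ts", adf$ts)
    data.table::set(a$tab, idx, "actor", adf$actor)
    data.table::set(a$tab, idx, "action", adf$action)
    data.table::set(a$tab, idx, "target", adf$target)
    data.table::set(a$tab, idx, "note",
                    if (is.null(adf$note)) "" else ifelse(is.na(adf$note), "", adf$note))
    a$n <- nrow(adf)
  }
  meta <- tryCatch(jsonlite::read_json(file.path(path, "meta.json")),
                   error = function(e) NULL)
  if (!is.null(meta$last_backup_at)) reg$last_backup_at <- meta$last_backup_at
  reg$persisted <- list(subjects = reg$state$subj$n,
                        biosamples = reg$state$bios$n,
                        audit = reg$state$audit$n)
  if (mode == "write") audit_add(reg, actor, "open_registry", path)
  reg
}

#' Close a registry handle
#'
#' Saves pending state (write mode) and releases the writer lock.
#'
#' @param registry a registry handle.
#' @return invisibly, `NULL`.
#' @export
registry_close <- function(registry) {
  if (identical(registry$mode, "write") && !is.null(registry$path)) {
    registry_save(registry)
    release_lock(registry)
  }
  invisible(NULL)
}

# -- export -------------------------------------------------------------------

#' Export registry contents as CSV
#'
#' Deterministic column order and row order (by pseudonym); the output is
#' re-importable through `bulk_import_subjects(mode =
#' "restore_with_pseudonyms")`. When `backup = TRUE`, the export is recorded
#' as a backup and resets the backup reminder.
#'
#' @param registry a registry handle.
#' @param dir output directory (created if missing).
#' @param scope `"all"`, `"subjects"` or `"biosamples"`.
#' @param backup record this export as a backup.
#' @param actor identifier recorded in the audit log.
#' @return named character vector of written file paths, invisibly.
#' @export
export_registry <- function(registry, dir, scope = c("all", "subjects", "biosamples"),
                            backup = FALSE, actor = "unknown") {
  scope <- match.arg(scope)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  if (scope %in% c("all", "subjects")) {
    df <- subjects_df(registry)
    df <- df[order(df$pseudonym), , drop = FALSE]
    f <- file.path(dir, "subjects.csv")
    data.table::fwrite(df, f, sep = ",", quote = "auto", eol = "\n")
    out["subjects"] <- f
  }
  if (scope %in% c("all", "biosamples")) {
    df <- biosamples_df(registry)
    df <- df[order(df$pseudonym), , drop = FALSE]
    f <- file.path(dir, "biosamples.csv")
    data.table::fwrite(df, f, sep = ",", quote = "auto", eol = "\n")
    out["biosamples"] <- f
  }
  if (isTRUE(backup)) {
    registry$last_backup_at <- utc_now()
    audit_add(registry, actor, "backup_export", dir)
  } else {
    audit_add(registry, actor, "export", dir)
  }
  invisible(out)
}

# -- bulk import --------------------------------------------------------------

import_rows <- function(rows) {
  if (is.character(rows) && length(rows) == 1L) {
    if (!file.exists(rows)) {
      psn_stop("pseudoreg_parse_error", paste0("import file not found: ", rows))
    }
    df <- tryCatch(
      as.data.frame(data.table::fread(rows, sep = ",", colClasses = "character",
                                      na.strings = NULL, encoding = "UTF-8")),
      error = function(e) psn_stop("pseudoreg_parse_error",
                                   paste0("malformed import file: ",
                                          conditionMessage(e))))
    df
  } else {
    as.data.frame(rows, stringsAsFactors = FALSE)
  }
}

new_import_report <- function(n) {
  data.frame(row = seq_len(n), status = rep(NA_character_, n),
             pseudonym = rep(NA_character_, n),
             matched_pseudonym = rep(NA_character_, n),
             reason = rep("", n), stringsAsFactors = FALSE)
}

summarize_report <- function(report) {
  structure(list(
    accepted = sum(report$status == "accepted"),
    rejected = sum(report$status == "rejected"),
    duplicates_flagged = sum(report$status == "duplicate"),
    rows = report
  ), class = "pseudoreg_import_report")
}

#' @export
print.pseudoreg_import_report <- function(x, ...) {
  cat(sprintf("Import report: %d accepted, %d rejected, %d duplicate(s) flagged\n",
              x$accepted, x$rejected, x$duplicates_flagged))
  bad <- x$rows[x$rows$status != "accepted", , drop = FALSE]
  if (nrow(bad)) {
    show <- utils::head(bad, 10L)
    for (i in seq_len(nrow(show))) {
      cat(sprintf("  row %d [%s] %s\n", show$row[i], show$status[i], show$reason[i]))
    }
    if (nrow(bad) > 10L) cat(sprintf("  ... and %d more\n", nrow(bad) - 10L))
  }
  invisible(x)
}

#' Bulk-import subjects from a delimited file
#'
#' `register_new` treats each row as a fresh enrolment: data-quality checks
#' and fuzzy linkage run against the registry *and* the rows already
#' accepted from the same file, so retrospective data sets are deduplicated
#' on the way in. `restore_with_pseudonyms` re-ingests a previous export
#' verbatim, preserving pseudonyms; any pseudonym collision aborts the whole
#' file with a diff report. Acceptance is always decided row by row, never
#' for the file as a whole (except the restore collision abort).
#'
#' @param registry a registry handle in write mode.
#' @param rows path to a UTF-8 CSV file with a header row, or a data frame.
#'   `register_new` expects the identity schema columns;
#'   `restore_with_pseudonyms` additionally expects `pseudonym` (and keeps
#'   `registered_at` / `registered_by` / `extra_properties` when present).
#' @param mode `"register_new"` or `"restore_with_pseudonyms"`.
#' @param actor identifier recorded in the audit log.
#' @return a `pseudoreg_import_report`: counts plus a row-indexed table of
#'   `accepted` / `rejected` / `duplicate` outcomes with reasons.
#' @export
bulk_import_subjects <- function(registry, rows,
                                 mode = c("register_new", "restore_with_pseudonyms"),
                                 actor = "unknown") {
  assert_writable(registry)
  mode <- match.arg(mode)
  df <- import_rows(rows)
  schema <- registry$config$identity_schema
  miss <- setdiff(schema_field_names(schema)[vapply(schema$fields, `[[`,
                                                    logical(1), "required")],
                  names(df))
  if (length(miss)) {
    psn_stop("pseudoreg_parse_error",
             paste0("import file is missing required column(s): ",
                    paste(miss, collapse = ", ")))
  }
  n <- nrow(df)
  report <- new_import_report(n)
  if (!n) {
    audit_add(registry, actor, "bulk_import_subjects", mode, "0 rows")
    return(summarize_report(report))
  }

  # Vectorized normalization + quality pre-pass.
  norm_cols <- list()
  row_error <- rep(NA_character_, n)
  today <- Sys.Date()
  for (f in schema$fields) {
    raw <- if (f$name %in% names(df)) as.character(df[[f$name]]) else rep(NA_character_, n)
    nc <- normalize_column(raw, f)
    norm_cols[[f$name]] <- nc
    blank <- is.na(raw) | !nzchar(trimws(raw))
    if (f$required) {
      bad <- blank & is.na(row_error)
      row_error[bad] <- paste0("required field '", f$name, "' is missing or blank")
    }
    invalid <- !blank & is.na(nc) & is.na(row_error)
    row_error[invalid] <- paste0("field '", f$name, "' has an invalid value")
    if (f$kind == "date") {
      fut <- !is.na(nc) & as.Date(nc) > today & is.na(row_error)
      row_error[fut] <- paste0("field '", f$name, "' lies in the future")
    }
  }

  if (mode == "restore_with_pseudonyms") {
    if (!"pseudonym" %in% names(df)) {
      psn_stop("pseudoreg_parse_error", "restore mode requires a 'pseudonym' column")
    }
    psn <- as.character(df$pseudonym)
    valid <- vapply(psn, function(v) {
      validate_pseudonym(v, registry$config$subject_format)$ok
    }, logical(1))
    row_error[!valid & is.na(row_error)] <- "pseudonym fails validation"
    existing <- psn %in% existing_pseudonym_set(registry)
    dup_in_file <- duplicated(psn) | duplicated(psn, fromLast = TRUE)
    collide <- (existing | dup_in_file) & valid
    if (any(collide)) {
      diff <- data.frame(row = which(collide), pseudonym = psn[collide],
                         conflict = ifelse(existing[collide],
                                           "already in registry",
                                           "duplicated within file"),
                         stringsAsFactors = FALSE)
      psn_stop("pseudoreg_restore_collision",
               paste0("restore aborted: ", nrow(diff),
                      " pseudonym collision(s); see the 'diff' field"),
               diff = diff)
    }
    now <- utc_now()
    reg_at <- if ("registered_at" %in% names(df)) as.character(df$registered_at) else rep(now, n)
    reg_by <- if ("registered_by" %in% names(df)) as.character(df$registered_by) else rep(actor, n)
    ep <- if ("extra_properties" %in% names(df)) as.character(df$extra_properties) else rep("", n)
    status <- report$status; reason <- report$reason; out_psn <- report$pseudonym
    fields <- schema_field_names(schema)
    for (i in seq_len(n)) {
      if (!is.na(row_error[i])) {
        status[i] <- "rejected"; reason[i] <- row_error[i]
        next
      }
      raw <- lapply(fields, function(f) df[[f]][i])
      names(raw) <- fields
      norm <- lapply(norm_cols, `[[`, i)
      extra <- if (nzchar(ep[i])) jsonlite::fromJSON(ep[i], simplifyVector = TRUE) else list()
      subj_insert(registry, psn[i], raw, norm, extra, reg_at[i], reg_by[i])
      status[i] <- "accepted"; out_psn[i] <- psn[i]
    }
    report$status <- status; report$reason <- reason; report$pseudonym <- out_psn
    audit_add(registry, actor, "bulk_import_subjects", mode,
              paste0(sum(report$status == "accepted"), " restored"))
    return(summarize_report(report))
  }

  # register_new: pre-generate one pseudonym per row, consume as accepted.
  psns <- generate_pseudonym(registry$config$subject_format,
                             existing_pseudonym_set(registry), n = n)
  used <- 0L
  now <- utc_now()
  review_thr <- registry$config$review_threshold
  fields <- schema_field_names(schema)
  status <- report$status; reason <- report$reason
  out_psn <- report$pseudonym; matched <- report$matched_pseudonym
  for (i in seq_len(n)) {
    if (!is.na(row_error[i])) {
      status[i] <- "rejected"; reason[i] <- row_error[i]
      next
    }
    norm <- lapply(norm_cols, `[[`, i)
    hit <- linkage_scan(registry, norm, min_score = review_thr, want_sims = FALSE)
    if (length(hit$idx)) {
      best <- which.max(hit$score)
      status[i] <- "duplicate"
      matched[i] <- registry$state$subj$tab$psn[hit$idx[best]]
      reason[i] <- sprintf("matches %s (score %.3f)", matched[i], hit$score[best])
      next
    }
    used <- used + 1L
    raw <- lapply(fields, function(f) df[[f]][i])
    names(raw) <- fields
    subj_insert(registry, psns[used], raw, norm, list(), now, actor)
    status[i] <- "accepted"; out_psn[i] <- psns[used]
  }
  report$status <- status; report$reason <- reason
  report$pseudonym <- out_psn; report$matched_pseudonym <- matched
  audit_add(registry, actor, "bulk_import_subjects", mode,
            sprintf("%d accepted, %d rejected, %d duplicates",
                    sum(report$status == "accepted"),
                    sum(report$status == "rejected"),
                    sum(report$status == "duplicate")))
  summarize_report(report)
}

#' Bulk-import biosamples from a delimited file
#'
#' `register_new` rows need `subject_pseudonym`, `visit_id` and
#' `sample_type`; each row becomes one aliquot with a fresh pseudonym after
#' checking that the subject exists and the visit/type combination is
#' scheduled. `restore_with_pseudonyms` preserves the `pseudonym` and
#' `aliquot_index` columns of a previous export; collisions abort the file.
#'
#' @inheritParams bulk_import_subjects
#' @return a `pseudoreg_import_report`.
#' @export
bulk_import_biosamples <- function(registry, rows,
                                   mode = c("register_new", "restore_with_pseudonyms"),
                                   actor = "unknown") {
  assert_writable(registry)
  mode <- match.arg(mode)
  df <- import_rows(rows)
  need <- c("subject_pseudonym", "visit_id", "sample_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    psn_stop("pseudoreg_parse_error",
             paste0("import file is missing required column(s): ",
                    paste(miss, collapse = ", ")))
  }
  n <- nrow(df)
  report <- new_import_report(n)
  if (!n) return(summarize_report(report))

  allowed <- new.env(parent = emptyenv())
  for (v in registry$config$schedule) {
    for (st in v$allowed_sample_types) allowed[[paste0(v$visit_id, "|", st)]] <- TRUE
  }
  subj_psn <- as.character(df$subject_pseudonym)
  visit <- as.character(df$visit_id)
  stype <- as.character(df$sample_type)
  attrs <- if ("attributes" %in% names(df)) as.character(df$attributes) else rep("", n)
  now <- utc_now()

  restore <- mode == "restore_with_pseudonyms"
  if (restore) {
    if (!"pseudonym" %in% names(df)) {
      psn_stop("pseudoreg_parse_error", "restore mode requires a 'pseudonym' column")
    }
    psn <- as.character(df$pseudonym)
    valid <- vapply(psn, function(v) {
      validate_pseudonym(v, registry$config$biosample_format)$ok
    }, logical(1))
    existing <- psn %in% existing_pseudonym_set(registry)
    dup_in_file <- duplicated(psn) | duplicated(psn, fromLast = TRUE)
    collide <- (existing | dup_in_file) & valid
    if (any(collide)) {
      diff <- data.frame(row = which(collide), pseudonym = psn[collide],
                         conflict = ifelse(existing[collide],
                                           "already in registry",
                                           "duplicated within file"),
                         stringsAsFactors = FALSE)
      psn_stop("pseudoreg_restore_collision",
               paste0("restore aborted: ", nrow(diff),
                      " pseudonym collision(s); see the 'diff' field"),
               diff = diff)
    }
  } else {
    psn <- generate_pseudonym(registry$config$biosample_format,
                              existing_pseudonym_set(registry), n = n)
    valid <- rep(TRUE, n)
  }
  ali <- if ("aliquot_index" %in% names(df)) as.character(df$aliquot_index) else NULL
  ali_counter <- new.env(parent = emptyenv())
  reg_at <- if (restore && "registered_at" %in% names(df)) {
    as.character(df$registered_at)
  } else rep(now, n)
  reg_by <- if (restore && "registered_by" %in% names(df)) {
    as.character(df$registered_by)
  } else rep(actor, n)
  used <- 0L
  status <- report$status; reason <- report$reason; out_psn <- report$pseudonym
  for (i in seq_len(n)) {
    if (restore && !valid[i]) {
      status[i] <- "rejected"; reason[i] <- "pseudonym fails validation"
      next
    }
    if (is.na(subject_lookup(registry, subj_psn[i]))) {
      status[i] <- "rejected"
      reason[i] <- paste0("unknown subject ", subj_psn[i])
      next
    }
    if (is.null(allowed[[paste0(visit[i], "|", stype[i])]])) {
      status[i] <- "rejected"
      reason[i] <- paste0("visit/type ", visit[i], "/", stype[i],
                          " is not in the schedule")
      next
    }
    used <- used + 1L
    this_psn <- if (restore) psn[i] else psn[used]
    a_idx <- if (!is.null(ali) && nzchar(ali[i])) {
      as.integer(ali[i])
    } else {
      key <- paste0(subj_psn[i], "|", visit[i], "|", stype[i])
      cur <- ali_counter[[key]] %||% 0L
      ali_counter[[key]] <- cur + 1L
      cur + 1L
    }
    attr_list <- if (nzchar(attrs[i])) jsonlite::fromJSON(attrs[i], simplifyVector = TRUE) else list()
    bios_insert(registry, this_psn, subj_psn[i], visit[i], stype[i], a_idx,
                attr_list, reg_at[i], reg_by[i])
    status[i] <- "accepted"; out_psn[i] <- this_psn
  }
  report$status <- status; report$reason <- reason; report$pseudonym <- out_psn
  audit_add(registry, actor, "bulk_import_biosamples", mode,
            sprintf("%d accepted, %d rejected",
                    sum(report$status == "accepted"),
                    sum(report$status == "rejected")))
  summarize_report(report)
}
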