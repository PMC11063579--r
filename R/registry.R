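#' The pseudonymization registry
#'
#' A registry holds the identifying data (IDAT) of enrolled subjects, the
#' sample data (SDAT) of their biosample aliquots, and the pseudonyms that
#' link them to downstream systems. Medical data are deliberately
#' unstorable: there are no free-form clinical fields, only the configured
#' identity schema and site-specific `extra_properties` (which must not be
#' used for clinical content). The registry is a local directory store with
#' single-writer locking, parallel read-only snapshots, an append-only audit
#' log and export-based backups.
#'
#' @name registry
NULL

utc_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S+0000", tz = "UTC")

# Columns live in a data.table and are written with data.table::set(),
# which updates by reference: a registry handle is referenced from several
# places (handle, closures, block index), and plain `env$col[i] <- v`
# writes on a shared structure would copy the whole column on every row.
new_column_store <- function(columns, int_columns = character(0)) {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$cap <- 0L
  e$columns <- columns
  e$int_columns <- int_columns
  e$tab <- store_chunk(columns, int_columns, 0L)
  e$index <- new.env(parent = emptyenv(), hash = TRUE)
  e$blocks <- new.env(parent = emptyenv(), hash = TRUE)
  e
}

store_chunk <- function(columns, int_columns, k) {
  cols <- stats::setNames(lapply(columns, function(x) rep(NA_character_, k)),
                          columns)
  for (ic in int_columns) cols[[ic]] <- rep(NA_integer_, k)
  cols$extra <- vector("list", k)
  data.table::setDT(cols)
  cols
}

store_grow <- function(e, need = 1L) {
  if (e$n + need <= e$cap) return(invisible(e))
  newcap <- max(64L, e$cap * 2L, e$n + need)
  e$tab <- data.table::rbindlist(list(
    e$tab, store_chunk(e$columns, e$int_columns, newcap - e$cap)))
  e$cap <- newcap
  invisible(e)
}

store_set <- function(e, i, col, v) {
  data.table::set(e$tab, i, col, v)
}

# Growing must happen one vector per function call so locals die on frame
# exit and the binding keeps reference count 1 (used by the block index).
grow_column <- function(e, col, newcap) {
  v <- e[[col]]
  length(v) <- newcap
  e[[col]] <- v
  invisible(NULL)
}

subject_columns <- function(schema) {
  c("psn", paste0("raw.", schema_field_names(schema)),
    paste0("norm.", schema_field_names(schema)), "reg_at", "reg_by")
}

# Integer year/month/day columns per date field, so the per-candidate scan
# compares integers instead of re-parsing date strings.
subject_date_fields <- function(schema) {
  nms <- schema_field_names(schema)
  nms[vapply(schema$fields, function(f) f$kind == "date", logical(1))]
}

subject_int_columns <- function(schema) {
  df <- subject_date_fields(schema)
  if (!length(df)) return(character(0))
  as.vector(t(outer(paste0("dc.", df), c(".y", ".m", ".d"), paste0)))
}

biosample_columns <- function() {
  c("psn", "subject_psn", "visit_id", "sample_type", "aliquot_index",
    "reg_at", "reg_by")
}

new_registry_state <- function(config) {
  st <- new.env(parent = emptyenv())
  st$subj <- new_column_store(subject_columns(config$identity_schema),
                              subject_int_columns(config$identity_schema))
  st$bios <- new_column_store(biosample_columns())
  st$audit <- new_column_store(c("ts", "actor", "action", "target", "note"))
  st$comparisons <- 0
  st
}

# Blocking keys of one normalized identity: 2-character prefix of every
# text field plus the full value of every date field. A record is a
# linkage candidate if it shares at least one key with the query. Because
# a duplicate leaves at least one identity field untouched (edits are
# bounded and never hit every field), at least one of these keys survives
# any admissible typo pattern, so blocking never loses a candidate that a
# brute-force scan would score - it is an optimization only.
block_keys <- function(norm, schema) {
  keys <- character(0)
  for (f in schema$fields) {
    v <- norm[[f$name]]
    if (is.null(v) || is.na(v) || !nzchar(v)) next
    if (f$kind == "text") {
      keys <- c(keys, paste0("t|", f$name, "|", substr(v, 1L, 2L)))
    } else if (f$kind == "date") {
      keys <- c(keys, paste0("d|", f$name, "|", v))
    }
  }
  keys
}

# Each block is a small environment holding a doubling integer vector, so
# appending a record is O(1) amortized rather than copying the block.
blocks_add <- function(store, keys, i) {
  for (k in keys) {
    be <- store$blocks[[k]]
    if (is.null(be)) {
      be <- new.env(parent = emptyenv())
      be$v <- integer(8L)
      be$n <- 0L
      store$blocks[[k]] <- be
    } else if (be$n == length(be$v)) {
      grow_column(be, "v", 2L * be$n)
    }
    be$n <- be$n + 1L
    be$v[be$n] <- i
  }
}

blocks_append_many <- function(store, key, idx) {
  be <- store$blocks[[key]]
  if (is.null(be)) {
    be <- new.env(parent = emptyenv())
    be$v <- idx
    be$n <- length(idx)
    store$blocks[[key]] <- be
  } else {
    need <- be$n + length(idx)
    if (need > length(be$v)) grow_column(be, "v", max(2L * be$n, need))
    be$v[be$n + seq_along(idx)] <- idx
    be$n <- need
  }
}

blocks_candidates <- function(store, keys) {
  hits <- lapply(keys, function(k) {
    be <- store$blocks[[k]]
    if (is.null(be)) NULL else be$v[seq_len(be$n)]
  })
  idx <- unlist(hits, use.names = FALSE)
  if (is.null(idx)) integer(0) else unique(idx)
}

# -- registry handle ----------------------------------------------------------

make_registry_handle <- function(config, path = NULL, mode = "write") {
  reg <- new.env(parent = emptyenv())
  reg$config <- config
  reg$path <- path
  reg$mode <- mode
  reg$revision <- 0L
  reg$last_backup_at <- NULL
  reg$state <- new_registry_state(config)
  reg$persisted <- list(subjects = 0L, biosamples = 0L, audit = 0L)
  reg$lock_token <- NULL
  class(reg) <- "pseudoreg_registry"
  reg
}

#' Create a new registry
#'
#' @param config a validated [study_config()].
#' @param path optional directory for the durable store; `NULL` keeps the
#'   registry in memory only (useful for evaluation runs and tests).
#' @param actor identifier of the person or process creating the registry.
#' @return a registry handle (class `pseudoreg_registry`) opened in write
#'   mode.
#' @export
registry_create <- function(config, path = NULL, actor = "system") {
  validate_config(config)
  reg <- make_registry_handle(config, path = path, mode = "write")
  if (!is.null(path)) {
    if (dir.exists(path) && length(list.files(path, all.files = TRUE, no.. = TRUE))) {
      psn_stop("pseudoreg_parse_error",
               paste0("directory exists and is not empty: ", path))
    }
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(path, "config.yaml"))
    acquire_lock(reg, actor = actor, takeover = FALSE, stale_after_hours = 12)
    registry_save(reg)
  }
  audit_add(reg, actor, "create_registry", config$study_name)
  reg
}

#' @export
print.pseudoreg_registry <- function(x, ...) {
  cat(sprintf("<pseudoreg registry '%s'> %s subjects, %s biosamples [%s%s]\n",
              x$config$study_name, x$state$subj$n, x$state$bios$n, x$mode,
              if (is.null(x$path)) ", in-memory" else paste0(", ", x$path)))
  invisible(x)
}

assert_writable <- function(reg) {
  if (!identical(reg$mode, "write")) {
    psn_stop("pseudoreg_readonly_error",
             "registry is open read-only; mutating operations need write mode")
  }
}

audit_add <- function(reg, actor, action, target, note = "") {
  a <- reg$state$audit
  store_grow(a)
  i <- a$n + 1L
  a$n <- i
  store_set(a, i, "ts", utc_now())
  store_set(a, i, "actor", as.character(actor))
  store_set(a, i, "action", action)
  store_set(a, i, "target", as.character(target))
  store_set(a, i, "note", note)
  invisible(reg)
}

#' Read the audit log
#'
#' @param registry a registry handle.
#' @return data frame with columns `ts`, `actor`, `action`, `target`,
#'   `note`, in append order.
#' @export
audit_log <- function(registry) {
  a <- registry$state$audit
  n <- a$n
  t <- a$tab
  data.frame(ts = t$ts[seq_len(n)], actor = t$actor[seq_len(n)],
             action = t$action[seq_len(n)], target = t$target[seq_len(n)],
             note = t$note[seq_len(n)], stringsAsFactors = FALSE)
}

existing_pseudonym_set <- function(reg) {
  s <- reg$state$subj; b <- reg$state$bios
  c(s$tab$psn[seq_len(s$n)], b$tab$psn[seq_len(b$n)])
}

subject_lookup <- function(reg, psn) {
  i <- reg$state$subj$index[[psn]]
  if (is.null(i)) NA_integer_ else i
}

subj_insert <- function(reg, psn, raw, norm, extra, reg_at, reg_by) {
  s <- reg$state$subj
  store_grow(s)
  i <- s$n + 1L
  s$n <- i
  store_set(s, i, "psn", psn)
  store_set(s, i, "reg_at", reg_at)
  store_set(s, i, "reg_by", reg_by)
  for (f in schema_field_names(reg$config$identity_schema)) {
    rv <- raw[[f]]
    store_set(s, i, paste0("raw.", f),
              if (is.null(rv) || is.na(rv)) NA_character_ else as.character(rv))
    nv <- norm[[f]]
    store_set(s, i, paste0("norm.", f),
              if (is.null(nv)) NA_character_ else nv)
  }
  for (f in subject_date_fields(reg$config$identity_schema)) {
    nv <- norm[[f]]
    if (!is.null(nv) && !is.na(nv)) {
      store_set(s, i, paste0("dc.", f, ".y"), as.integer(substr(nv, 1L, 4L)))
      store_set(s, i, paste0("dc.", f, ".m"), as.integer(substr(nv, 6L, 7L)))
      store_set(s, i, paste0("dc.", f, ".d"), as.integer(substr(nv, 9L, 10L)))
    }
  }
  if (length(extra)) store_set(s, i, "extra", list(extra))
  s$index[[psn]] <- i
  blocks_add(s, block_keys(norm, reg$config$identity_schema), i)
  reg$revision <- reg$revision + 1L
  i
}

bios_insert <- function(reg, psn, subject_psn, visit_id, sample_type,
                        aliquot_index, attributes, reg_at, reg_by) {
  b <- reg$state$bios
  store_grow(b)
  i <- b$n + 1L
  b$n <- i
  store_set(b, i, "psn", psn)
  store_set(b, i, "subject_psn", subject_psn)
  store_set(b, i, "visit_id", visit_id)
  store_set(b, i, "sample_type", sample_type)
  store_set(b, i, "aliquot_index", as.character(aliquot_index))
  store_set(b, i, "reg_at", reg_at)
  store_set(b, i, "reg_by", reg_by)
  if (length(attributes)) store_set(b, i, "extra", list(attributes))
  b$index[[psn]] <- i
  reg$revision <- reg$revision + 1L
  i
}

# Date similarity against stored integer components: 1 when equal, 0.8 on
# a day/month transposition or when exactly one component differs, else 0.
date_sim_components <- function(qy, qm, qd, y, m, d) {
  sim <- numeric(length(y))
  ey <- y == qy; em <- m == qm; ed <- d == qd
  sim[ey & em & ed] <- 1
  partial <- (ey & (m == qd) & (d == qm)) |
    ((ey + em + ed) == 2L)
  sim[partial & sim < 1] <- 0.8
  sim[is.na(y)] <- NA_real_
  sim
}

date_query_components <- function(v) {
  c(as.integer(substr(v, 1L, 4L)), as.integer(substr(v, 6L, 7L)),
    as.integer(substr(v, 9L, 10L)))
}

# Fuzzy linkage scan: score the blocked candidate set of `norm` against the
# registry. Returns indices, per-field similarity matrix and aggregate
# scores. Every scanned candidate increments the comparison counter, which
# is how scaling is asserted without relying on wall clocks.
linkage_scan <- function(reg, norm, min_score = 0, want_sims = TRUE) {
  s <- reg$state$subj
  schema <- reg$config$identity_schema
  empty <- list(idx = integer(0),
                score = numeric(0),
                sims = matrix(numeric(0), nrow = 0, ncol = length(schema$fields),
                              dimnames = list(NULL, schema_field_names(schema))))
  if (s$n == 0L) return(empty)
  cand <- blocks_candidates(s, block_keys(norm, schema))
  if (!length(cand)) return(empty)
  reg$state$comparisons <- reg$state$comparisons + length(cand)
  w <- schema_weights(schema)
  nms <- schema_field_names(schema)

  queried <- Filter(function(f) !is.null(norm[[f$name]]) && !is.na(norm[[f$name]]),
                    schema$fields)
  cheap <- Filter(function(f) f$kind != "text", queried)
  texts <- Filter(function(f) f$kind == "text", queried)

  cheap_sims <- list()
  ssum <- numeric(length(cand))
  wsum <- numeric(length(cand))
  for (f in cheap) {
    qv <- norm[[f$name]]
    sim <- if (f$kind == "date") {
      q3 <- date_query_components(qv)
      date_sim_components(q3[1], q3[2], q3[3],
                          s$tab[[paste0("dc.", f$name, ".y")]][cand],
                          s$tab[[paste0("dc.", f$name, ".m")]][cand],
                          s$tab[[paste0("dc.", f$name, ".d")]][cand])
    } else {
      col <- s$tab[[paste0("norm.", f$name)]][cand]
      sim <- as.numeric(!is.na(col) & col == qv)
      sim[is.na(col)] <- NA_real_
      sim
    }
    cheap_sims[[f$name]] <- sim
    ok <- !is.na(sim)
    ssum[ok] <- ssum[ok] + sim[ok] * w[[f$name]]
    wsum[ok] <- wsum[ok] + w[[f$name]]
  }

  # Exact pruning: text similarities are at most 1, so an optimistic score
  # bound filters candidates before any Jaro-Winkler work. Adding weight at
  # similarity 1 can only raise a weighted mean, so the bound also covers
  # records whose text fields are missing (their weight is redistributed).
  w_text <- sum(vapply(texts, function(f) w[[f$name]], numeric(1)))
  live <- seq_along(cand)
  if (min_score > 0 && length(cheap)) {
    bound <- (ssum + w_text) / (wsum + w_text)
    bound[wsum == 0] <- 1
    live <- which(bound >= min_score)
    if (!length(live)) return(empty)
  }

  text_sims <- list()
  for (f in texts) {
    col <- s$tab[[paste0("norm.", f$name)]][cand[live]]
    sim <- jw_vec_cpp(col, norm[[f$name]])
    text_sims[[f$name]] <- sim
    ok <- !is.na(sim)
    ssum[live][ok] <- ssum[live][ok] + sim[ok] * w[[f$name]]
    wsum[live][ok] <- wsum[live][ok] + w[[f$name]]
  }
  score <- ifelse(wsum[live] > 0, ssum[live] / wsum[live], NA_real_)
  keep <- !is.na(score) & score >= min_score
  kept <- live[keep]
  sims <- empty$sims
  if (want_sims && length(kept)) {
    sims <- matrix(NA_real_, nrow = length(kept), ncol = length(nms),
                   dimnames = list(NULL, nms))
    for (f in names(cheap_sims)) sims[, f] <- cheap_sims[[f]][kept]
    for (f in names(text_sims)) sims[, f] <- text_sims[[f]][keep]
  }
  list(idx = cand[kept], score = score[keep], sims = sims)
}

# Lenient normalization for search queries: invalid components become NA
# instead of raising, and wildcard patterns pass through untouched.
normalize_query <- function(query, schema) {
  out <- list()
  for (f in schema$fields) {
    v <- query[[f$name]]
    if (is.null(v) || length(v) == 0L || is.na(v) || !nzchar(trimws(as.character(v)))) {
      out[[f$name]] <- NA_character_
      next
    }
    v <- as.character(v)
    if (grepl("[*?]", v)) {
      out[[f$name]] <- normalize_text(v)   # keeps * and ? intact
    } else {
      out[[f$name]] <- switch(f$kind,
        text = normalize_text(v),
        date = normalize_date(v),
        enum = {
          canon <- toupper(trimws(f$enum_values))
          hit <- match(toupper(trimws(v)), canon)
          if (is.na(hit)) NA_character_ else f$enum_values[hit]
        })
    }
  }
  out
}

identity_digest <- function(norm, schema) {
  vals <- vapply(schema_field_names(schema), function(f) {
    v <- norm[[f]]
    if (is.null(v) || is.na(v)) "" else v
  }, character(1))
  paste(vals, collapse = "\x1f")
}

# Translate study-nurse wildcards (`*` any run, `?` one character) into an
# anchored regular expression, escaping every other character literally.
wildcard_regex <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  body <- vapply(chars, function(ch) {
    if (ch == "*") ".*"
    else if (ch == "?") "."
    else if (grepl("[A-Za-z0-9 '-]", ch)) ch
    else paste0("\\", ch)
  }, character(1), USE.NAMES = FALSE)
  paste0("^", paste(body, collapse = ""), "$")
}

#' Search the registry for matching subjects
#'
#' The mandatory first step of any registration. Wildcard mode matches `*`
#' (any run) and `?` (one character) on normalized values; fuzzy mode ranks
#' blocked candidates by weighted Jaro-Winkler / date / enum similarity and
#' keeps those at or above the review threshold; combined mode returns the
#' union. Results are ranked by score descending, then pseudonym ascending.
#' Blocking is an optimization only: for the duplicate classes the typo
#' model generates, the result set equals a brute-force scan.
#'
#' The returned object doubles as the *search proof* that
#' [register_subject()] demands: it records the registry revision and a
#' digest of the queried identity.
#'
#' @param registry a registry handle.
#' @param query named list of field values; at least one non-empty field.
#'   Values may contain `*`/`?` wildcards (wildcard fields are excluded
#'   from fuzzy scoring).
#' @param mode `"combined"` (default), `"wildcard"` or `"fuzzy"`.
#' @return data frame of candidates with columns `subject_pseudonym`,
#'   `score`, `classification` and one `sim_<field>` column per schema
#'   field, plus the stored raw identity columns for review.
#' @export
search_subjects <- function(registry, query,
                            mode = c("combined", "wildcard", "fuzzy")) {
  mode <- match.arg(mode)
  schema <- registry$config$identity_schema
  query <- as.list(query)
  nonempty <- Filter(function(v) !is.null(v) && length(v) && !is.na(v) &&
                       nzchar(trimws(as.character(v))), query)
  if (!length(nonempty)) {
    psn_stop("pseudoreg_empty_query", "search query needs at least one non-empty field")
  }
  nq <- normalize_query(query, schema)
  s <- registry$state$subj
  nms <- schema_field_names(schema)
  is_wild <- vapply(nms, function(f) !is.na(nq[[f]]) && grepl("[*?]", nq[[f]]),
                    logical(1))

  wild_idx <- integer(0)
  if (mode %in% c("wildcard", "combined")) {
    queried <- nms[vapply(nms, function(f) !is.na(nq[[f]]), logical(1))]
    if (length(queried) && s$n > 0L) {
      keep <- rep(TRUE, s$n)
      for (f in queried) {
        col <- s$tab[[paste0("norm.", f)]][seq_len(s$n)]
        if (is_wild[[f]]) {
          keep <- keep & !is.na(col) & grepl(wildcard_regex(nq[[f]]), col)
        } else {
          keep <- keep & !is.na(col) & col == nq[[f]]
        }
      }
      wild_idx <- which(keep)
      registry$state$comparisons <- registry$state$comparisons + s$n
    }
  }

  fuzzy <- list(idx = integer(0), score = numeric(0),
                sims = matrix(numeric(0), 0, length(nms), dimnames = list(NULL, nms)))
  literal_nq <- nq
  for (f in nms[is_wild]) literal_nq[[f]] <- NA_character_
  has_literal <- any(vapply(nms, function(f) !is.na(literal_nq[[f]]), logical(1)))
  if (mode %in% c("fuzzy", "combined")) {
    if (mode == "fuzzy" && !has_literal) {
      psn_stop("pseudoreg_empty_query",
               "fuzzy search needs at least one literal (non-wildcard) field")
    }
    if (has_literal) {
      fuzzy <- linkage_scan(registry, literal_nq,
                            min_score = registry$config$review_threshold)
    }
  }

  idx <- switch(mode,
    wildcard = wild_idx,
    fuzzy = fuzzy$idx,
    combined = union(wild_idx, fuzzy$idx))

  score <- rep(0, length(idx))
  sims <- matrix(NA_real_, nrow = length(idx), ncol = length(nms),
                 dimnames = list(NULL, nms))
  if (length(idx) && has_literal) {
    rescored <- score_indices(registry, literal_nq, idx)
    score <- rescored$score
    sims <- rescored$sims
  }
  ord <- order(-score, s$tab$psn[idx])
  idx <- idx[ord]; score <- score[ord]; sims <- sims[ord, , drop = FALSE]

  out <- data.frame(subject_pseudonym = s$tab$psn[idx], score = score,
                    classification = classify_match(
                      score, c(registry$config$block_threshold,
                               registry$config$review_threshold)),
                    stringsAsFactors = FALSE)
  colnames(sims) <- paste0("sim_", nms)
  out <- cbind(out, as.data.frame(sims))
  for (f in nms) out[[f]] <- s$tab[[paste0("raw.", f)]][idx]
  attr(out, "revision") <- registry$revision
  attr(out, "identity_digest") <- identity_digest(nq, schema)
  attr(out, "mode") <- mode
  class(out) <- c("pseudoreg_match_result", "data.frame")
  out
}

# Score a fixed set of row indices against a normalized query (no blocking).
score_indices <- function(reg, norm, idx) {
  s <- reg$state$subj
  schema <- reg$config$identity_schema
  w <- schema_weights(schema)
  nms <- schema_field_names(schema)
  sims <- matrix(NA_real_, nrow = length(idx), ncol = length(nms),
                 dimnames = list(NULL, nms))
  ssum <- numeric(length(idx)); wsum <- numeric(length(idx))
  for (f in schema$fields) {
    qv <- norm[[f$name]]
    if (is.null(qv) || is.na(qv)) next
    if (f$kind == "date") {
      q3 <- date_query_components(qv)
      sim <- date_sim_components(
        q3[1], q3[2], q3[3],
        s$tab[[paste0("dc.", f$name, ".y")]][idx],
        s$tab[[paste0("dc.", f$name, ".m")]][idx],
        s$tab[[paste0("dc.", f$name, ".d")]][idx])
    } else {
      col <- s$tab[[paste0("norm.", f$name)]][idx]
      sim <- switch(f$kind,
        text = jw_vec_cpp(col, qv),
        enum = as.numeric(!is.na(col) & col == qv))
      sim[is.na(col)] <- NA_real_
    }
    sims[, f$name] <- sim
    ok <- !is.na(sim)
    ssum[ok] <- ssum[ok] + sim[ok] * w[[f$name]]
    wsum[ok] <- wsum[ok] + w[[f$name]]
  }
  list(score = ifelse(wsum > 0, ssum / wsum, 0), sims = sims)
}

#' Register a new study subject
#'
#' Refuses to run without a fresh search over the same identity
#' (`search_proof`), mirroring the workflow in which the duplicate search is
#' the mandatory first step of every registration. A proof containing an
#' `exact_block` candidate always blocks; `review` candidates block unless
#' `override_review = TRUE`, in which case the override is recorded in the
#' audit log.
#'
#' @param registry a registry handle in write mode.
#' @param identity named list of raw identity values.
#' @param search_proof the return value of a prior [search_subjects()] call
#'   for this identity against the current registry state.
#' @param override_review register despite `review`-class candidates.
#' @param actor identifier recorded in the audit log.
#' @param extra_properties optional named list of site-specific,
#'   non-clinical properties.
#' @return the new subject record as a list (class `subject_record`).
#' @export
register_subject <- function(registry, identity, search_proof,
                             override_review = FALSE, actor = "unknown",
                             extra_properties = list()) {
  assert_writable(registry)
  schema <- registry$config$identity_schema
  norm <- normalize_identity(identity, schema)

  if (missing(search_proof) || is.null(search_proof) ||
      !inherits(search_proof, "pseudoreg_match_result")) {
    psn_stop("pseudoreg_missing_search",
             "registration requires a prior search_subjects() result for this identity")
  }
  if (!identical(attr(search_proof, "identity_digest"),
                 identity_digest(norm, schema))) {
    psn_stop("pseudoreg_missing_search",
             "search_proof was produced for a different identity")
  }
  if (!identical(attr(search_proof, "revision"), registry$revision)) {
    psn_stop("pseudoreg_stale_search",
             "registry changed since the search; repeat the search")
  }

  qc <- quality_check(identity, schema)
  if (any(qc$severity == "error")) {
    psn_stop("pseudoreg_quality_error",
             paste0("identity fails data-quality checks:\n",
                    paste0("  - ", qc$field[qc$severity == "error"], ": ",
                           qc$message[qc$severity == "error"], collapse = "\n")),
             issues = qc)
  }

  cls <- search_proof$classification
  if (any(cls == "exact_block")) {
    hit <- search_proof$subject_pseudonym[cls == "exact_block"][1]
    psn_stop("pseudoreg_duplicate_blocked",
             paste0("identity matches registered subject ", hit,
                    " (score >= block threshold)"),
             matched_pseudonym = hit)
  }
  reviews <- search_proof$subject_pseudonym[cls == "review"]
  if (length(reviews) && !isTRUE(override_review)) {
    psn_stop("pseudoreg_review_required",
             paste0("possible duplicate(s) need review: ",
                    paste(reviews, collapse = ", "),
                    "; pass override_review = TRUE to register anyway"),
             matched_pseudonyms = reviews)
  }

  psn <- generate_pseudonym(registry$config$subject_format,
                            existing_pseudonym_set(registry), n = 1L)
  now <- utc_now()
  subj_insert(registry, psn, as.list(identity), norm, extra_properties, now, actor)
  note <- if (length(reviews)) paste0("override_review over ",
                                      paste(reviews, collapse = ",")) else ""
  audit_add(registry, actor, "register_subject", psn, note)
  structure(list(pseudonym = psn, identity = as.list(identity),
                 extra_properties = extra_properties,
                 registered_at = now, registered_by = actor),
            class = "subject_record")
}

visit_definition <- function(config, visit_id) {
  for (v in config$schedule) if (identical(v$visit_id, visit_id)) return(v)
  NULL
}

sample_type_label <- function(config, code) {
  for (s in config$sample_types) if (identical(s$code, code)) return(s$label)
  NULL
}

#' Register biosample aliquots for a subject
#'
#' Creates `n_aliquots` biosample records, each with its own pseudonym,
#' linked to an existing subject at a scheduled visit. The subject's
#' existence and the visit/sample-type combination are checked first.
#'
#' @param registry a registry handle in write mode.
#' @param subject_pseudonym pseudonym of the owning subject.
#' @param visit_id visit code from the study schedule.
#' @param sample_type sample type code; must be allowed at the visit.
#' @param n_aliquots number of aliquots collected (one pseudonym each).
#' @param attributes optional named list of sample attributes (SDAT).
#' @param actor identifier recorded in the audit log.
#' @return list of biosample records (each of class `biosample_record`).
#' @export
register_biosamples <- function(registry, subject_pseudonym, visit_id,
                                sample_type, n_aliquots = 1L,
                                attributes = list(), actor = "unknown") {
  assert_writable(registry)
  stopifnot(is_count(n_aliquots))
  if (is.na(subject_lookup(registry, subject_pseudonym))) {
    psn_stop("pseudoreg_unknown_subject",
             paste0("no registered subject with pseudonym ", subject_pseudonym))
  }
  v <- visit_definition(registry$config, visit_id)
  if (is.null(v)) {
    psn_stop("pseudoreg_schedule_violation",
             paste0("unknown visit '", visit_id, "'; scheduled visits: ",
                    paste(vapply(registry$config$schedule, `[[`, character(1),
                                 "visit_id"), collapse = ", ")))
  }
  if (!sample_type %in% v$allowed_sample_types) {
    psn_stop("pseudoreg_schedule_violation",
             paste0("sample type '", sample_type, "' is not allowed at visit '",
                    visit_id, "'; allowed: ",
                    paste(v$allowed_sample_types, collapse = ", ")))
  }
  psns <- generate_pseudonym(registry$config$biosample_format,
                             existing_pseudonym_set(registry), n = n_aliquots)
  now <- utc_now()
  out <- vector("list", n_aliquots)
  for (k in seq_len(n_aliquots)) {
    bios_insert(registry, psns[k], subject_pseudonym, visit_id, sample_type,
                k, attributes, now, actor)
    audit_add(registry, actor, "register_biosample", psns[k],
              paste0("subject=", subject_pseudonym, " visit=", visit_id,
                     " type=", sample_type, " aliquot=", k))
    out[[k]] <- structure(
      list(pseudonym = psns[k], subject_pseudonym = subject_pseudonym,
           visit_id = visit_id, sample_type = sample_type, aliquot_index = k,
           attributes = attributes, registered_at = now, registered_by = actor),
      class = "biosample_record")
  }
  out
}

#' Look up the record behind a pseudonym (depseudonymization)
#'
#' Reidentification is the sensitive operation of a pseudonymization
#' registry: every call, successful or not, appends an audit entry. A value
#' that is structurally well-formed but fails its check character is
#' reported as a suspected transcription error, distinctly from a plain
#' not-found, because a mistyped character is the far more likely cause.
#'
#' @param registry a registry handle.
#' @param pseudonym_value the pseudonym to resolve (subject or biosample
#'   scope).
#' @param actor identifier recorded in the audit log.
#' @return for a subject pseudonym, a `subject_record`; for a biosample
#'   pseudonym, a `biosample_record` whose `subject_pseudonym` names the
#'   owning subject.
#' @export
depseudonymize <- function(registry, pseudonym_value, actor = "unknown") {
  s <- registry$state$subj
  i <- subject_lookup(registry, pseudonym_value)
  if (!is.na(i)) {
    audit_add(registry, actor, "depseudonymize", pseudonym_value, "subject")
    schema <- registry$config$identity_schema
    identity <- lapply(schema_field_names(schema),
                       function(f) s$tab[[paste0("raw.", f)]][i])
    names(identity) <- schema_field_names(schema)
    extra <- s$tab$extra[[i]]
    return(structure(list(pseudonym = pseudonym_value, identity = identity,
                          extra_properties = if (is.null(extra)) list() else extra,
                          registered_at = s$tab$reg_at[i],
                          registered_by = s$tab$reg_by[i]),
                     class = "subject_record"))
  }
  b <- registry$state$bios
  j <- b$index[[pseudonym_value]]
  if (!is.null(j)) {
    audit_add(registry, actor, "depseudonymize", pseudonym_value, "biosample")
    attrs <- b$tab$extra[[j]]
    return(structure(list(pseudonym = pseudonym_value,
                          subject_pseudonym = b$tab$subject_psn[j],
                          visit_id = b$tab$visit_id[j],
                          sample_type = b$tab$sample_type[j],
                          aliquot_index = as.integer(b$tab$aliquot_index[j]),
                          attributes = if (is.null(attrs)) list() else attrs,
                          registered_at = b$tab$reg_at[j],
                          registered_by = b$tab$reg_by[j]),
                     class = "biosample_record"))
  }
  audit_add(registry, actor, "depseudonymize", pseudonym_value, "not_found")
  for (fmt in list(registry$config$subject_format, registry$config$biosample_format)) {
    vr <- validate_pseudonym(pseudonym_value, fmt)
    if (vr$check_mismatch) {
      psn_stop("pseudoreg_transcription_suspected",
               paste0(pseudonym_value, ": check character mismatch - likely a ",
                      "transcription error; re-read the identifier"))
    }
  }
  psn_stop("pseudoreg_not_found",
           paste0("no record with pseudonym ", pseudonym_value))
}

#' Registry statistics
#'
#' All counts are recomputed from the record collections by full scan, so a
#' statistics report is always exactly consistent with the stored data.
#'
#' @param registry a registry handle.
#' @return a list (class `pseudoreg_stats`) with totals, per-visit and
#'   per-sample-type pseudonym counts, and cumulative monthly registration
#'   series for subjects and biosamples.
#' @export
registry_statistics <- function(registry) {
  s <- registry$state$subj; b <- registry$state$bios
  vids <- vapply(registry$config$schedule, `[[`, character(1), "visit_id")
  stypes <- vapply(registry$config$sample_types, `[[`, character(1), "code")
  per_visit <- stats::setNames(integer(length(vids)), vids)
  per_type <- stats::setNames(integer(length(stypes)), stypes)
  if (b$n > 0L) {
    tv <- table(factor(b$tab$visit_id[seq_len(b$n)], levels = vids))
    per_visit[names(tv)] <- as.integer(tv)
    tt <- table(factor(b$tab$sample_type[seq_len(b$n)], levels = stypes))
    per_type[names(tt)] <- as.integer(tt)
  }
  monthly_cum <- function(ts) {
    if (!length(ts)) {
      return(data.frame(month = character(0), cumulative = integer(0),
                        stringsAsFactors = FALSE))
    }
    mo <- sort(substr(ts, 1, 7))
    tab <- table(mo)
    data.frame(month = names(tab), cumulative = cumsum(as.integer(tab)),
               stringsAsFactors = FALSE)
  }
  structure(list(
    subjects_total = s$n,
    biosamples_total = b$n,
    per_visit = per_visit,
    per_sample_type = per_type,
    subjects_monthly = monthly_cum(s$tab$reg_at[seq_len(s$n)]),
    biosamples_monthly = monthly_cum(b$tab$reg_at[seq_len(b$n)])
  ), class = "pseudoreg_stats")
}

#' @export
print.pseudoreg_stats <- function(x, ...) {
  cat("Registry statistics\n")
  cat(sprintf("  subjects:   %d\n  biosamples: %d\n",
              x$subjects_total, x$biosamples_total))
  if (length(x$per_visit)) {
    cat("  biosamples per visit:  ",
        paste(names(x$per_visit), x$per_visit, sep = "=", collapse = "  "), "\n")
  }
  if (length(x$per_sample_type)) {
    cat("  biosamples per type:   ",
        paste(names(x$per_sample_type), x$per_sample_type, sep = "=",
              collapse = "  "), "\n")
  }
  invisible(x)
}

#' Is an export backup due?
#'
#' @param registry a registry handle.
#' @param now reference time.
#' @return list with `due` (logical) and `message`.
#' @export
backup_due <- function(registry, now = Sys.time()) {
  interval <- registry$config$backup_interval_days
  if (is.null(registry$last_backup_at)) {
    return(list(due = TRUE,
                message = "no backup recorded yet - export a backup now"))
  }
  last <- as.POSIXct(registry$last_backup_at, format = "%Y-%m-%dT%H:%M:%S%z",
                     tz = "UTC")
  age_days <- as.numeric(difftime(now, last, units = "days"))
  if (age_days >= interval) {
    list(due = TRUE,
         message = sprintf("last backup %.1f days ago (interval: %d day%s) - export a backup",
                           age_days, interval, if (interval > 1) "s" else ""))
  } else {
    list(due = FALSE, message = sprintf("last backup %.1f days ago", age_days))
  }
}

#' Candidate-comparison counters
#'
#' Every fuzzy linkage scan adds the number of scanned candidates, and every
#' wildcard scan adds the registry size, to an internal counter. Scaling
#' properties are asserted on these counts rather than on wall-clock time.
#'
#' @param registry a registry handle.
#' @return `comparison_count()`: the current count. `reset_comparison_count()`:
#'   the previous count, invisibly.
#' @export
comparison_count <- function(registry) registry$state$comparisons

#' @rdname comparison_count
#' @export
reset_comparison_count <- function(registry) {
  old <- registry$state$comparisons
  registry$state$comparisons <- 0
  invisible(old)
}
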