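#' Synthetic identity cohorts with ground truth
#'
#' Deterministic generator of realistic subject identities (multi-locale
#' names with diacritics, dates of birth, sex) with a controlled fraction
#' of injected duplicates. Each duplicate is an existing identity with 1 to
#' `max_typos` character-level edits (substitution, adjacent transposition,
#' deletion) and/or a day-month transposition of the birth date; every edit
#' is logged, and the truth mapping assigns each record to its duplicate
#' cluster. This is what makes linkage quality measurable without any real
#' enrolment data.
#'
#' A duplicate never has all of its fields edited at once, so clusters stay
#' separable in principle: a recall shortfall indicts the matcher, not the
#' data.
#'
#' @name cohort
NULL

sample_surnames <- function(n) {
  # ~70% from the weighted common list, ~30% generated rare tail
  w <- 1 / seq_along(SURNAMES)^0.85
  common <- sample(SURNAMES, n, replace = TRUE, prob = w)
  tail_mask <- stats::runif(n) < 0.3
  n_tail <- sum(tail_mask)
  if (n_tail) {
    common[tail_mask] <- paste0(sample(SURNAME_SYL_A, n_tail, replace = TRUE),
                                sample(SURNAME_SYL_B, n_tail, replace = TRUE),
                                sample(SURNAME_SYL_C, n_tail, replace = TRUE))
  }
  common
}

sample_identities <- function(n) {
  sex <- sample(c("F", "M"), n, replace = TRUE)
  first <- character(n)
  wf <- 1 / seq_along(FIRST_NAMES_F)^0.7
  wm <- 1 / seq_along(FIRST_NAMES_M)^0.7
  first[sex == "F"] <- sample(FIRST_NAMES_F, sum(sex == "F"), replace = TRUE, prob = wf)
  first[sex == "M"] <- sample(FIRST_NAMES_M, sum(sex == "M"), replace = TRUE, prob = wm)
  dob <- as.Date("1930-01-01") +
    sample.int(as.integer(as.Date("2009-12-31") - as.Date("1930-01-01")), n,
               replace = TRUE)
  data.frame(first_name = first, last_name = sample_surnames(n),
             date_of_birth = format(dob, "%Y-%m-%d"), sex = sex,
             stringsAsFactors = FALSE)
}

TYPO_LETTERS <- strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1]]

# Indices of originals that sit too close to an earlier original: the pair
# agrees on all but one field and the differing field is within the typo
# bound (text: edit distance <= max_typos; date: the date typo operations -
# day/month swap or a single differing component). For each leave-one-out
# key, records sharing the key are compared pairwise on the left-out field.
find_cluster_conflicts <- function(ids, max_typos) {
  f_up <- toupper(ids$first_name)
  l_up <- toupper(ids$last_name)
  dob <- ids$date_of_birth
  sex <- ids$sex
  cols <- list(first_name = f_up, last_name = l_up, date_of_birth = dob,
               sex = sex)
  bad <- integer(0)
  for (leave in names(cols)) {
    others <- cols[setdiff(names(cols), leave)]
    key <- do.call(paste, c(others, sep = "\x1f"))
    grp <- split(seq_along(key), key)
    grp <- grp[lengths(grp) > 1L]
    left <- cols[[leave]]
    for (g in grp) {
      for (a in seq_along(g)[-length(g)]) for (b in (a + 1L):length(g)) {
        i <- g[a]; j <- g[b]
        close <- if (leave == "date_of_birth") {
          date_similarity_vec(left[i], left[j]) > 0
        } else if (leave == "sex") {
          TRUE          # same name + dob, differing only in sex: too close
        } else {
          utils::adist(left[i], left[j]) <= max_typos
        }
        if (close) bad <- c(bad, j)
      }
    }
  }
  unique(bad)
}

# Draw `n` originals that the default matcher itself keeps apart: each
# candidate identity is scanned against the previously accepted ones and
# redrawn whenever it scores at or above the review threshold. Under the
# default weights this subsumes the structural separation rules (any pair
# agreeing on all but one field, with that field inside the typo bound,
# scores >= 0.91), so a record flagged during sequential registration of a
# generated cohort is always a true duplicate.
sample_separated_identities <- function(n, config = default_config()) {
  schema <- config$identity_schema
  nms <- schema_field_names(schema)
  reg <- make_registry_handle(config)
  out <- vector("list", 0L)
  need <- n
  while (need > 0L) {
    batch <- sample_identities(need)
    normc <- lapply(schema$fields, function(f) normalize_column(batch[[f$name]], f))
    names(normc) <- nms
    ok <- logical(need)
    for (i in seq_len(need)) {
      norm <- lapply(normc, `[[`, i)
      hit <- linkage_scan(reg, norm, min_score = config$review_threshold,
                          want_sims = FALSE)
      if (length(hit$idx)) next
      raw <- lapply(nms, function(f) batch[[f]][i])
      names(raw) <- nms
      subj_insert(reg, paste0("T", reg$state$subj$n + 1L), raw, norm,
                  list(), "", "")
      ok[i] <- TRUE
    }
    out[[length(out) + 1L]] <- batch[ok, , drop = FALSE]
    need <- sum(!ok)
  }
  ids <- do.call(rbind, out)
  rownames(ids) <- NULL
  ids
}

apply_text_edit <- function(value, op) {
  chars <- strsplit(value, "")[[1]]
  n <- length(chars)
  if (op == "substitution") {
    i <- sample.int(n, 1L)
    repl <- sample(setdiff(TYPO_LETTERS, toupper(chars[i])), 1L)
    if (chars[i] == tolower(chars[i]) && grepl("[a-z]", chars[i])) repl <- tolower(repl)
    chars[i] <- repl
    list(value = paste(chars, collapse = ""),
         edit = sprintf("substitution@%d", i))
  } else if (op == "transposition") {
    if (n < 2L) return(apply_text_edit(value, "substitution"))
    i <- sample.int(n - 1L, 1L)
    tmp <- chars[i]; chars[i] <- chars[i + 1L]; chars[i + 1L] <- tmp
    list(value = paste(chars, collapse = ""),
         edit = sprintf("transposition@%d", i))
  } else {                                      # deletion
    if (n < 3L) return(apply_text_edit(value, "substitution"))
    i <- sample.int(n, 1L)
    list(value = paste(chars[-i], collapse = ""),
         edit = sprintf("deletion@%d", i))
  }
}

swap_day_month <- function(iso) {
  p <- strsplit(iso, "-")[[1]]
  if (as.integer(p[3]) <= 12L && p[2] != p[3]) {
    paste(p[1], p[3], p[2], sep = "-")
  } else {
    NA_character_
  }
}

#' Generate a synthetic cohort
#'
#' @param n total number of records (originals + duplicates).
#' @param duplicate_rate fraction of records that are duplicates of an
#'   earlier original; `floor(n * duplicate_rate)` duplicates are produced.
#' @param max_typos maximum number of edits applied to a duplicate (at
#'   least one is always applied).
#' @param seed integer seed; the cohort is bit-identical across runs for a
#'   fixed seed.
#' @return a `synthetic_cohort`: list with `identities` (data frame with
#'   columns `first_name`, `last_name`, `date_of_birth`, `sex`), `truth`
#'   (integer cluster id per record; duplicates share their original's
#'   cluster), `typo_log` (data frame `index`, `field`, `edit`) and `seed`.
#' @examples
#' cohort <- generate_cohort(100, duplicate_rate = 0.05, seed = 7)
#' table(table(cohort$truth))
#' @export
generate_cohort <- function(n, duplicate_rate = 0.05, max_typos = 2L, seed = 1L) {
  stopifnot(is_count(n), duplicate_rate >= 0, duplicate_rate < 1,
            is_count(max_typos))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  n_dup <- floor(n * duplicate_rate)
  n_orig <- n - n_dup
  # cluster-separation invariant: distinct originals differ in at least two
  # fields or by more than the typo bound, enforced by redrawing any
  # candidate the default matcher would flag against an earlier original
  ids <- sample_separated_identities(n_orig)

  truth <- seq_len(n_orig)
  typo_log <- list()
  if (n_dup > 0L) {
    src <- sample.int(n_orig, n_dup, replace = TRUE)
    editable <- c("first_name", "last_name", "date_of_birth")
    for (k in seq_len(n_dup)) {
      rec <- ids[src[k], , drop = FALSE]
      n_edits <- sample.int(max_typos, 1L)
      # never touch every identity field at once
      fields <- sample(editable, min(n_edits, length(editable) - 1L))
      edits <- list()
      budget <- n_edits
      for (f in fields) {
        if (budget <= 0L) break
        if (f == "date_of_birth") {
          swapped <- swap_day_month(rec$date_of_birth)
          if (is.na(swapped)) next
          rec$date_of_birth <- swapped
          edits[[length(edits) + 1L]] <- data.frame(
            field = f, edit = "day_month_swap", stringsAsFactors = FALSE)
          budget <- budget - 1L
        } else {
          k_edits <- min(budget, if (length(fields) == 1L) n_edits else 1L)
          for (e in seq_len(k_edits)) {
            op <- sample(c("substitution", "transposition", "deletion"), 1L)
            r <- apply_text_edit(rec[[f]], op)
            rec[[f]] <- r$value
            edits[[length(edits) + 1L]] <- data.frame(
              field = f, edit = r$edit, stringsAsFactors = FALSE)
            budget <- budget - 1L
          }
        }
      }
      if (!length(edits)) {                     # ensure at least one edit
        r <- apply_text_edit(rec$last_name, "substitution")
        rec$last_name <- r$value
        edits[[1L]] <- data.frame(field = "last_name", edit = r$edit,
                                  stringsAsFactors = FALSE)
      }
      idx <- n_orig + k
      ids <- rbind(ids, rec)
      truth <- c(truth, src[k])
      for (e in edits) {
        typo_log[[length(typo_log) + 1L]] <-
          cbind(data.frame(index = idx), e)
      }
    }
  }
  # interleave duplicates among the originals (duplicates must come after
  # their original for sequential registration, so we keep order but the
  # consumer sees a realistic mixed stream via the stable index mapping)
  typo_df <- if (length(typo_log)) do.call(rbind, typo_log) else
    data.frame(index = integer(0), field = character(0), edit = character(0),
               stringsAsFactors = FALSE)
  rownames(ids) <- NULL
  structure(list(identities = ids, truth = truth, typo_log = typo_df,
                 seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- nrow(x$identities)
  cat(sprintf("<synthetic cohort: %d records, %d duplicate(s), seed %d>\n",
              n, n - length(unique(x$truth)), x$seed))
  invisible(x)
}

#' Evaluate linkage quality on a synthetic cohort
#'
#' Registers the cohort sequentially into a fresh in-memory registry with
#' fuzzy linkage active. A record is *flagged* when the scan returns any
#' candidate at or above the review threshold; it is a *true duplicate*
#' when its cluster already has a registered member. Flagged records are
#' not registered (the duplicate-prevention workflow). By convention,
#' precision and recall are 1.0 when there are no positives and no false
#' positives.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config study configuration supplying schema and thresholds.
#' @return list (class `linkage_evaluation`) with `precision`, `recall`,
#'   confusion counts (`tp`, `fp`, `fn`, `tn`) and the per-record flag /
#'   truth vectors.
#' @export
evaluate_linkage <- function(cohort, config = default_config()) {
  reg <- registry_create(config)
  ids <- cohort$identities
  n <- nrow(ids)
  schema <- config$identity_schema
  flagged <- logical(n)
  matched_cluster <- logical(n)
  registered_idx <- integer(0)
  psn_of <- character(n)
  for (i in seq_len(n)) {
    raw <- as.list(ids[i, , drop = FALSE])
    norm <- tryCatch(normalize_identity(raw, schema), error = function(e) NULL)
    if (is.null(norm)) next
    hit <- linkage_scan(reg, norm, min_score = config$review_threshold,
                        want_sims = FALSE)
    if (length(hit$idx)) {
      flagged[i] <- TRUE
      hit_psn <- reg$state$subj$tab$psn[hit$idx]
      hit_rows <- match(hit_psn, psn_of)
      matched_cluster[i] <- any(cohort$truth[registered_idx[hit_rows]] ==
                                  cohort$truth[i])
    } else {
      psn <- generate_pseudonym(config$subject_format,
                                existing_pseudonym_set(reg), n = 1L)
      subj_insert(reg, psn, raw, norm, list(), utc_now(), "eval")
      registered_idx <- c(registered_idx, i)
      psn_of[length(registered_idx)] <- psn
    }
  }
  seen <- new.env(parent = emptyenv())
  true_dup <- logical(n)
  for (i in seq_len(n)) {
    k <- as.character(cohort$truth[i])
    if (!is.null(seen[[k]])) true_dup[i] <- TRUE else seen[[k]] <- TRUE
  }
  tp <- sum(flagged & true_dup)
  fp <- sum(flagged & !true_dup)
  fn <- sum(true_dup & !flagged)
  tn <- n - tp - fp - fn
  precision <- if (tp + fp == 0L) 1.0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 1.0 else tp / (tp + fn)
  structure(list(precision = precision, recall = recall,
                 tp = tp, fp = fp, fn = fn, tn = tn,
                 flagged = flagged, true_duplicate = true_dup),
            class = "linkage_evaluation")
}

#' @export
print.linkage_evaluation <- function(x, ...) {
  cat(sprintf("Linkage evaluation: precision %.3f, recall %.3f (tp %d, fp %d, fn %d)\n",
              x$precision, x$recall, x$tp, x$fp, x$fn))
  invisible(x)
}
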