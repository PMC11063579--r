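# Independent oracles, implemented without reference to the package's own
# code paths.

# Jaro-Winkler, direct textbook formulation in plain R (the package uses a
# separate C++ implementation).
ref_jaro_winkler <- function(a, b) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  la <- length(sa); lb <- length(sb)
  if (la == 0 && lb == 0) return(1)
  if (la == 0 || lb == 0) return(0)
  win <- max(floor(max(la, lb) / 2) - 1, 0)
  ma <- logical(la); mb <- logical(lb)
  for (i in seq_len(la)) {
    lo <- max(1, i - win); hi <- min(lb, i + win)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!mb[j] && sa[i] == sb[j]) { ma[i] <- TRUE; mb[j] <- TRUE; break }
    }
  }
  m <- sum(ma)
  if (m == 0) return(0)
  t <- sum(sa[ma] != sb[mb]) / 2
  jaro <- mean(c(m / la, m / lb, (m - t) / m))
  l <- 0
  while (l < min(4, la, lb) && sa[l + 1] == sb[l + 1]) l <- l + 1
  jaro + l * 0.1 * (1 - jaro)
}

# ISO 7064 MOD 37-2 via the polynomial definition: a string a_1..a_n is a
# valid codeword iff sum_i a_i * 2^(n-i+1) == 1 (mod 37). The check
# character is found by brute force over the 37-character set.
ref_iso_chars <- strsplit("0123456789ABCDEFGHIJKLMNOPQRSTUVWXYZ*", "")[[1]]

ref_iso_valid <- function(s) {
  a <- match(strsplit(s, "")[[1]], ref_iso_chars) - 1L
  n <- length(a)
  pow <- vapply(seq_len(n), function(i) {
    p <- 1L
    for (k in seq_len(n - i + 1L)) p <- (p * 2L) %% 37L
    p
  }, integer(1))
  sum(a * pow) %% 37L == 1L
}

ref_iso_check <- function(body) {
  for (ch in ref_iso_chars) {
    if (ref_iso_valid(paste0(body, ch))) return(ch)
  }
  stop("no valid check character found")
}

# Brute-force search oracle: score / pattern-match every registered subject
# with scalar package primitives, no blocking, no vectorized scan.
oracle_search <- function(registry, query, mode, config) {
  schema <- config$identity_schema
  s <- registry$state$subj
  n <- s$n
  if (n == 0) return(character(0))
  nq <- pseudoreg:::normalize_query(query, schema)
  nms <- vapply(schema$fields, `[[`, character(1), "name")
  queried <- nms[vapply(nms, function(f) !is.na(nq[[f]]), logical(1))]
  is_wild <- vapply(nms, function(f) !is.na(nq[[f]]) && grepl("[*?]", nq[[f]]),
                    logical(1))
  names(is_wild) <- nms
  w <- vapply(schema$fields, `[[`, numeric(1), "weight")
  names(w) <- nms

  wild_hits <- logical(n)
  if (mode %in% c("wildcard", "combined") && length(queried)) {
    for (i in seq_len(n)) {
      ok <- TRUE
      for (f in queried) {
        v <- s$tab[[paste0("norm.", f)]][i]
        if (is.na(v)) { ok <- FALSE; break }
        if (is_wild[[f]]) {
          pat <- glob2rx(nq[[f]])
          if (!grepl(pat, v)) { ok <- FALSE; break }
        } else if (v != nq[[f]]) { ok <- FALSE; break }
      }
      wild_hits[i] <- ok
    }
  }
  fuzzy_hits <- logical(n)
  literal <- queried[!is_wild[queried]]
  if (mode %in% c("fuzzy", "combined") && length(literal)) {
    for (i in seq_len(n)) {
      sims <- numeric(0)
      for (f in literal) {
        kind <- NULL
        for (fd in schema$fields) if (fd$name == f) kind <- fd$kind
        v <- s$tab[[paste0("norm.", f)]][i]
        sims[f] <- if (is.na(v)) NA_real_ else field_similarity(nq[[f]], v, kind)
      }
      sc <- tryCatch(aggregate_score(sims, w), error = function(e) NA_real_)
      fuzzy_hits[i] <- !is.na(sc) && sc >= config$review_threshold
    }
  }
  hits <- switch(mode, wildcard = wild_hits, fuzzy = fuzzy_hits,
                 combined = wild_hits | fuzzy_hits)
  sort(s$tab$psn[which(hits)])
}
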