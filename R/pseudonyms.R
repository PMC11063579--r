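#' Pseudonym generation and validation
#'
#' A pseudonym is rendered as `PREFIX<sep>SITE<sep>BODY<sep>CHECK`, where the
#' body is drawn uniformly at random from the configured alphabet and the
#' check character is ISO 7064 MOD 37-2 over the concatenated
#' `prefix + site_code + body` (so a mistyped site code is caught too).
#' Bodies are random rather than sequential so that exported pseudonyms do
#' not leak enrolment order; generation against a set of existing values is
#' collision-free by construction and deterministic for a fixed RNG state.
#'
#' @name pseudonyms
NULL

render_pseudonym <- function(fmt, bodies) {
  parts <- paste(fmt$prefix, fmt$site_code, bodies, sep = fmt$separator)
  if (identical(fmt$check_scheme, "iso7064_mod37_2")) {
    chk <- compute_check_character_fixed(paste0(fmt$prefix, fmt$site_code, bodies))
    parts <- paste(parts, chk, sep = fmt$separator)
  }
  parts
}

random_bodies <- function(fmt, n) {
  chars <- strsplit(fmt$alphabet, "")[[1]]
  m <- matrix(sample(chars, n * fmt$body_length, replace = TRUE),
              nrow = n, ncol = fmt$body_length)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Deterministic lexicographic enumeration of all bodies, used as the
# termination guarantee when rejection sampling keeps colliding near
# capacity. Returns the first `want` free full values in alphabet order.
scan_free_values <- function(fmt, taken, want) {
  chars <- strsplit(fmt$alphabet, "")[[1]]
  k <- length(chars)
  len <- fmt$body_length
  out <- character(0)
  idx <- rep(1L, len)                 # odometer over alphabet positions
  repeat {
    body <- paste(chars[idx], collapse = "")
    val <- render_pseudonym(fmt, body)
    if (!(val %in% taken)) {
      out <- c(out, val)
      if (length(out) >= want) return(out)
    }
    j <- len
    while (j >= 1L) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= k) break
      idx[j] <- 1L
      j <- j - 1L
    }
    if (j < 1L) return(out)           # space exhausted
  }
}

#' Generate fresh pseudonyms
#'
#' Draws `n` new pseudonyms conforming to `format` that collide neither with
#' `existing` nor with each other. Uses bounded rejection sampling (64
#' rounds) and then falls back to a deterministic lexicographic scan, so the
#' function terminates even when the identifier space is nearly full and
#' raises a capacity error only when it is genuinely exhausted.
#'
#' Randomness comes from R's global RNG: call `set.seed()` beforehand for a
#' reproducible sequence.
#'
#' @param format a [pseudonym_format()].
#' @param existing character vector (or environment-backed set) of already
#'   issued full pseudonym values.
#' @param n number of pseudonyms to generate.
#' @return character vector of `n` new pseudonym values.
#' @examples
#' set.seed(1)
#' fmt <- pseudonym_format("SUB", "BER")
#' generate_pseudonym(fmt, character(0), n = 3)
#' @export
generate_pseudonym <- function(format, existing = character(0), n = 1L) {
  stopifnot(is_count(n))
  space <- format_space_size(format)
  have <- if (is.environment(existing)) length(existing) else length(existing)
  if (have >= space) {
    psn_stop("pseudoreg_capacity_error",
             sprintf("identifier space exhausted: %d values over a space of %.0f",
                     have, space))
  }
  taken_has <- if (is.environment(existing)) {
    function(v) vapply(v, function(x) !is.null(existing[[x]]), logical(1))
  } else {
    function(v) v %in% existing
  }
  out <- character(0)
  rounds <- 0L
  while (length(out) < n && rounds < 64L) {
    rounds <- rounds + 1L
    need <- n - length(out)
    cand <- render_pseudonym(format, random_bodies(format, need))
    cand <- cand[!duplicated(cand) & !taken_has(cand) & !(cand %in% out)]
    out <- c(out, cand)
  }
  if (length(out) < n) {
    taken <- if (is.environment(existing)) ls(existing, all.names = TRUE) else existing
    extra <- scan_free_values(format, c(taken, out), n - length(out))
    out <- c(out, extra)
    if (length(out) < n) {
      psn_stop("pseudoreg_capacity_error",
               sprintf("identifier space exhausted after deterministic scan (space = %.0f)",
                       space))
    }
  }
  out
}

#' Parse and validate a pseudonym value
#'
#' Total function: never raises. Structural defects (wrong prefix, site,
#' length, separator, or characters outside the alphabet) are reported
#' separately from a check-character mismatch, because the latter on an
#' otherwise well-formed value suggests a transcription error rather than a
#' foreign identifier.
#'
#' @param value pseudonym string to check.
#' @param format the [pseudonym_format()] it should conform to.
#' @return a list with `ok` (logical), `defects` (character vector, empty
#'   when ok) and `check_mismatch` (logical).
#' @export
validate_pseudonym <- function(value, format) {
  defects <- character(0)
  check_mismatch <- FALSE
  if (!is_string(value) || !nzchar(value)) {
    return(list(ok = FALSE, defects = "empty or non-string value",
                check_mismatch = FALSE))
  }
  has_check <- identical(format$check_scheme, "iso7064_mod37_2")
  parts <- strsplit(value, format$separator, fixed = TRUE)[[1]]
  want_parts <- if (has_check) 4L else 3L
  if (length(parts) != want_parts) {
    return(list(ok = FALSE,
                defects = sprintf("expected %d '%s'-separated segments, found %d",
                                  want_parts, format$separator, length(parts)),
                check_mismatch = FALSE))
  }
  if (!identical(parts[1], format$prefix)) {
    defects <- c(defects, sprintf("prefix '%s' != expected '%s'", parts[1], format$prefix))
  }
  if (!identical(parts[2], format$site_code)) {
    defects <- c(defects, sprintf("site code '%s' != expected '%s'", parts[2], format$site_code))
  }
  body <- parts[3]
  if (nchar(body) != format$body_length) {
    defects <- c(defects, sprintf("body length %d != expected %d",
                                  nchar(body), format$body_length))
  }
  alpha <- strsplit(format$alphabet, "")[[1]]
  bad <- setdiff(strsplit(body, "")[[1]], alpha)
  if (length(bad)) {
    defects <- c(defects, paste0("body characters outside alphabet: ",
                                 paste(bad, collapse = ", ")))
  }
  if (has_check) {
    chk <- parts[4]
    iso <- strsplit(ISO7064_SET, "")[[1]]
    if (nchar(chk) != 1L || !(chk %in% iso)) {
      defects <- c(defects, "check segment must be a single character from 0-9A-Z*")
    } else if (!length(defects)) {
      ok <- tryCatch(
        verify_check_character(paste0(format$prefix, format$site_code, body, chk)),
        error = function(e) FALSE
      )
      if (!ok) {
        check_mismatch <- TRUE
        defects <- c(defects, "check character mismatch (possible transcription error)")
      }
    }
  }
  list(ok = !length(defects), defects = defects, check_mismatch = check_mismatch)
}
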