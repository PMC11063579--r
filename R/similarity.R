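#' Field similarity and score aggregation
#'
#' Per-field similarities in `[0, 1]` feed a weighted arithmetic mean that
#' is the linkage score between two identity records:
#' * text: Jaro-Winkler similarity (prefix boost p = 0.1, prefix length
#'   capped at 4), computed on normalized values;
#' * date: 1.0 when equal, 0.8 when day and month are transposed or exactly
#'   one of year/month/day differs (typical transcription slips), else 0.0;
#' * enum: equality indicator.
#'
#' Fields missing in either record are excluded and their weight is
#' redistributed over the comparable fields.
#'
#' @name similarity
NULL

#' Similarity between two field values
#'
#' @param a,b normalized values (see [normalize_identity()]).
#' @param kind `"text"`, `"date"` or `"enum"`.
#' @return a similarity in `[0, 1]`; `NA` when either value is missing.
#' @examples
#' field_similarity("MARTHA", "MARHTA", "text")
#' field_similarity("1980-03-04", "1980-04-03", "date")
#' @export
field_similarity <- function(a, b, kind = c("text", "date", "enum")) {
  kind <- match.arg(kind)
  if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) return(NA_real_)
  a <- as.character(a); b <- as.character(b)
  switch(kind,
    text = jw_vec_cpp(a, b)[1],
    date = date_similarity_vec(a, b)[1],
    enum = as.numeric(identical(a, b))
  )
}

# Vectorized date comparison on canonical "YYYY-MM-DD" strings.
date_similarity_vec <- function(a, b_scalar) {
  n <- length(a)
  out <- numeric(n)
  eq <- !is.na(a) & a == b_scalar
  out[eq] <- 1
  rest <- which(!eq & !is.na(a))
  if (length(rest)) {
    pa <- date_components(a[rest])
    pb <- date_components(rep(b_scalar, length(rest)))
    swapped <- pa[, "y"] == pb[, "y"] & pa[, "m"] == pb[, "d"] & pa[, "d"] == pb[, "m"]
    ndiff <- (pa[, "y"] != pb[, "y"]) + (pa[, "m"] != pb[, "m"]) + (pa[, "d"] != pb[, "d"])
    out[rest][swapped | ndiff == 1L] <- 0.8
  }
  out[is.na(a)] <- NA_real_
  out
}

#' Aggregate per-field similarities into one linkage score
#'
#' Weighted arithmetic mean over the fields that are comparable (non-`NA`
#' similarity); the weight of missing fields is implicitly redistributed by
#' renormalizing over the comparable set.
#'
#' @param per_field named numeric vector of per-field similarities (use
#'   `NA` for fields missing in either record).
#' @param weights named non-negative weights (from the identity schema).
#' @return scalar score in `[0, 1]`.
#' @export
aggregate_score <- function(per_field, weights) {
  common <- intersect(names(per_field), names(weights))
  s <- per_field[common]
  w <- weights[common]
  keep <- !is.na(s) & w > 0
  if (!any(keep)) {
    psn_stop("pseudoreg_no_comparable_fields",
             "no comparable fields between query and record")
  }
  sum(s[keep] * w[keep]) / sum(w[keep])
}

#' Classify a linkage score against the study thresholds
#'
#' @param score linkage score in `[0, 1]`.
#' @param thresholds numeric vector `c(block, review)` with
#'   `block >= review`.
#' @return `"exact_block"`, `"review"` or `"no_match"` (vectorized over
#'   `score`).
#' @export
classify_match <- function(score, thresholds) {
  stopifnot(length(thresholds) == 2L, thresholds[1] >= thresholds[2])
  out <- rep("no_match", length(score))
  out[score >= thresholds[2]] <- "review"
  out[score >= thresholds[1]] <- "exact_block"
  out
}
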