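# Typed conditions: every user-facing failure carries a condition class so the
# CLI can map it to an exit code and tests can assert on the class, not the text.

psn_error <- function(class, message, ..., call = sys.call(-1)) {
  structure(
    class = c(class, "pseudoreg_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

psn_stop <- function(class, message, ...) {
  stop(psn_error(class, message, ...))
}

#' @keywords internal
validation_stop <- function(problems) {
  psn_stop(
    "pseudoreg_validation_error",
    paste0(
      "invalid configuration (", length(problems), " problem",
      if (length(problems) > 1L) "s" else "", "):\n",
      paste0("  - ", problems, collapse = "\n")
    ),
    problems = problems
  )
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}
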