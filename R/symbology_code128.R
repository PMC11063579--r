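# Code 128 (code set B) encoder and decoder. A symbol is a run of
# alternating bar/space widths: start B, one symbol per character, the
# modulo-103 check symbol, and the stop pattern. Character set B covers
# ASCII 32..127, which includes every pseudonym character.

CODE128_PATTERNS <- c(
  "212222", "222122", "222221", "121223", "121322", "131222", "122213",
  "122312", "132212", "221213", "221312", "231212", "112232", "122132",
  "122231", "113222", "123122", "123221", "223211", "221132", "221231",
  "213212", "223112", "312131", "311222", "321122", "321221", "312212",
  "322112", "322211", "212123", "212321", "232121", "111323", "131123",
  "131321", "112313", "132113", "132311", "211313", "231113", "231311",
  "112133", "112331", "132131", "113123", "113321", "133121", "313121",
  "211331", "231131", "213113", "213311", "213131", "311123", "311321",
  "331121", "312113", "312311", "332111", "314111", "221411", "431111",
  "111224", "111422", "121124", "121421", "141122", "141221", "112214",
  "112412", "122114", "122411", "142112", "142211", "241211", "221114",
  "413111", "241112", "134111", "111242", "121142", "121241", "114212",
  "124112", "124211", "411212", "421112", "421211", "212141", "214121",
  "412121", "111143", "111341", "131141", "114113", "114311", "411113",
  "411311", "113141", "114131", "311141", "411131", "211412", "211214",
  "211232", "2331112"
)
CODE128_START_B <- 104L
CODE128_STOP <- 106L

code128_values <- function(text) {
  codes <- utf8ToInt(text)
  if (any(codes < 32L | codes > 127L)) {
    psn_stop("pseudoreg_symbology_error",
             "Code 128 set B supports ASCII 32..127 only")
  }
  codes - 32L
}

code128_encode <- function(text) {
  if (!is_string(text) || !nzchar(text)) {
    psn_stop("pseudoreg_symbology_error", "cannot encode an empty value")
  }
  vals <- code128_values(text)
  checksum <- (CODE128_START_B +
                 sum(vals * seq_along(vals))) %% 103L
  symbols <- c(CODE128_START_B, vals, checksum, CODE128_STOP)
  widths <- as.integer(unlist(strsplit(CODE128_PATTERNS[symbols + 1L], "")))
  # widths alternate bar, space, bar, ... starting and ending with a bar
  list(widths = widths, symbols = symbols)
}

code128_decode <- function(widths) {
  widths <- as.integer(widths)
  if (length(widths) < 6L + 6L + 7L || (length(widths) - 7L) %% 6L != 0L) {
    psn_stop("pseudoreg_symbology_error", "not a Code 128 width sequence")
  }
  n_sym <- (length(widths) - 7L) %/% 6L
  lut <- stats::setNames(seq_along(CODE128_PATTERNS) - 1L, CODE128_PATTERNS)
  read_symbol <- function(w) {
    v <- lut[paste(w, collapse = "")]
    if (is.na(v)) {
      psn_stop("pseudoreg_symbology_error", "unknown Code 128 pattern")
    }
    unname(v)
  }
  symbols <- vapply(seq_len(n_sym), function(k) {
    read_symbol(widths[(k - 1L) * 6L + 1:6])
  }, integer(1))
  stop_sym <- read_symbol(widths[n_sym * 6L + 1:7])
  if (stop_sym != CODE128_STOP) {
    psn_stop("pseudoreg_symbology_error", "missing Code 128 stop pattern")
  }
  if (symbols[1] != CODE128_START_B) {
    psn_stop("pseudoreg_symbology_error", "only code set B symbols are produced here")
  }
  vals <- symbols[-c(1L, length(symbols))]
  check <- symbols[length(symbols)]
  expect <- (CODE128_START_B + sum(vals * seq_along(vals))) %% 103L
  if (check != expect) {
    psn_stop("pseudoreg_symbology_error", "Code 128 checksum mismatch")
  }
  intToUtf8(vals + 32L)
}
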