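# DataMatrix ECC200 encoder/decoder for square symbols 10x10 .. 26x26
# (single Reed-Solomon block each), ASCII encodation. These sizes carry up
# to 40-odd characters, ample for a biosample identifier, and are the
# symbols laboratory vial scanners expect.

DM_SIZES <- data.frame(
  size    = c(10L, 12L, 14L, 16L, 18L, 20L, 22L, 24L, 26L),
  data_cw = c( 3L,  5L,  8L, 12L, 18L, 22L, 30L, 36L, 44L),
  ecc_cw  = c( 5L,  7L, 10L, 12L, 14L, 18L, 20L, 24L, 28L)
)

dm_ascii_codewords <- function(text) {
  chars <- utf8ToInt(text)
  if (any(chars > 127L)) {
    psn_stop("pseudoreg_symbology_error",
             "DataMatrix ASCII encodation supports ASCII 0..127 only")
  }
  out <- integer(0)
  i <- 1L
  digits <- chars >= 48L & chars <= 57L
  while (i <= length(chars)) {
    if (i < length(chars) && digits[i] && digits[i + 1L]) {
      out <- c(out, 130L + (chars[i] - 48L) * 10L + (chars[i + 1L] - 48L))
      i <- i + 2L
    } else {
      out <- c(out, chars[i] + 1L)
      i <- i + 1L
    }
  }
  out
}

dm_pad <- function(cw, data_cw) {
  if (length(cw) > data_cw) {
    psn_stop("pseudoreg_symbology_error", "payload exceeds symbol capacity")
  }
  if (length(cw) == data_cw) return(cw)
  cw <- c(cw, 129L)                                 # explicit pad
  while (length(cw) < data_cw) {
    pos <- length(cw) + 1L
    r <- 129L + ((149L * pos) %% 253L) + 1L         # 253-state randomization
    if (r > 254L) r <- r - 254L
    cw <- c(cw, r)
  }
  cw
}

dm_unpad <- function(cw) {
  # ASCII-encodation data codewords are 1..128 (characters) and 130..229
  # (digit pairs); 129 appears exclusively as the pad marker, so everything
  # from the first 129 onwards is padding.
  i <- match(129L, cw)
  if (is.na(i)) cw else cw[seq_len(i - 1L)]
}

dm_decode_ascii <- function(cw) {
  out <- character(0)
  for (v in cw) {
    if (v >= 1L && v <= 128L) {
      out <- c(out, intToUtf8(v - 1L))
    } else if (v >= 130L && v <= 229L) {
      out <- c(out, sprintf("%02d", v - 130L))
    } else {
      psn_stop("pseudoreg_symbology_error",
               paste0("unsupported DataMatrix codeword ", v))
    }
  }
  paste(out, collapse = "")
}

# ECC200 bit placement over the (size-2) x (size-2) data region. Returns
# two matrices: codeword index and bit index (1 = MSB) for every cell;
# cells left at 0 form the fixed 2x2 corner pattern present in some sizes.
dm_placement <- function(nrow_, ncol_) {
  posm <- matrix(0L, nrow_, ncol_)
  bitm <- matrix(0L, nrow_, ncol_)
  put <- function(r, c, pos, bit) {
    if (r < 0L) { r <- r + nrow_; c <- c + 4L - ((nrow_ + 4L) %% 8L) }
    if (c < 0L) { c <- c + ncol_; r <- r + 4L - ((ncol_ + 4L) %% 8L) }
    posm[r + 1L, c + 1L] <<- pos
    bitm[r + 1L, c + 1L] <<- bit
  }
  utah <- function(r, c, pos) {
    put(r - 2L, c - 2L, pos, 1L); put(r - 2L, c - 1L, pos, 2L)
    put(r - 1L, c - 2L, pos, 3L); put(r - 1L, c - 1L, pos, 4L)
    put(r - 1L, c,      pos, 5L); put(r,      c - 2L, pos, 6L)
    put(r,      c - 1L, pos, 7L); put(r,      c,      pos, 8L)
  }
  corner1 <- function(pos) {
    put(nrow_ - 1L, 0L, pos, 1L); put(nrow_ - 1L, 1L, pos, 2L)
    put(nrow_ - 1L, 2L, pos, 3L); put(0L, ncol_ - 2L, pos, 4L)
    put(0L, ncol_ - 1L, pos, 5L); put(1L, ncol_ - 1L, pos, 6L)
    put(2L, ncol_ - 1L, pos, 7L); put(3L, ncol_ - 1L, pos, 8L)
  }
  corner2 <- function(pos) {
    put(nrow_ - 3L, 0L, pos, 1L); put(nrow_ - 2L, 0L, pos, 2L)
    put(nrow_ - 1L, 0L, pos, 3L); put(0L, ncol_ - 4L, pos, 4L)
    put(0L, ncol_ - 3L, pos, 5L); put(0L, ncol_ - 2L, pos, 6L)
    put(0L, ncol_ - 1L, pos, 7L); put(1L, ncol_ - 1L, pos, 8L)
  }
  corner3 <- function(pos) {
    put(nrow_ - 3L, 0L, pos, 1L); put(nrow_ - 2L, 0L, pos, 2L)
    put(nrow_ - 1L, 0L, pos, 3L); put(0L, ncol_ - 2L, pos, 4L)
    put(0L, ncol_ - 1L, pos, 5L); put(1L, ncol_ - 1L, pos, 6L)
    put(2L, ncol_ - 1L, pos, 7L); put(3L, ncol_ - 1L, pos, 8L)
  }
  corner4 <- function(pos) {
    put(nrow_ - 1L, 0L, pos, 1L); put(nrow_ - 1L, ncol_ - 1L, pos, 2L)
    put(0L, ncol_ - 3L, pos, 3L); put(0L, ncol_ - 2L, pos, 4L)
    put(0L, ncol_ - 1L, pos, 5L); put(1L, ncol_ - 3L, pos, 6L)
    put(1L, ncol_ - 2L, pos, 7L); put(1L, ncol_ - 1L, pos, 8L)
  }
  pos <- 1L; row <- 4L; col <- 0L
  repeat {
    if (row == nrow_ && col == 0L) { corner1(pos); pos <- pos + 1L }
    if (row == nrow_ - 2L && col == 0L && ncol_ %% 4L != 0L) {
      corner2(pos); pos <- pos + 1L
    }
    if (row == nrow_ - 2L && col == 0L && ncol_ %% 8L == 4L) {
      corner3(pos); pos <- pos + 1L
    }
    if (row == nrow_ + 4L && col == 2L && ncol_ %% 8L == 0L) {
      corner4(pos); pos <- pos + 1L
    }
    repeat {
      if (row < nrow_ && col >= 0L && posm[row + 1L, col + 1L] == 0L) {
        utah(row, col, pos); pos <- pos + 1L
      }
      row <- row - 2L; col <- col + 2L
      if (row < 0L || col >= ncol_) break
    }
    row <- row + 1L; col <- col + 3L
    repeat {
      if (row >= 0L && col < ncol_ && posm[row + 1L, col + 1L] == 0L) {
        utah(row, col, pos); pos <- pos + 1L
      }
      row <- row + 2L; col <- col - 2L
      if (row >= nrow_ || col < 0L) break
    }
    row <- row + 3L; col <- col + 1L
    if (row >= nrow_ && col >= ncol_) break
  }
  list(pos = posm, bit = bitm)
}

dm_encode <- function(text) {
  if (!is_string(text) || !nzchar(text)) {
    psn_stop("pseudoreg_symbology_error", "cannot encode an empty value")
  }
  cw <- dm_ascii_codewords(text)
  row <- NULL
  for (k in seq_len(nrow(DM_SIZES))) {
    if (length(cw) <= DM_SIZES$data_cw[k]) { row <- DM_SIZES[k, ]; break }
  }
  if (is.null(row)) {
    psn_stop("pseudoreg_symbology_error",
             sprintf("payload needs %d codewords, exceeding the 26x26 capacity of %d",
                     length(cw), max(DM_SIZES$data_cw)))
  }
  data_cw <- dm_pad(cw, row$data_cw)
  ecc <- rs_encode(data_cw, row$ecc_cw, gf_dm(), first_root = 1L)
  codewords <- c(data_cw, ecc)

  reg <- row$size - 2L
  pl <- dm_placement(reg, reg)
  region <- matrix(FALSE, reg, reg)
  for (r in seq_len(reg)) for (c in seq_len(reg)) {
    p <- pl$pos[r, c]
    if (p > 0L && p <= length(codewords)) {
      region[r, c] <- bitwAnd(codewords[p], bitwShiftL(1L, 8L - pl$bit[r, c])) != 0L
    }
  }
  if (any(pl$pos == 0L)) {                 # fixed corner pattern
    region[reg - 1L, reg - 1L] <- TRUE
    region[reg, reg] <- TRUE
    region[reg - 1L, reg] <- FALSE
    region[reg, reg - 1L] <- FALSE
  }
  m <- matrix(FALSE, row$size, row$size)
  m[2:(row$size - 1L), 2:(row$size - 1L)] <- region
  m[, 1L] <- TRUE                                  # solid left edge
  m[row$size, ] <- TRUE                            # solid bottom edge
  m[1L, ] <- seq_len(row$size) %% 2L == 1L         # alternating top edge
  m[, row$size] <- seq_len(row$size) %% 2L == 0L   # alternating right edge
  m
}

dm_decode <- function(m) {
  size <- nrow(m)
  row <- DM_SIZES[DM_SIZES$size == size, ]
  if (!nrow(row) || ncol(m) != size) {
    psn_stop("pseudoreg_symbology_error", "unsupported DataMatrix size")
  }
  if (!all(m[, 1L]) || !all(m[size, ])) {
    psn_stop("pseudoreg_symbology_error", "DataMatrix finder pattern missing")
  }
  reg <- size - 2L
  region <- m[2:(size - 1L), 2:(size - 1L)]
  pl <- dm_placement(reg, reg)
  total <- row$data_cw + row$ecc_cw
  cw <- integer(total)
  for (r in seq_len(reg)) for (c in seq_len(reg)) {
    p <- pl$pos[r, c]
    if (p > 0L && p <= total && region[r, c]) {
      cw[p] <- bitwOr(cw[p], bitwShiftL(1L, 8L - pl$bit[r, c]))
    }
  }
  if (any(rs_syndromes(cw, row$ecc_cw, gf_dm(), 1L) != 0L)) {
    psn_stop("pseudoreg_symbology_error",
             "DataMatrix Reed-Solomon syndromes are non-zero")
  }
  dm_decode_ascii(dm_unpad(cw[seq_len(row$data_cw)]))
}
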