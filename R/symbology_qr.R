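# QR code encoder/decoder: byte mode, versions 1-3, error-correction level
# M, mask pattern 0. Biosample identifiers are short (<= 42 bytes at
# version 3-M), so small symbols suffice for vial labels. The decoder reads
# any of the produced symbols back: format information is recovered by
# minimum Hamming distance over all 32 valid format words, data modules are
# unmasked and deinterleaved, and the Reed-Solomon syndromes must vanish.

QR_VERSIONS <- list(
  list(version = 1L, size = 21L, data_cw = 16L, ecc_cw = 10L, align = integer(0)),
  list(version = 2L, size = 25L, data_cw = 28L, ecc_cw = 16L, align = 18L),
  list(version = 3L, size = 29L, data_cw = 44L, ecc_cw = 26L, align = 22L)
)

qr_format_bits <- function(ec = "M", mask = 0L) {
  ec_bits <- switch(ec, L = 1L, M = 0L, Q = 3L, H = 2L)
  d <- bitwOr(bitwShiftL(ec_bits, 3L), mask)
  # BCH(15,5) remainder with generator 0x537
  val <- bitwShiftL(d, 10L)
  for (i in 14:10) {
    if (bitwAnd(val, bitwShiftL(1L, i)) != 0L) {
      val <- bitwXor(val, bitwShiftL(0x537L, i - 10L))
    }
  }
  word <- bitwXor(bitwOr(bitwShiftL(d, 10L), val), 0x5412L)
  as.integer(intToBits(word))[15:1]
}

# Function-pattern template: returns list(modules, reserved) where reserved
# marks every non-data module (finders, separators, timing, alignment,
# format areas, dark module).
qr_template <- function(spec) {
  n <- spec$size
  m <- matrix(FALSE, n, n)
  res <- matrix(FALSE, n, n)
  place_finder <- function(r, c) {
    for (i in 0:6) for (j in 0:6) {
      dark <- i %in% c(0L, 6L) || j %in% c(0L, 6L) || (i %in% 2:4 && j %in% 2:4)
      m[r + i, c + j] <<- dark
      res[r + i, c + j] <<- TRUE
    }
    for (i in -1:7) for (j in -1:7) {      # separator ring
      ri <- r + i; cj <- c + j
      if (ri >= 1 && ri <= n && cj >= 1 && cj <= n && !res[ri, cj]) {
        res[ri, cj] <<- TRUE
        m[ri, cj] <<- FALSE
      }
    }
  }
  place_finder(1L, 1L)
  place_finder(1L, n - 6L)
  place_finder(n - 6L, 1L)
  for (k in 9:(n - 8)) {                   # timing
    m[7L, k] <- k %% 2L == 1L; res[7L, k] <- TRUE
    m[k, 7L] <- k %% 2L == 1L; res[k, 7L] <- TRUE
  }
  if (length(spec$align)) {                # alignment pattern (center 1-based)
    ctr <- spec$align + 1L
    for (i in -2:2) for (j in -2:2) {
      dark <- max(abs(i), abs(j)) != 1L
      m[ctr + i, ctr + j] <- dark
      res[ctr + i, ctr + j] <- TRUE
    }
  }
  m[n - 7L, 9L] <- TRUE; res[n - 7L, 9L] <- TRUE   # dark module
  # format information areas
  for (k in 1:6) { res[9L, k] <- TRUE; res[k, 9L] <- TRUE }
  res[9L, 8L] <- TRUE; res[9L, 9L] <- TRUE; res[8L, 9L] <- TRUE
  for (k in (n - 7L):n) res[9L, k] <- TRUE
  for (k in (n - 6L):n) res[k, 9L] <- TRUE
  list(modules = m, reserved = res)
}

# Zigzag order of data modules: two-column strips from the right edge,
# alternating upward/downward, skipping the timing column.
qr_data_positions <- function(spec, reserved) {
  n <- spec$size
  out <- matrix(0L, nrow = 0, ncol = 2)
  col <- n
  upward <- TRUE
  while (col >= 1L) {
    if (col == 7L) col <- col - 1L         # timing column
    rows <- if (upward) n:1 else 1:n
    for (r in rows) {
      for (c in c(col, col - 1L)) {
        if (c >= 1L && !reserved[r, c]) out <- rbind(out, c(r, c))
      }
    }
    upward <- !upward
    col <- col - 2L
  }
  out
}

qr_place_format <- function(m, bits) {
  n <- nrow(m)
  # copy 1: around the top-left finder
  cells1 <- rbind(
    cbind(9L, 1:6), cbind(9L, 8L), cbind(9L, 9L), cbind(8L, 9L),
    cbind(6:1, 9L))
  # copy 2: below the top-right finder and right of the bottom-left finder
  cells2 <- rbind(cbind((n - 0L):(n - 6L), 9L), cbind(9L, (n - 7L):n))
  for (k in 1:15) {
    m[cells1[k, 1], cells1[k, 2]] <- bits[k] == 1L
    m[cells2[k, 1], cells2[k, 2]] <- bits[k] == 1L
  }
  m
}

qr_read_format <- function(m) {
  n <- nrow(m)
  cells1 <- rbind(cbind(9L, 1:6), cbind(9L, 8L), cbind(9L, 9L), cbind(8L, 9L),
                  cbind(6:1, 9L))
  bits <- vapply(1:15, function(k) as.integer(m[cells1[k, 1], cells1[k, 2]]),
                 integer(1))
  best <- NULL; best_d <- Inf
  for (ec in c("L", "M", "Q", "H")) for (mask in 0:7) {
    cand <- qr_format_bits(ec, mask)
    d <- sum(cand != bits)
    if (d < best_d) { best_d <- d; best <- list(ec = ec, mask = mask) }
  }
  if (best_d > 3L) {
    psn_stop("pseudoreg_symbology_error", "unreadable QR format information")
  }
  best
}

qr_mask_fun <- function(mask) {
  switch(mask + 1L,
    function(r, c) (r + c) %% 2L == 0L,
    function(r, c) r %% 2L == 0L,
    function(r, c) c %% 3L == 0L,
    function(r, c) (r + c) %% 3L == 0L,
    function(r, c) (r %/% 2L + c %/% 3L) %% 2L == 0L,
    function(r, c) (r * c) %% 2L + (r * c) %% 3L == 0L,
    function(r, c) ((r * c) %% 2L + (r * c) %% 3L) %% 2L == 0L,
    function(r, c) ((r + c) %% 2L + (r * c) %% 3L) %% 2L == 0L)
}

qr_encode <- function(text) {
  if (!is_string(text) || !nzchar(text)) {
    psn_stop("pseudoreg_symbology_error", "cannot encode an empty value")
  }
  bytes <- as.integer(charToRaw(enc2utf8(text)))
  spec <- NULL
  for (cand in QR_VERSIONS) {
    if (length(bytes) <= cand$data_cw - 2L) { spec <- cand; break }
  }
  if (is.null(spec)) {
    psn_stop("pseudoreg_symbology_error",
             sprintf("payload of %d bytes exceeds the %d-byte capacity of version 3-M",
                     length(bytes), QR_VERSIONS[[3]]$data_cw - 2L))
  }
  bits <- c(c(0L, 1L, 0L, 0L),                               # byte mode
            as.integer(intToBits(length(bytes)))[8:1],       # 8-bit count
            unlist(lapply(bytes, function(b) as.integer(intToBits(b))[8:1])))
  bits <- c(bits, integer(min(4L, spec$data_cw * 8L - length(bits))))
  if (length(bits) %% 8L != 0L) bits <- c(bits, integer(8L - length(bits) %% 8L))
  cw <- vapply(seq_len(length(bits) / 8L), function(k) {
    sum(bits[(k - 1L) * 8L + 1:8] * bitwShiftL(1L, 7:0))
  }, numeric(1))
  pads <- rep(c(0xECL, 0x11L), length.out = spec$data_cw - length(cw))
  data_cw <- c(as.integer(cw), pads)
  ecc <- rs_encode(data_cw, spec$ecc_cw, gf_qr(), first_root = 0L)
  codewords <- c(data_cw, ecc)

  tpl <- qr_template(spec)
  m <- tpl$modules
  pos <- qr_data_positions(spec, tpl$reserved)
  all_bits <- unlist(lapply(codewords, function(b) as.integer(intToBits(b))[8:1]))
  maskf <- qr_mask_fun(0L)
  for (k in seq_len(nrow(pos))) {
    r <- pos[k, 1]; c <- pos[k, 2]
    bit <- if (k <= length(all_bits)) all_bits[k] else 0L
    if (maskf(r - 1L, c - 1L)) bit <- 1L - bit
    m[r, c] <- bit == 1L
  }
  m <- qr_place_format(m, qr_format_bits("M", 0L))
  m
}

qr_decode <- function(m) {
  n <- nrow(m)
  v <- (n - 17L) / 4L
  if (v < 1L || v > 3L || n != ncol(m) || (n - 17L) %% 4L != 0L) {
    psn_stop("pseudoreg_symbology_error", "unsupported QR matrix size")
  }
  spec <- QR_VERSIONS[[v]]
  fmt <- qr_read_format(m)
  tpl <- qr_template(spec)
  pos <- qr_data_positions(spec, tpl$reserved)
  maskf <- qr_mask_fun(fmt$mask)
  bits <- integer(nrow(pos))
  for (k in seq_len(nrow(pos))) {
    r <- pos[k, 1]; c <- pos[k, 2]
    bit <- as.integer(m[r, c])
    if (maskf(r - 1L, c - 1L)) bit <- 1L - bit
    bits[k] <- bit
  }
  total_cw <- spec$data_cw + spec$ecc_cw
  cw <- vapply(seq_len(total_cw), function(k) {
    sum(bits[(k - 1L) * 8L + 1:8] * bitwShiftL(1L, 7:0))
  }, numeric(1))
  if (any(rs_syndromes(as.integer(cw), spec$ecc_cw, gf_qr(), 0L) != 0L)) {
    psn_stop("pseudoreg_symbology_error", "QR Reed-Solomon syndromes are non-zero")
  }
  data_cw <- as.integer(cw[seq_len(spec$data_cw)])
  stream <- unlist(lapply(data_cw, function(b) as.integer(intToBits(b))[8:1]))
  mode <- sum(stream[1:4] * c(8L, 4L, 2L, 1L))
  if (mode != 4L) {
    psn_stop("pseudoreg_symbology_error", "only byte-mode QR payloads are produced here")
  }
  len <- sum(stream[5:12] * bitwShiftL(1L, 7:0))
  bytes <- vapply(seq_len(len), function(k) {
    sum(stream[12L + (k - 1L) * 8L + 1:8] * bitwShiftL(1L, 7:0))
  }, numeric(1))
  rawToChar(as.raw(bytes))
}
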