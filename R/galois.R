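# GF(256) arithmetic and Reed-Solomon encoding, parameterized by the
# primitive polynomial (0x11D for QR, 0x12D for DataMatrix ECC200) and the
# first root of the generator polynomial (alpha^0 for QR, alpha^1 for
# DataMatrix).

gf_tables <- function(prim) {
  exp <- integer(512)
  log <- integer(256)
  x <- 1L
  for (i in 0:254) {
    exp[i + 1L] <- x
    log[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwAnd(bitwXor(x, prim), 255L)
  }
  exp[256:511] <- exp[1:256]
  list(exp = exp, log = log)
}

gf_mul <- function(a, b, gf) {
  if (a == 0L || b == 0L) return(0L)
  gf$exp[((gf$log[a + 1L] + gf$log[b + 1L]) %% 255L) + 1L]
}

# Generator polynomial prod_{i=0}^{nsym-1} (x - alpha^(first_root + i)),
# returned as coefficient vector, highest degree first, leading 1.
rs_generator <- function(nsym, gf, first_root = 0L) {
  g <- 1L
  for (i in seq_len(nsym) - 1L) {
    root <- gf$exp[((first_root + i) %% 255L) + 1L]
    g_new <- integer(length(g) + 1L)
    for (j in seq_along(g)) {
      g_new[j] <- bitwXor(g_new[j], g[j])                    # x * g
      g_new[j + 1L] <- bitwXor(g_new[j + 1L], gf_mul(g[j], root, gf))
    }
    g <- g_new
  }
  g
}

# Systematic RS encoding: returns the nsym parity symbols for `data`.
rs_encode <- function(data, nsym, gf, first_root = 0L) {
  gen <- rs_generator(nsym, gf, first_root)
  buf <- c(as.integer(data), integer(nsym))
  for (i in seq_along(data)) {
    coef <- buf[i]
    if (coef != 0L) {
      for (j in seq_along(gen)[-1L]) {
        buf[i + j - 1L] <- bitwXor(buf[i + j - 1L], gf_mul(gen[j], coef, gf))
      }
    }
  }
  buf[length(data) + seq_len(nsym)]
}

# Syndromes of a received codeword; all zero iff the word is a valid
# codeword (no correction is attempted here -- a printed label that fails
# its syndromes should be re-printed, not guessed at).
rs_syndromes <- function(codeword, nsym, gf, first_root = 0L) {
  vapply(seq_len(nsym) - 1L, function(i) {
    root <- gf$exp[((first_root + i) %% 255L) + 1L]
    s <- 0L
    for (c in as.integer(codeword)) s <- bitwXor(gf_mul(s, root, gf), c)
    s
  }, integer(1))
}

.gf_cache <- new.env(parent = emptyenv())

gf_qr <- function() {
  if (is.null(.gf_cache$qr)) .gf_cache$qr <- gf_tables(0x11DL)
  .gf_cache$qr
}

gf_dm <- function() {
  if (is.null(.gf_cache$dm)) .gf_cache$dm <- gf_tables(0x12DL)
  .gf_cache$dm
}
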