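# Minimal arbitrary-precision non-negative/signed integer arithmetic.
#
# Reconstruction counts routinely exceed double precision (the survey scale
# is 2^900), and no big-integer package is available, so exact counting is
# done on base-1e7 digit vectors (little-endian doubles). Only the
# operations the counting theorem needs are provided: add, subtract,
# compare, multiply/divide/modulo by a machine-size integer, decimal
# rendering and log2. Exact determinants avoid big-by-big division entirely
# by Chinese-remaindering modular eliminations (see det_exact in count.R).

BIG_BASE <- 1e7

big_new <- function(sign, mag) {
  mag <- as.numeric(mag)
  while (length(mag) > 1L && mag[[length(mag)]] == 0) {
    mag <- mag[-length(mag)]
  }
  if (length(mag) == 1L && mag[[1L]] == 0) sign <- 0L
  structure(list(s = as.integer(sign), d = mag), class = "bignum")
}

big_from_num <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x == floor(x), abs(x) < 2^53)
  s <- sign(x)
  x <- abs(x)
  d <- numeric(0L)
  repeat {
    d <- c(d, x %% BIG_BASE)
    x <- floor(x / BIG_BASE)
    if (x == 0) break
  }
  big_new(s, d)
}

big_zero <- function() big_new(0L, 0)
big_one <- function() big_new(1L, 1)
big_is_zero <- function(a) a$s == 0L

# compare magnitudes: -1, 0, 1
big_cmp_mag <- function(a, b) {
  la <- length(a$d); lb <- length(b$d)
  if (la != lb) return(if (la < lb) -1L else 1L)
  for (i in rev(seq_len(la))) {
    if (a$d[[i]] != b$d[[i]]) return(if (a$d[[i]] < b$d[[i]]) -1L else 1L)
  }
  0L
}

big_cmp <- function(a, b) {
  if (a$s != b$s) return(if (a$s < b$s) -1L else 1L)
  if (a$s == 0L) return(0L)
  a$s * big_cmp_mag(a, b)
}

big_add_mag <- function(x, y) {
  n <- max(length(x), length(y))
  x <- c(x, numeric(n - length(x)))
  y <- c(y, numeric(n - length(y)))
  z <- x + y
  carry <- 0
  for (i in seq_len(n)) {
    z[[i]] <- z[[i]] + carry
    carry <- if (z[[i]] >= BIG_BASE) 1 else 0
    z[[i]] <- z[[i]] - carry * BIG_BASE
  }
  if (carry > 0) z <- c(z, carry)
  z
}

# requires |x| >= |y|
big_sub_mag <- function(x, y) {
  y <- c(y, numeric(length(x) - length(y)))
  z <- x - y
  for (i in seq_along(z)) {
    if (z[[i]] < 0) {
      z[[i]] <- z[[i]] + BIG_BASE
      z[[i + 1L]] <- z[[i + 1L]] - 1
    }
  }
  z
}

big_add <- function(a, b) {
  if (big_is_zero(a)) return(b)
  if (big_is_zero(b)) return(a)
  if (a$s == b$s) return(big_new(a$s, big_add_mag(a$d, b$d)))
  cmp <- big_cmp_mag(a, b)
  if (cmp == 0L) return(big_zero())
  if (cmp > 0L) big_new(a$s, big_sub_mag(a$d, b$d))
  else big_new(b$s, big_sub_mag(b$d, a$d))
}

big_neg <- function(a) big_new(-a$s, a$d)
big_sub <- function(a, b) big_add(a, big_neg(b))

# multiply by machine integer 0 <= m < 2^26 (digit*m + carry stays exact)
big_mul_small <- function(a, m) {
  stopifnot(m >= 0, m == floor(m), m < 2^26)
  if (m == 0 || big_is_zero(a)) return(big_zero())
  z <- a$d * m
  carry <- 0
  out <- numeric(0L)
  i <- 1L
  while (i <= length(z) || carry > 0) {
    cur <- (if (i <= length(z)) z[[i]] else 0) + carry
    carry <- floor(cur / BIG_BASE)
    out <- c(out, cur - carry * BIG_BASE)
    i <- i + 1L
  }
  big_new(a$s, out)
}

# exact-capable division by machine integer m (r*BASE + digit stays exact
# in doubles for m < 2^29)
big_div_small <- function(a, m) {
  stopifnot(m >= 1, m == floor(m), m < 2^29)
  r <- 0
  q <- numeric(length(a$d))
  for (i in rev(seq_along(a$d))) {
    cur <- r * BIG_BASE + a$d[[i]]
    q[[i]] <- floor(cur / m)
    r <- cur - q[[i]] * m
  }
  list(q = big_new(a$s, q), r = r)
}

big_mod_small <- function(a, m) {
  stopifnot(m >= 1, m == floor(m), m < 2^29)
  r <- 0
  for (i in rev(seq_along(a$d))) {
    r <- (r * (BIG_BASE %% m) + a$d[[i]]) %% m
  }
  if (a$s < 0L && r != 0) r <- m - r
  r
}

big_to_string <- function(a) {
  if (big_is_zero(a)) return("0")
  digits <- rev(a$d)
  body <- paste0(format(digits[[1L]], scientific = FALSE, trim = TRUE),
                 paste(sprintf("%07.0f", digits[-1L]), collapse = ""))
  if (a$s < 0L) paste0("-", body) else body
}

big_to_num <- function(a) {
  v <- 0
  for (i in rev(seq_along(a$d))) v <- v * BIG_BASE + a$d[[i]]
  a$s * v
}

big_log2 <- function(a) {
  if (big_is_zero(a)) return(-Inf)
  n <- length(a$d)
  top <- 0
  for (i in seq(n, max(1L, n - 2L))) top <- top * BIG_BASE + a$d[[i]]
  log2(top) + (n - length(seq(n, max(1L, n - 2L)))) * log2(BIG_BASE)
}

#' @export
print.bignum <- function(x, ...) {
  cat(big_to_string(x), "\n")
  invisible(x)
}

#' @export
#' @method format bignum
format.bignum <- function(x, ...) big_to_string(x)
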