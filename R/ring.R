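#' Ring and fixed-point number system
#'
#' The protocol suite works with 2-out-of-2 additive secret sharing over three
#' rings: \eqn{Z_L} with \eqn{L = 2^n}, \eqn{Z_K} with \eqn{K = 2^{n-1}} and the
#' prime field \eqn{Z_V} with \eqn{V = 67}. Real numbers are carried in
#' fixed-point form: an \eqn{n}-bit two's-complement integer whose least
#' significant \eqn{f} bits hold the fractional part.
#'
#' @param n ring bit width, one of 8, 16, 32, 64 (default 64)
#' @param f number of fractional bits, \eqn{0 \le f < n - 2} (default 20 when
#'   `n = 64`, otherwise 0 so that small rings default to raw integers)
#' @return an object of class `ring_spec` with fields `n`, `f`, `V` and helper
#'   constants
#' @examples
#' rs <- ring_spec()
#' rs$n
#' decode_fixed(encode_fixed(1.5, rs), rs)
#' @export
ring_spec <- function(n = 64L, f = if (n == 64L) 20L else 0L) {
  n <- as.integer(n)
  f <- as.integer(f)
  if (!n %in% c(8L, 16L, 32L, 64L)) stop("n must be one of 8, 16, 32, 64")
  if (f < 0L || f >= n - 2L) stop("f must satisfy 0 <= f < n - 2")
  structure(list(n = n, f = f, V = 67L), class = "ring_spec")
}

#' @export
print.ring_spec <- function(x, ...) {
  cat(sprintf("<ring_spec> n = %d (L = 2^%d, K = 2^%d), f = %d, V = %d\n",
              x$n, x$n, x$n - 1L, x$f, x$V))
  invisible(x)
}

# number of bits of the ring a value lives in ("L" or "K")
ring_bits <- function(spec, ring) {
  switch(ring, L = spec$n, K = spec$n - 1L,
         stop("unknown ring: ", ring))
}

# modulus of ring, bit-cast (0 stands for 2^64)
ring_modulus_u64 <- function(spec, ring) {
  nb <- ring_bits(spec, ring)
  if (nb == 64L) rg_from_dbl(0, 64L) else rg_from_dbl(2^nb, 64L)
}

#' Fixed-point encoding of reals into the ring
#'
#' Encodes reals as `round(x * 2^f)` in two's complement modulo \eqn{2^n},
#' rounding half away from zero. The representable range is
#' \eqn{|x| < 2^{n-1-f}}.
#'
#' @param x numeric vector of reals
#' @param spec a [ring_spec()]
#' @return a `ring64` vector (raw ring elements)
#' @export
encode_fixed <- function(x, spec = ring_spec()) {
  as_ring64(rg_encode(as.numeric(x), spec$n, spec$f))
}

#' Decode fixed-point ring elements back to reals
#'
#' Inverse of [encode_fixed()] up to one unit in the last place
#' (\eqn{2^{-f}}): the raw word is read as a two's-complement integer and
#' scaled by \eqn{2^{-f}}.
#'
#' @param v a `ring64` vector of raw ring elements
#' @param spec a [ring_spec()]
#' @return numeric vector
#' @export
decode_fixed <- function(v, spec = ring_spec()) {
  out <- rg_decode(unclass_ring(v), spec$n, spec$f)
  d <- dim(v)
  if (!is.null(d)) dim(out) <- d
  out
}

# ---- ring64 vectors --------------------------------------------------------

#' Raw ring elements
#'
#' `ring64` vectors store unsigned ring elements as the 8-byte patterns of R
#' doubles. Never do R arithmetic on them; use the `ring_*` helpers, which run
#' exact unsigned 64-bit arithmetic in C++.
#'
#' @param x numeric vector of non-negative integers below 2^53 (exact in a
#'   double), or an existing `ring64` vector
#' @param spec a [ring_spec()]
#' @param ring `"L"` or `"K"`
#' @return a `ring64` vector
#' @export
ring_elem <- function(x, spec = ring_spec(), ring = "L") {
  as_ring64(rg_from_dbl(as.numeric(x), ring_bits(spec, ring)))
}

as_ring64 <- function(x) {
  class(x) <- "ring64"
  x
}

unclass_ring <- function(x) {
  y <- unclass(x)
  y
}

#' @export
print.ring64 <- function(x, ...) {
  v <- rg_as_char(unclass_ring(x))
  cat("<ring64>", utils::head(v, 20L),
      if (length(v) > 20L) sprintf("... (%d total)", length(v)), "\n")
  invisible(x)
}

#' @export
`[.ring64` <- function(x, ...) as_ring64(NextMethod())

#' @export
length.ring64 <- function(x) length(unclass_ring(x))

#' @export
c.ring64 <- function(...) {
  as_ring64(do.call(c, lapply(list(...), unclass_ring)))
}

# exact equality of raw ring words
ring_identical <- function(a, b) {
  all(rg_eq(unclass_ring(a), unclass_ring(b)))
}

# elementwise modular helpers on ring64 vectors (nbits from spec/ring)
ring_add <- function(a, b, spec, ring = "L") {
  as_ring64(rg_add(unclass_ring(a), unclass_ring(b), ring_bits(spec, ring)))
}
ring_sub <- function(a, b, spec, ring = "L") {
  as_ring64(rg_sub(unclass_ring(a), unclass_ring(b), ring_bits(spec, ring)))
}
ring_neg <- function(a, spec, ring = "L") {
  as_ring64(rg_neg(unclass_ring(a), ring_bits(spec, ring)))
}
ring_mulv <- function(a, b, spec, ring = "L") {
  as_ring64(rg_mul(unclass_ring(a), unclass_ring(b), ring_bits(spec, ring)))
}

# ---- additive sharing ------------------------------------------------------

#' Additively share ring elements
#'
#' Splits each element `x` of a vector into two shares with
#' `share0 + share1 = x (mod 2^nbits)`, `share0` uniform. Randomness comes
#' from a deterministic stream object created with [rng_stream()].
#'
#' @param x a `ring64` vector of secrets (elements of the ring)
#' @param spec a [ring_spec()]
#' @param ring `"L"` (modulus `2^n`) or `"K"` (modulus `2^(n-1)`)
#' @param rng an [rng_stream()] supplying the masking randomness
#' @return list with `ring64` components `s0` and `s1` and the ring name
#' @export
share_additive <- function(x, spec = ring_spec(), ring = "L",
                           rng = rng_stream(1L)) {
  xr <- unclass_ring(x)
  nb <- ring_bits(spec, ring)
  s0 <- rng_next(rng, length(xr), modulus_bits = nb)
  s1 <- rg_sub(xr, s0, nb)
  list(s0 = as_ring64(s0), s1 = as_ring64(s1), ring = ring)
}

#' Reconstruct a secret from its two additive shares
#'
#' @param s0,s1 `ring64` share vectors held by the two proxies
#' @param spec a [ring_spec()]
#' @param ring ring the shares live in (`"L"` or `"K"`); both shares must be
#'   from the same ring
#' @return `ring64` vector of secrets
#' @export
reconstruct <- function(s0, s1, spec = ring_spec(), ring = "L") {
  if (length(s0) != length(s1)) stop("share length mismatch")
  ring_add(s0, s1, spec, ring)
}

#' Bitwise sharing over the prime field Z_67
#'
#' Decomposes each element of `x` (a value of the K ring, i.e. below
#' \eqn{2^{n-1}}) into its `n` bits, most significant first, and additively
#' shares every bit over \eqn{Z_{67}}. This is the input format of the private
#' compare protocol.
#'
#' @param x a `ring64` vector with values below \eqn{2^{n-1}}
#' @param spec a [ring_spec()]
#' @param rng an [rng_stream()]
#' @return list with integer matrices `b0`, `b1` (`n` rows, one column per
#'   element; entries in `0..66`)
#' @export
share_bitwise <- function(x, spec = ring_spec(), rng = rng_stream(1L)) {
  bits <- rg_bits(unclass_ring(x), spec$n)
  b0 <- matrix(rng_next_int(rng, length(bits), spec$V),
               nrow = nrow(bits))
  b1 <- (bits - b0) %% spec$V
  list(b0 = b0, b1 = b1)
}

#' Reconstruct a bitwise-shared value
#'
#' @param bs a list with `b0`, `b1` as returned by [share_bitwise()]
#' @param spec a [ring_spec()]
#' @return `ring64` vector of the reassembled secrets
#' @export
reconstruct_bitwise <- function(bs, spec = ring_spec()) {
  bits <- (bs$b0 + bs$b1) %% spec$V
  if (any(bits > 1L)) stop("reconstructed bits outside {0,1}")
  as_ring64(rg_from_bits(bits))
}

# ---- deterministic randomness ----------------------------------------------

#' Deterministic randomness stream
#'
#' A seeded splitmix64 stream. Every source of randomness in the package --
#' the proxies' common tape, the helper's dealing randomness, the outsourcing
#' masks -- is one of these, so any run is reproducible from its seeds.
#'
#' @param seed an integer seed
#' @return an environment holding the evolving stream state
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- rng_seed_state(as.numeric(seed))
  class(e) <- "rng_stream"
  e
}

# draw `count` ring elements (modulus 2^modulus_bits; 64 means full words)
rng_next <- function(rng, count, modulus_bits = 64L) {
  mod <- if (modulus_bits == 64L) rg_from_dbl(0, 64L)
         else rg_from_dbl(2^modulus_bits, 64L)
  res <- rng_draw(rng$state, as.integer(count), mod)
  rng$state <- res$state
  res$values
}

# draw `count` integers in [0, modulus)
rng_next_int <- function(rng, count, modulus) {
  res <- rng_draw_int(rng$state, as.integer(count), as.integer(modulus))
  rng$state <- res$state
  res$values
}

# draw `m` random permutations of 0..(nbits-1) (one per column)
rng_next_perm <- function(rng, nbits, m) {
  res <- rng_perm(rng$state, as.integer(nbits), as.integer(m))
  rng$state <- res$state
  res$values
}
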