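# The secure building blocks. Every protocol is vectorized: one call over a
# whole tensor is one invocation (and one helper round), which is what the
# transcript counts. Code is organized so each computation uses only the
# state its party legitimately holds: tape draws are shared by P0/P1 only,
# helper draws only by P2, and everything that crosses a party boundary goes
# through msg_transfer (where bytes are counted and, under the socket
# transport, framed through a real TCP connection).

#' Secure addition
#'
#' Local modular addition of shares; exchanges no messages.
#'
#' @param sess an [mpc_session()]
#' @param x,y `shared_tensor`s over the same ring
#' @return a `shared_tensor` of `x + y`
#' @export
mpc_add <- function(sess, x, y) {
  check_same_ring(x, y)
  count_invocation(sess, "ADD")
  new_shared(ring_add(x$s0, y$s0, x$spec, x$ring),
             ring_add(x$s1, y$s1, x$spec, x$ring),
             x$spec, x$ring, x$dims)
}

#' Secure subtraction (local)
#' @inheritParams mpc_add
#' @return a `shared_tensor` of `x - y`
#' @export
mpc_sub <- function(sess, x, y) {
  check_same_ring(x, y)
  count_invocation(sess, "ADD")
  new_shared(ring_sub(x$s0, y$s0, x$spec, x$ring),
             ring_sub(x$s1, y$s1, x$spec, x$ring),
             x$spec, x$ring, x$dims)
}

mpc_neg <- function(sess, x) {
  new_shared(ring_neg(x$s0, x$spec, x$ring), ring_neg(x$s1, x$spec, x$ring),
             x$spec, x$ring, x$dims)
}

#' Add a public constant (local)
#'
#' Only P0 adjusts its share; the constant is encoded in fixed point.
#'
#' @inheritParams mpc_add
#' @param const numeric scalar (plaintext, known to the proxies)
#' @export
mpc_add_public <- function(sess, x, const) {
  enc <- rg_encode(const, x$spec$n, x$spec$f)
  new_shared(as_ring64(rg_add(unclass_ring(x$s0), enc, ring_bits(x$spec, x$ring))),
             x$s1, x$spec, x$ring, x$dims)
}

#' Multiply by a public scalar (local, one truncation)
#'
#' Both proxies scale their share by the fixed-point encoding of the scalar
#' and truncate locally; no helper round is needed.
#'
#' @inheritParams mpc_add
#' @param const numeric scalar (plaintext, known to the proxies)
#' @export
mpc_scale_public <- function(sess, x, const) {
  nb <- ring_bits(x$spec, x$ring)
  enc <- rg_encode(const, x$spec$n, x$spec$f)
  tp <- trunc_pair(sess, rg_mul(unclass_ring(x$s0), enc, nb),
                   rg_mul(unclass_ring(x$s1), enc, nb), "SCALE")
  new_shared(tp$s0, tp$s1, x$spec, x$ring, x$dims)
}

# Wrap-safe truncation of a shared product by f bits: P0 flags elements whose
# (uniform, secret-independent) share sits in the ring-boundary danger zone,
# both proxies shift those by a public constant, then truncate locally. The
# result reconstructs to the truncated value with error at most one unit in
# the last fractional bit -- with certainty, not just with high probability.
# Contract: pre-truncation magnitudes below 2^(n-11) raw.
trunc_pair <- function(sess, z0, z1, proto) {
  spec <- sess$ring
  nb <- spec$n
  if (spec$f == 0L) return(list(s0 = z0, s1 = z1))
  flags <- trunc_flags(z0, nb)
  flags <- msg_transfer(sess, "P0", "P1", proto, flags)
  z0 <- trunc_apply(z0, flags, 1L, nb)
  z1 <- trunc_apply(z1, flags, -1L, nb)
  list(s0 = rg_trunc_share(z0, spec$f, 0L, nb),
       s1 = rg_trunc_share(z1, spec$f, 1L, nb))
}

# ---- multiplication (Beaver triples dealt by the helper) --------------------

#' Secure fixed-point multiplication
#'
#' Elementwise product via helper-dealt multiplication triples; the only
#' values the proxies reveal to each other are the maskings `x - a`, `y - b`.
#' The doubled fixed-point scale is removed by local probabilistic truncation,
#' so each product carries at most ~one unit of error in the last fractional
#' bit.
#'
#' @param sess an [mpc_session()]
#' @param x,y `shared_tensor`s over L holding fixed-point values with
#'   `|x*y| < 2^(n-1-f)`
#' @param truncate set `FALSE` for raw ring products (no fixed-point scale)
#' @return a `shared_tensor` of the products
#' @export
mpc_mul <- function(sess, x, y, truncate = TRUE) {
  check_same_ring(x, y)
  count_invocation(sess, "MUL")
  spec <- x$spec
  nb <- ring_bits(spec, x$ring)
  m <- shared_length(x)

  # P2 deals one triple batch
  a <- rng_next(sess$rng$P2, m, nb); b <- rng_next(sess$rng$P2, m, nb)
  cc <- rg_mul(a, b, nb)
  a0 <- rng_next(sess$rng$P2, m, nb); a1 <- rg_sub(a, a0, nb)
  b0 <- rng_next(sess$rng$P2, m, nb); b1 <- rg_sub(b, b0, nb)
  c0 <- rng_next(sess$rng$P2, m, nb); c1 <- rg_sub(cc, c0, nb)
  trip0 <- msg_transfer(sess, "P2", "P0", "MUL", c(a0, b0, c0))
  trip1 <- msg_transfer(sess, "P2", "P1", "MUL", c(a1, b1, c1))

  # proxies open the maskings
  e0 <- rg_sub(unclass_ring(x$s0), trip0[1:m], nb)
  f0 <- rg_sub(unclass_ring(y$s0), trip0[m + 1:m], nb)
  e1 <- rg_sub(unclass_ring(x$s1), trip1[1:m], nb)
  f1 <- rg_sub(unclass_ring(y$s1), trip1[m + 1:m], nb)
  op <- mpc_exchange(sess, c(e0, f0), c(e1, f1), proto = "MUL")
  e <- rg_add(e0, op$at_p0[1:m], nb)       # e = x - a, public to proxies
  f <- rg_add(f0, op$at_p0[m + 1:m], nb)   # f = y - b

  z0 <- rg_add(rg_add(rg_mul(e, f, nb), rg_mul(e, trip0[m + 1:m], nb), nb),
               rg_add(rg_mul(f, trip0[1:m], nb), trip0[2 * m + 1:m], nb), nb)
  z1 <- rg_add(rg_add(rg_mul(e, trip1[m + 1:m], nb),
                      rg_mul(f, trip1[1:m], nb), nb), trip1[2 * m + 1:m], nb)
  if (truncate) {
    tp <- trunc_pair(sess, z0, z1, "MUL")
    z0 <- tp$s0; z1 <- tp$s1
  }
  new_shared(z0, z1, spec, x$ring, x$dims)
}

#' Secure matrix product
#'
#' Beaver multiplication lifted to matrices (one matrix triple per call, the
#' standard communication optimization), truncating once per output entry
#' after accumulation. Dot products are the `1 x m . m x 1` case.
#'
#' @param sess an [mpc_session()]
#' @param x a `shared_tensor` with dims `p x q`
#' @param y a `shared_tensor` with dims `q x s`
#' @param truncate set `FALSE` for raw ring products
#' @return a `shared_tensor` with dims `p x s`
#' @export
mpc_matmul <- function(sess, x, y, truncate = TRUE) {
  check_same_ring(x, y)
  count_invocation(sess, "MP")
  spec <- x$spec
  nb <- ring_bits(spec, x$ring)
  dx <- x$dims; dy <- y$dims
  if (length(dx) != 2L || length(dy) != 2L || dx[2] != dy[1])
    stop("mpc_matmul: shape mismatch")
  p <- dx[1]; q <- dx[2]; s <- dy[2]

  A <- rng_next(sess$rng$P2, p * q, nb); B <- rng_next(sess$rng$P2, q * s, nb)
  C <- rg_matmul(A, B, p, q, s, nb)
  A0 <- rng_next(sess$rng$P2, p * q, nb); A1 <- rg_sub(A, A0, nb)
  B0 <- rng_next(sess$rng$P2, q * s, nb); B1 <- rg_sub(B, B0, nb)
  C0 <- rng_next(sess$rng$P2, p * s, nb); C1 <- rg_sub(C, C0, nb)
  t0 <- msg_transfer(sess, "P2", "P0", "MP", c(A0, B0, C0))
  t1 <- msg_transfer(sess, "P2", "P1", "MP", c(A1, B1, C1))
  iA <- 1:(p * q); iB <- p * q + 1:(q * s); iC <- p * q + q * s + 1:(p * s)

  E0 <- rg_sub(unclass_ring(x$s0), t0[iA], nb)
  F0 <- rg_sub(unclass_ring(y$s0), t0[iB], nb)
  E1 <- rg_sub(unclass_ring(x$s1), t1[iA], nb)
  F1 <- rg_sub(unclass_ring(y$s1), t1[iB], nb)
  op <- mpc_exchange(sess, c(E0, F0), c(E1, F1), proto = "MP")
  E <- rg_add(E0, op$at_p0[iA - 0L], nb)
  F <- rg_add(F0, op$at_p0[p * q + 1:(q * s)], nb)

  Z0 <- rg_add(rg_add(rg_matmul(E, F, p, q, s, nb),
                      rg_matmul(E, t0[iB], p, q, s, nb), nb),
               rg_add(rg_matmul(t0[iA], F, p, q, s, nb), t0[iC], nb), nb)
  Z1 <- rg_add(rg_add(rg_matmul(E, t1[iB], p, q, s, nb),
                      rg_matmul(t1[iA], F, p, q, s, nb), nb), t1[iC], nb)
  if (truncate) {
    tp <- trunc_pair(sess, Z0, Z1, "MP")
    Z0 <- tp$s0; Z1 <- tp$s1
  }
  new_shared(Z0, Z1, spec, x$ring, c(p, s))
}

# Fused recurrence step: trunc(x*y + enc(scalar)*z) with a single truncation
# (one Beaver product plus a local public-scalar product, truncated together;
# the fused form halves the rounding noise injected per recurrence step).
mpc_mul_add_scaled <- function(sess, x, y, z, scalar) {
  prod <- mpc_mul(sess, x, y, truncate = FALSE)
  spec <- x$spec
  nb <- ring_bits(spec, x$ring)
  enc <- rg_encode(scalar, spec$n, spec$f)
  s0 <- rg_add(unclass_ring(prod$s0), rg_mul(unclass_ring(z$s0), enc, nb), nb)
  s1 <- rg_add(unclass_ring(prod$s1), rg_mul(unclass_ring(z$s1), enc, nb), nb)
  tp <- trunc_pair(sess, s0, s1, "MUL")
  new_shared(tp$s0, tp$s1, spec, x$ring, x$dims)
}

# ---- private compare --------------------------------------------------------

# Core: proxies hold Z_67 bit shares (b0, b1) of a secret below K; `pub` is a
# public ring64 vector below K. Returns XOR shares (c0 at P0, c1 at P1) of
# the predicate (secret > pub). The helper learns only u' = u XOR result with
# u a tape bit it never sees.
pc_core <- function(sess, b0, b1, pub) {
  count_invocation(sess, "PC")
  spec <- sess$ring
  m <- length(pub)
  beta <- tape_bits(sess, m)
  pubbits <- rg_bits(unclass_ring(pub), spec$n)
  scal <- tape_scalars_v(sess, spec$n * m)
  dim(scal) <- c(spec$n, m)
  perm <- tape_perms(sess, spec$n, m)

  d0 <- pc_party_msg(b0, pubbits, 0L, beta, scal, perm, spec$V)
  d1 <- pc_party_msg(b1, pubbits, 1L, beta, scal, perm, spec$V)
  d0r <- msg_transfer(sess, "P0", "P2", "PC", d0)
  d1r <- msg_transfer(sess, "P1", "P2", "PC", d1)

  uprime <- pc_helper(d0r, d1r, spec$V)
  g <- helper_bits(sess, m)
  g_at_p0 <- msg_transfer(sess, "P2", "P0", "PC", g)
  ug_at_p1 <- msg_transfer(sess, "P2", "P1", "PC", bitwXor(uprime, g))
  list(c0 = bitwXor(beta, g_at_p0), c1 = ug_at_p1)
}

#' Private compare of a bitwise-shared value against a public value
#'
#' Computes a Boolean (XOR) sharing of `(x > r)` from additive Z_67 shares of
#' the bits of `x`, with `r` public to the proxies. The helper sees only
#' scaled, permuted differences and a masked result bit.
#'
#' @param sess an [mpc_session()]
#' @param bitshares list with matrices `b0`, `b1` from [share_bitwise()]
#' @param r_pub `ring64` vector of public comparands (values below
#'   \eqn{2^{n-1}})
#' @return list of 0/1 integer vectors `c0`, `c1` with `xor(c0, c1) = (x > r)`
#' @export
private_compare <- function(sess, bitshares, r_pub) {
  pc_core(sess, bitshares$b0, bitshares$b1, r_pub)
}

# ---- modulus conversion -----------------------------------------------------

#' Modulus conversion: shares over K to fresh shares over L
#'
#' The helper deals a random `r` over K (additively and bitwise-shared) plus
#' Boolean shares of the wrap of its sharing; the proxies open `y = x + r mod
#' K`, detect the wrap of `x + r` with one private compare (`r > y`), then
#' correct by `K` per Boolean share -- sound because `2K = 0 mod L` -- and
#' subtract `r` over L.
#'
#' @param sess an [mpc_session()]
#' @param x a `shared_tensor` over the K ring
#' @return a `shared_tensor` over L reconstructing to the same value
#' @export
mpc_moc <- function(sess, x) {
  if (!identical(x$ring, "K")) stop("mpc_moc expects shares over K")
  count_invocation(sess, "MOC")
  spec <- sess$ring
  n <- spec$n
  m <- shared_length(x)
  Kv <- rg_from_dbl(2^(n - 1), n)

  # helper deals r, its K-sharing, Z_67 bit shares, and Boolean wrap shares
  dl <- moc_deal(sess$rng$P2$state, m, n)
  sess$rng$P2$state <- dl$state
  r0 <- dl$r0; r1 <- dl$r1
  rb0 <- dl$rb0; rb1 <- dl$rb1
  w0 <- dl$w0; w1 <- dl$w1
  deal0 <- msg_transfer(sess, "P2", "P0", "MOC", r0)
  rb0 <- msg_transfer(sess, "P2", "P0", "MOC", rb0)
  w0 <- msg_transfer(sess, "P2", "P0", "MOC", w0)
  deal1 <- msg_transfer(sess, "P2", "P1", "MOC", r1)
  rb1 <- msg_transfer(sess, "P2", "P1", "MOC", rb1)
  w1 <- msg_transfer(sess, "P2", "P1", "MOC", w1)

  # proxies mask and open y = (x + r) mod K
  yh0 <- rg_add(unclass_ring(x$s0), deal0, n - 1L)
  yh1 <- rg_add(unclass_ring(x$s1), deal1, n - 1L)
  op <- mpc_exchange(sess, yh0, yh1, proto = "MOC")
  y <- rg_add(yh0, op$at_p0, n - 1L)
  wy <- as.integer(rg_lt(y, yh0))          # (yh0 + yh1) wrapped over K

  # c = (r > y) via private compare on the helper-dealt bit shares
  pc <- pc_core(sess, rb0, rb1, as_ring64(y))

  # assemble over L: x_i = yh_i + K*([i==0]*wy + c_i + w_i) - r_i
  s0 <- moc_local(yh0, wy, pc$c0, w0, deal0, n)
  s1 <- moc_local(yh1, integer(m), pc$c1, w1, deal1, n)
  new_shared(s0, s1, spec, "L", x$dims)
}

# ---- most significant bit ---------------------------------------------------

#' Most significant bit of shared values
#'
#' Extracts the top bit (the sign, for fixed-point values) of each element.
#' The low `n-1` bits are split off share-locally, lifted back to L with one
#' modulus conversion, and subtracted, leaving `z in {0, K}`; the helper maps
#' the two candidates `z0, z0 + K` (sent in tape-randomized order) to fresh
#' shares of 0/1 and the proxies pick the real one.
#'
#' @param sess an [mpc_session()]
#' @param x a `shared_tensor` over L
#' @return a `shared_tensor` over L whose elements reconstruct to raw 0/1
#' @export
mpc_msb <- function(sess, x) {
  if (!identical(x$ring, "L")) stop("mpc_msb expects shares over L")
  count_invocation(sess, "MSB")
  spec <- sess$ring
  n <- spec$n
  m <- shared_length(x)
  Kv <- rg_from_dbl(2^(n - 1), n)

  d <- new_shared(rg_mod2m(unclass_ring(x$s0), n - 1L),
                  rg_mod2m(unclass_ring(x$s1), n - 1L), spec, "K", x$dims)
  D <- mpc_moc(sess, d)
  z0 <- rg_sub(unclass_ring(x$s0), unclass_ring(D$s0), n)
  z1 <- rg_sub(unclass_ring(x$s1), unclass_ring(D$s1), n)

  # two candidates in tape-randomized order; both proxies know the order
  pi_ <- tape_bits(sess, m)
  zK <- rg_add(z0, Kv, n)
  first <- z0; second <- zK
  swap <- pi_ == 1L
  first[swap] <- zK[swap]; second[swap] <- z0[swap]
  cand <- msg_transfer(sess, "P0", "P2", "MSB", c(first, second))
  z1r <- msg_transfer(sess, "P1", "P2", "MSB", z1)

  s1v <- rg_add(cand[1:m], z1r, n)
  s2v <- rg_add(cand[m + 1:m], z1r, n)
  zero <- rg_from_dbl(0, n)
  ok <- (rg_eq(s1v, rep(zero, m)) | rg_eq(s1v, rep(unclass(Kv), m))) &
        (rg_eq(s2v, rep(zero, m)) | rg_eq(s2v, rep(unclass(Kv), m)))
  if (!all(ok)) stop("msb internal error: candidate not in {0, K}")
  m1 <- rg_from_dbl(as.numeric(rg_eq(s1v, rep(unclass(Kv), m))), n)
  m2 <- rg_from_dbl(as.numeric(rg_eq(s2v, rep(unclass(Kv), m))), n)
  a10 <- rng_next(sess$rng$P2, m, n); a11 <- rg_sub(m1, a10, n)
  a20 <- rng_next(sess$rng$P2, m, n); a21 <- rg_sub(m2, a20, n)
  at0 <- msg_transfer(sess, "P2", "P0", "MSB", c(a10, a20))
  at1 <- msg_transfer(sess, "P2", "P1", "MSB", c(a11, a21))

  out0 <- at0[1:m]; out0[swap] <- at0[m + 1:m][swap]
  out1 <- at1[1:m]; out1[swap] <- at1[m + 1:m][swap]
  new_shared(out0, out1, spec, "L", x$dims)
}

#' Secure comparison
#'
#' Returns shares of the bit `(x > y)`: the most significant bit of `y - x`.
#' Requires `|x - y| < 2^(n-1-f)` in decoded terms.
#'
#' @param sess an [mpc_session()]
#' @param x,y `shared_tensor`s over L (fixed-point values)
#' @return a `shared_tensor` over L reconstructing to raw 0/1
#' @export
mpc_cmp <- function(sess, x, y) {
  check_same_ring(x, y)
  count_invocation(sess, "CMP")
  mpc_msb(sess, mpc_sub(sess, y, x))
}

# ---- multiplexer ------------------------------------------------------------

#' Secure multiplexer (oblivious selection)
#'
#' Computes shares of `z = x - b*(x - y)`, i.e. `x` when `b = 0` and `y` when
#' `b = 1`, with the two cross-party products outsourced to the helper through
#' a randomized encoding: P0 sends `M2 = <b>0 + r0`, `M3 = (<x>0 - <y>0) +
#' r3`; P1 sends `M5 = (<x>1 - <y>1) + r1`, `M6 = <b>1 + r2`; the helper
#' returns fresh shares of `M2*M5 + M3*M6` and the proxies cancel the tape
#' terms locally. The selector is a raw ring bit (the output format of
#' [mpc_msb()]/[mpc_cmp()]), so no truncation is needed.
#'
#' @param sess an [mpc_session()]
#' @param x,y `shared_tensor`s over L
#' @param b a `shared_tensor` over L reconstructing to 0/1 per element
#' @return a `shared_tensor` of the selected values
#' @export
mpc_mux <- function(sess, x, y, b) {
  check_same_ring(x, y); check_same_ring(x, b)
  count_invocation(sess, "MUX")
  spec <- sess$ring
  nb <- ring_bits(spec, x$ring)
  m <- shared_length(x)

  r0 <- rng_next(sess$tape, m, nb); r1 <- rng_next(sess$tape, m, nb)
  r2 <- rng_next(sess$tape, m, nb); r3 <- rng_next(sess$tape, m, nb)
  d0 <- rg_sub(unclass_ring(x$s0), unclass_ring(y$s0), nb)
  d1 <- rg_sub(unclass_ring(x$s1), unclass_ring(y$s1), nb)
  b0 <- unclass_ring(b$s0); b1 <- unclass_ring(b$s1)

  M2 <- msg_transfer(sess, "P0", "P2", "MUX", rg_add(b0, r0, nb))
  M3 <- msg_transfer(sess, "P0", "P2", "MUX", rg_add(d0, r3, nb))
  M5 <- msg_transfer(sess, "P1", "P2", "MUX", rg_add(d1, r1, nb))
  M6 <- msg_transfer(sess, "P1", "P2", "MUX", rg_add(b1, r2, nb))

  H <- rg_add(rg_mul(M2, M5, nb), rg_mul(M3, M6, nb), nb)
  H0 <- rng_next(sess$rng$P2, m, nb)
  H1 <- rg_sub(H, H0, nb)
  H0 <- msg_transfer(sess, "P2", "P0", "MUX", H0)
  H1 <- msg_transfer(sess, "P2", "P1", "MUX", H1)

  # local completion with the tape terms of Eq. 2
  z0 <- mux_local(unclass_ring(x$s0), b0, d0, r1, r2,
                  rg_mul(r2, r3, nb), H0, nb)
  z1 <- mux_local(unclass_ring(x$s1), b1, d1, r3, r0,
                  rg_mul(r0, r1, nb), H1, nb)
  new_shared(z0, z1, spec, x$ring, x$dims)
}

# ---- exact exponential ------------------------------------------------------

# contribution window: highest integer bit weight i with base^(2^i) encodable
exp_window <- function(spec, base) {
  lim <- 2^(spec$n - 1L - spec$f)
  imax <- -1L
  while (base^(2^(imax + 1L)) < lim && imax + 1L + spec$f < spec$n - 1L)
    imax <- imax + 1L
  if (imax < 0L) stop("exp base too large for this ring spec")
  imax
}

#' Secure exponential of a public base to a shared power
#'
#' Exact square-and-multiply-style exponentiation: one MSB gives the sign; one
#' vectorized MUX selects the power/|power| together with the matching per-bit
#' contribution table (`Cp[i] = base^(2^(i-f))` for positive powers, `Cn[i] =
#' base^(-2^(i-f))` for negative ones, one proxy holding the table, the other
#' zeros); one vectorized MSB over left-shifted copies of the power exposes
#' every covered bit; one vectorized MUX picks contribution-or-1 per bit; and
#' a binary tree of `log2(table size)` vectorized MUL calls multiplies the
#' selected contributions.
#'
#' Valid domain: the covered bit window spans weights `2^-f .. 2^imax` where
#' `imax` is the largest integer exponent with `base^(2^imax)` representable
#' (defaults: 25 entries, padded to 32, for base e at n = 64, f = 20); callers
#' must keep `|power|` below `2^(imax+1)` and the result representable
#' (|power| < 30 for base e at the defaults). This cannot be checked privately.
#'
#' @param sess an [mpc_session()]
#' @param x a `shared_tensor` over L holding the fixed-point powers
#' @param base public base (default: the session's, normally e)
#' @return a `shared_tensor` of `base^x`
#' @export
mpc_exp <- function(sess, x, base = sess$exp_base) {
  if (!identical(x$ring, "L")) stop("mpc_exp expects shares over L")
  count_invocation(sess, "EXP")
  spec <- sess$ring
  n <- spec$n; f <- spec$f
  m <- shared_length(x)
  imax <- exp_window(spec, base)
  pvals <- (f + imax):0                    # covered bit positions, MSB first
  T <- length(pvals)

  Cp <- rg_encode(base^(2^(pvals - f)), n, f)
  Cn <- rg_encode(base^(-(2^(pvals - f))), n, f)
  one <- rg_encode(1, n, f)

  # (1) sign of the power
  s <- mpc_msb(sess, x)

  # (2) one vectorized MUX: [x | Cp-table] vs [-x | Cn-table], selector = sign
  negx <- mpc_neg(sess, x)
  cand_pos <- shared_bind(x, shared_public(sess, rep(Cp, each = m)))
  cand_neg <- shared_bind(negx, shared_public(sess, rep(Cn, each = m)))
  sel <- new_shared(rep(unclass_ring(s$s0), T + 1L),
                    rep(unclass_ring(s$s1), T + 1L), spec, "L")
  picked <- mpc_mux(sess, cand_pos, cand_neg, sel)
  a <- shared_subset(picked, 1:m)                       # |x| as needed
  Csel <- shared_subset(picked, m + 1:(m * T))          # m x T, element-major

  # (3) every covered bit of a, via one vectorized MSB over shifted copies
  sh0 <- unlist(lapply(pvals, function(p) rg_shl(unclass_ring(a$s0), n - 1L - p, n)))
  sh1 <- unlist(lapply(pvals, function(p) rg_shl(unclass_ring(a$s1), n - 1L - p, n)))
  bits <- mpc_msb(sess, new_shared(sh0, sh1, spec, "L"))

  # (4) contribution-or-one per bit, one vectorized MUX
  ones <- shared_public(sess, rep(one, m * T))
  fac <- mpc_mux(sess, ones, Csel, bits)

  # (5) binary-tree product, padded with encoded ones
  P <- 2^ceiling(log2(T))
  pad <- shared_public(sess, rep(one, m * (P - T)))
  prod <- shared_bind(fac, pad)                          # m x P element-major
  width <- P
  while (width > 1L) {
    half <- width %/% 2L
    lo <- shared_subset(prod, 1:(m * half))
    hi <- shared_subset(prod, m * half + 1:(m * half))
    prod <- mpc_mul(sess, lo, hi)
    width <- half
  }
  new_shared(unclass_ring(prod$s0), unclass_ring(prod$s1), spec, "L", x$dims)
}
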