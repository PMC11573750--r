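# Shared tensors: the simulator's container for one secret value (scalar,
# vector or matrix) split into the two proxies' additive shares. The helper
# never appears here; it only sees masked messages inside the protocols.

new_shared <- function(s0, s1, spec, ring = "L", dims = NULL) {
  if (length(s0) != length(s1)) stop("share length mismatch")
  structure(list(s0 = as_ring64(s0), s1 = as_ring64(s1),
                 spec = spec, ring = ring,
                 dims = dims %||% length(s0)),
            class = "shared_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.shared_tensor <- function(x, ...) {
  cat(sprintf("<shared_tensor> ring %s, dims [%s]\n", x$ring,
              paste(x$dims, collapse = " x ")))
  invisible(x)
}

shared_length <- function(st) length(st$s0)

check_same_ring <- function(a, b) {
  if (!identical(a$ring, b$ring) || !identical(a$spec$n, b$spec$n))
    stop("operands live in different rings")
}

#' Share fixed-point values into a session
#'
#' Encodes reals in the session's fixed-point format and additively shares
#' them between the proxies, as a data or model owner would before
#' outsourcing. The masking randomness comes from `rng` (the owner's own
#' stream), not from the proxies' tape.
#'
#' @param sess an [mpc_session()]
#' @param x numeric scalar, vector or matrix
#' @param rng an [rng_stream()]; defaults to a stream derived from P0's
#' @return a `shared_tensor` over the L ring
#' @export
mpc_share <- function(sess, x, rng = sess$rng$P0) {
  raw <- rg_encode(as.numeric(x), sess$ring$n, sess$ring$f)
  sh <- share_additive(as_ring64(raw), sess$ring, "L", rng)
  new_shared(sh$s0, sh$s1, sess$ring, "L", dims = dim(x) %||% length(raw))
}

#' Share raw ring elements into a session
#'
#' Like [mpc_share()] but without fixed-point encoding: the inputs are taken
#' as raw ring words (e.g. selection bits).
#'
#' @inheritParams mpc_share
#' @param ring `"L"` or `"K"`
#' @export
mpc_share_raw <- function(sess, x, ring = "L", rng = sess$rng$P0) {
  sh <- share_additive(x, sess$ring, ring, rng)
  new_shared(sh$s0, sh$s1, sess$ring, ring, dims = dim(x) %||% length(x))
}

# share of a public constant: P0 holds the value, P1 holds zeros -- a valid
# additive sharing (used for the exponential tables and the c_0 row of ones)
shared_public <- function(sess, raw, dims = NULL) {
  z <- as_ring64(rg_from_dbl(numeric(length(raw)), sess$ring$n))
  new_shared(as_ring64(raw), z, sess$ring, "L", dims = dims %||% length(raw))
}

#' Reveal (reconstruct) a shared tensor
#'
#' Adds the two shares modulo the ring size; this is what the data owner does
#' after receiving both prediction shares.
#'
#' @param sess an [mpc_session()]
#' @param st a `shared_tensor`
#' @return `ring64` vector/matrix of raw secrets
#' @export
mpc_reveal <- function(sess, st) {
  count_invocation(sess, "RECONSTRUCT")
  out <- reconstruct(st$s0, st$s1, st$spec, st$ring)
  if (length(st$dims) > 1L) dim(out) <- st$dims
  out
}

#' Reveal and decode a fixed-point shared tensor
#'
#' @inheritParams mpc_reveal
#' @return numeric vector/matrix
#' @export
mpc_decode <- function(sess, st) {
  out <- rg_decode(unclass_ring(mpc_reveal(sess, st)), st$spec$n, st$spec$f)
  if (length(st$dims) > 1L) dim(out) <- st$dims
  out
}

# subset a shared tensor by flat indices (local, both parties)
shared_subset <- function(st, idx, dims = NULL) {
  new_shared(st$s0[idx], st$s1[idx], st$spec, st$ring,
             dims = dims %||% length(idx))
}

shared_bind <- function(a, b) {
  check_same_ring(a, b)
  new_shared(c(unclass_ring(a$s0), unclass_ring(b$s0)),
             c(unclass_ring(a$s1), unclass_ring(b$s1)),
             a$spec, a$ring)
}
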