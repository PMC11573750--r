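#' Open a three-party computation session
#'
#' A session holds the state of the two proxies (P0, P1) and the helper (P2):
#' the proxies' common randomness tape (seeded by `seed_common`, never visible
#' to the helper), the helper's own dealing stream, per-protocol transcript
#' counters, and the transport that carries every inter-party message.
#'
#' Two transports are available. `"inproc"` moves payloads directly between
#' the simulated parties. `"socket"` frames every payload (4-byte little-endian
#' length prefix, little-endian 64-bit words) and routes it through a real
#' localhost TCP connection before delivery, so the byte-level wire format is
#' exercised; both transports produce identical transcripts for equal seeds.
#'
#' @param ring a [ring_spec()]
#' @param seeds named integer vector or list with entries `common`, `p0`,
#'   `p1`, `p2`; a single unnamed integer is expanded deterministically
#' @param transport `"inproc"` or `"socket"`
#' @param log_helper if `TRUE`, every payload the helper receives is kept in
#'   the transcript (used by the uniformity/privacy tests; off by default to
#'   bound memory)
#' @param exp_base base of the secure exponential (default `exp(1)`)
#' @return an environment of class `mpc_session`
#' @examples
#' sess <- mpc_session(ring_spec(8, 0), seeds = 7)
#' x <- mpc_share_raw(sess, ring_elem(5, sess$ring))
#' y <- mpc_share_raw(sess, ring_elem(9, sess$ring))
#' as.numeric(rg_to_dbl(mpc_reveal(sess, mpc_add(sess, x, y))))
#' close_session(sess)
#' @export
mpc_session <- function(ring = ring_spec(), seeds = 1L,
                        transport = c("inproc", "socket"),
                        log_helper = FALSE, exp_base = exp(1)) {
  transport <- match.arg(transport)
  if (length(seeds) == 1L && is.null(names(seeds))) {
    s <- as.integer(seeds)
    seeds <- list(common = s, p0 = s + 101L, p1 = s + 202L, p2 = s + 303L)
  }
  seeds <- as.list(seeds)
  stopifnot(all(c("common", "p0", "p1", "p2") %in% names(seeds)))

  sess <- new.env(parent = emptyenv())
  sess$ring <- ring
  sess$transport <- transport
  sess$exp_base <- exp_base
  sess$log_helper <- isTRUE(log_helper)
  sess$helper_log <- list()
  # common tape shared by P0/P1; the helper has its own independent stream
  sess$tape <- rng_stream(seeds$common)
  sess$rng <- list(P0 = rng_stream(seeds$p0), P1 = rng_stream(seeds$p1),
                   P2 = rng_stream(seeds$p2))
  sess$counters <- new.env(parent = emptyenv())
  sess$open <- TRUE
  if (transport == "socket") {
    sock <- open_loopback_pair()
    sess$sock_out <- sock$out
    sess$sock_in <- sock$in_
    sess$sock_srv <- sock$srv
  }
  class(sess) <- "mpc_session"
  sess
}

#' @export
print.mpc_session <- function(x, ...) {
  cat(sprintf("<mpc_session> ring n=%d f=%d, transport=%s, open=%s\n",
              x$ring$n, x$ring$f, x$transport, x$open))
  invisible(x)
}

#' Close a session and release its transport
#' @param sess an [mpc_session()]
#' @export
close_session <- function(sess) {
  if (identical(sess$transport, "socket") && isTRUE(sess$open)) {
    close(sess$sock_in)
    close(sess$sock_out)
    close(sess$sock_srv)
  }
  sess$open <- FALSE
  invisible(sess)
}

open_loopback_pair <- function() {
  for (attempt in 1:32) {
    port <- 40000L + (Sys.getpid() * 7L + attempt * 131L) %% 20000L
    srv <- tryCatch(serverSocket(port), error = function(e) NULL)
    if (is.null(srv)) next
    out <- socketConnection("127.0.0.1", port = port, blocking = FALSE,
                            open = "a+b")
    in_ <- socketAccept(srv, blocking = TRUE, open = "a+b")
    return(list(out = out, in_ = in_, srv = srv))
  }
  stop("could not open a loopback TCP pair")
}

# ---- message routing ---------------------------------------------------------

payload_nbytes <- function(payload) {
  if (inherits(payload, "ring64") || is.double(payload)) {
    8L * length(payload)          # 64-bit words on the wire
  } else if (is.integer(payload) || is.logical(payload)) {
    length(payload)               # Z_67 / Boolean shares travel as bytes
  } else if (is.raw(payload)) {
    length(payload)
  } else stop("unsupported payload type")
}

# serialize through the loopback TCP pair and back (socket transport only)
socket_roundtrip <- function(sess, payload) {
  d <- dim(payload)
  if (is.raw(payload)) {
    bytes <- payload
  } else if (is.integer(payload) || is.logical(payload)) {
    bytes <- as.raw(as.integer(payload) %% 256L)
  } else {
    bytes <- writeBin(as.numeric(unclass(payload)), raw(), size = 8L,
                      endian = "little")
  }
  writeBin(c(writeBin(length(bytes), raw(), size = 4L, endian = "little"),
             bytes), sess$sock_out)
  flush(sess$sock_out)
  len <- readBin(sess$sock_in, "integer", 1L, size = 4L, endian = "little")
  got <- raw(0)
  while (length(got) < len) {
    chunk <- readBin(sess$sock_in, "raw", len - length(got))
    if (length(chunk) == 0L) Sys.sleep(0.001)
    got <- c(got, chunk)
  }
  if (is.raw(payload)) {
    out <- got
  } else if (is.integer(payload) || is.logical(payload)) {
    out <- as.integer(got)
    if (is.logical(payload)) out <- as.logical(out)
  } else {
    out <- readBin(got, "numeric", len %/% 8L, size = 8L, endian = "little")
    if (inherits(payload, "ring64")) out <- as_ring64(out)
  }
  dim(out) <- d
  out
}

# Route one message; returns the delivered payload. All byte/message
# accounting happens here, and helper-bound payloads are optionally logged.
msg_transfer <- function(sess, from, to, proto, payload) {
  ctr <- counter_env(sess, proto)
  ctr$messages <- ctr$messages + 1L
  ctr$bytes <- ctr$bytes + payload_nbytes(payload)
  delivered <- if (identical(sess$transport, "socket")) {
    socket_roundtrip(sess, payload)
  } else payload
  if (sess$log_helper && identical(to, "P2")) {
    sess$helper_log[[length(sess$helper_log) + 1L]] <-
      list(from = from, proto = proto, payload = delivered)
  }
  delivered
}

#' Symmetric payload exchange between the proxies
#'
#' Both proxies send a payload to the other and receive the counterpart's,
#' as in the share-opening steps of the protocols.
#'
#' @param sess an [mpc_session()]
#' @param from_p0 payload P0 sends
#' @param from_p1 payload P1 sends
#' @param proto protocol label for the transcript
#' @return list with `at_p0` (what P0 received) and `at_p1`
#' @export
mpc_exchange <- function(sess, from_p0, from_p1, proto = "EXCHANGE") {
  list(at_p1 = msg_transfer(sess, "P0", "P1", proto, from_p0),
       at_p0 = msg_transfer(sess, "P1", "P0", proto, from_p1))
}

# ---- transcript --------------------------------------------------------------

counter_env <- function(sess, proto) {
  if (is.null(sess$counters[[proto]]))
    sess$counters[[proto]] <- new.env(parent = emptyenv())
  e <- sess$counters[[proto]]
  if (is.null(e$invocations)) {
    e$invocations <- 0L
    e$messages <- 0L
    e$bytes <- 0
  }
  e
}

count_invocation <- function(sess, proto) {
  ctr <- counter_env(sess, proto)
  ctr$invocations <- ctr$invocations + 1L
  invisible(NULL)
}

#' Transcript counters of a session
#'
#' One row per protocol: number of top-level vectorized invocations (a batched
#' call over a whole vector counts once), messages routed and bytes moved.
#'
#' @param sess an [mpc_session()]
#' @return a data.frame with columns `protocol`, `invocations`, `messages`,
#'   `bytes`
#' @export
transcript <- function(sess) {
  protos <- sort(ls(sess$counters))
  out <- data.frame(
    protocol = protos,
    invocations = vapply(protos, function(p) sess$counters[[p]]$invocations,
                         integer(1)),
    messages = vapply(protos, function(p) sess$counters[[p]]$messages,
                      integer(1)),
    bytes = vapply(protos, function(p) sess$counters[[p]]$bytes, numeric(1)),
    row.names = NULL)
  out
}

#' Number of top-level invocations of one protocol
#'
#' @param sess an [mpc_session()]
#' @param proto protocol name, e.g. `"MUL"`, `"MSB"`, `"MUX"`, `"EXP"`
#' @return integer count (0 if the protocol never ran)
#' @export
count_invocations <- function(sess, proto) {
  known <- c("ADD", "MUL", "MP", "MOC", "MSB", "CMP", "MUX", "EXP", "PC",
             "EXCHANGE", "RECONSTRUCT")
  if (!proto %in% known && is.null(sess$counters[[proto]]))
    stop("unknown protocol: ", proto)
  if (is.null(sess$counters[[proto]])) return(0L)
  sess$counters[[proto]]$invocations
}

#' Reset transcript counters (and the helper log)
#' @param sess an [mpc_session()]
#' @export
reset_transcript <- function(sess) {
  rm(list = ls(sess$counters), envir = sess$counters)
  sess$helper_log <- list()
  invisible(sess)
}

# tape draws (identical streams on P0 and P1; the helper never touches these)
tape_elems <- function(sess, count, ring = "L") {
  as_ring64(rng_next(sess$tape, count, ring_bits(sess$ring, ring)))
}
tape_bits <- function(sess, count) {
  rng_next_int(sess$tape, count, 2L)
}
tape_scalars_v <- function(sess, count) {
  rng_next_int(sess$tape, count, sess$ring$V - 1L) + 1L   # 1..66
}
tape_perms <- function(sess, nbits, m) {
  rng_next_perm(sess$tape, nbits, m)
}

# helper draws (P2's independent stream)
helper_elems <- function(sess, count, ring = "L") {
  as_ring64(rng_next(sess$rng$P2, count, ring_bits(sess$ring, ring)))
}
helper_ints <- function(sess, count, modulus) {
  rng_next_int(sess$rng$P2, count, modulus)
}
helper_bits <- function(sess, count) {
  rng_next_int(sess$rng$P2, count, 2L)
}
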