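# Synthetic data generation: models with the parameter shapes a trained RKN
# would have, uniform random protein sequences, and the invocation-count
# scaling report that stands in for wall-clock benchmarks.

# run code under a temporary R RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic RKN model
#'
#' Anchor characters are drawn standard normal and normalized to unit rows;
#' the gram matrix of the anchor points is the kernel gram
#' `exp(alpha * (<z_i, z_j> - k))` (strictly positive definite for distinct
#' anchors), inverted through an eigendecomposition with eigenvalue floor
#' `1e-6`; classifier weights and bias are standard normal. Deterministic in
#' `seed`.
#'
#' @param q number of anchor points
#' @param k motif (k-mer) length
#' @param alpha similarity scale (default 0.6)
#' @param lambda gap factor (default 0.5)
#' @param alphabet residue alphabet (default 20 standard amino acids)
#' @param seed integer seed
#' @return an [rkn_model()]
#' @export
generate_rkn_model <- function(q, k, alpha = 0.6, lambda = 0.5,
                               alphabet = AA_ALPHABET20, seed = 1L) {
  stopifnot(q >= 1L, k >= 1L)
  A <- length(alphabet)
  with_local_seed(seed, {
    Z <- matrix(stats::rnorm(k * q * A), nrow = k * q, ncol = A)
    Z <- Z / sqrt(rowSums(Z^2))
    # per-anchor flattened vectors: anchor i occupies rows (j-1)*q + i
    Zf <- do.call(cbind, lapply(seq_len(k), function(j)
      Z[(j - 1L) * q + seq_len(q), , drop = FALSE]))
    gram <- exp(alpha * (tcrossprod(Zf) - k))
    eig <- eigen(gram, symmetric = TRUE)
    vals <- pmax(eig$values, 1e-6)
    G <- eig$vectors %*% (t(eig$vectors) / sqrt(vals))
    G <- (G + t(G)) / 2
    w <- stats::rnorm(q)
    beta <- stats::rnorm(1)
    rkn_model(Z, alpha, lambda, G, w, beta, k = k, q = q, alphabet = alphabet)
  })
}

#' Generate synthetic protein sequences
#'
#' Characters are i.i.d. uniform over the alphabet. Either a fixed `length`
#' or a `len_range` (one uniform draw per sequence) can be given.
#' Deterministic in `seed`.
#'
#' @param n number of sequences
#' @param length fixed sequence length (e.g. 128)
#' @param len_range integer vector `c(min, max)`; ignored when `length` given
#' @param alphabet residue alphabet
#' @param seed integer seed
#' @return named character vector (`seq1`, `seq2`, ...)
#' @export
generate_sequences <- function(n, length = NULL, len_range = NULL,
                               alphabet = AA_ALPHABET20, seed = 1L) {
  if (is.null(length) && is.null(len_range))
    stop("give either `length` or `len_range`")
  with_local_seed(seed, {
    lens <- if (!is.null(length)) rep(as.integer(length), n)
            else sample(len_range[1]:len_range[2], n, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
    stats::setNames(seqs, paste0("seq", seq_len(n)))
  })
}

#' Invocation-count scaling report
#'
#' Runs the private forward pass over a grid in one RKN parameter (number of
#' anchors `q`, motif length `k`, or sequence length `len`) with the other
#' two fixed, and tabulates per-protocol invocation counts and communication
#' bytes from the session transcript. Counts and bytes are deterministic
#' given the circuit, so they are the portable proxy for execution-time
#' scaling: invocation counts grow with `len` (one exponential batch per
#' position) while communicated bytes grow with each of `q`, `k` and `len`.
#'
#' @param vary one of `"q"`, `"k"`, `"len"`
#' @param values grid of values for the varied parameter
#' @param fixed named list of the fixed values (default all 8)
#' @param ring a [ring_spec()]
#' @param seed integer seed for model/sequence/session randomness
#' @return data.frame with one row per grid point: the varied value,
#'   `EXP`/`MUL`/`MUX`/`MSB`/`MP` invocation counts, per-protocol bytes, and
#'   `total_bytes`
#' @export
scaling_report <- function(vary = c("q", "k", "len"), values,
                           fixed = list(q = 8L, k = 8L, len = 8L),
                           ring = ring_spec(), seed = 1L) {
  vary <- match.arg(vary)
  protos <- c("EXP", "MUL", "MUX", "MSB", "MP")
  rows <- lapply(values, function(v) {
    p <- fixed
    p[[vary]] <- v
    model <- generate_rkn_model(q = p$q, k = p$k, seed = seed)
    seqs <- generate_sequences(1L, length = p$len, seed = seed + 1L)
    sess <- mpc_session(ring, seeds = seed)
    sm <- outsource_model(sess, model)
    sq <- outsource_sequence(sess, seqs[[1]])
    reset_transcript(sess)                     # count inference only
    invisible(private_forward(sess, sm, sq))
    tr <- transcript(sess)
    close_session(sess)
    counts <- stats::setNames(
      vapply(protos, function(pr)
        if (pr %in% tr$protocol) tr$invocations[tr$protocol == pr] else 0L,
        integer(1)), protos)
    bytes <- stats::setNames(
      vapply(protos, function(pr)
        if (pr %in% tr$protocol) tr$bytes[tr$protocol == pr] else 0,
        numeric(1)), paste0(protos, "_bytes"))
    data.frame(vary = vary, value = v, t(counts), t(bytes),
               total_bytes = sum(tr$bytes))
  })
  do.call(rbind, rows)
}

#' R-squared of a straight-line fit
#'
#' Helper for the linearity checks: ordinary least squares of `y` on `x`,
#' with the convention that an exactly constant `y` (zero total variance) is
#' a perfect line, R-squared 1.
#'
#' @param x,y numeric vectors
#' @return R-squared in `[0, 1]`
#' @export
linear_fit_r2 <- function(x, y) {
  sst <- sum((y - mean(y))^2)
  if (sst < .Machine$double.eps * max(1, sum(y^2))) return(1)
  fit <- stats::lm(y ~ x)
  1 - sum(stats::residuals(fit)^2) / sst
}
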