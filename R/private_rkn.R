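# Private RKN inference: the model owner and the data owner secret-share
# their inputs to the proxies, which walk the RKN circuit with the secure
# building blocks and end up holding shares of the prediction. Only the data
# owner, holding both prediction shares, can reconstruct the score.

#' Secret-share an RKN model into a session
#'
#' Every tensor (anchor matrix, gram inverse square root, classifier weights
#' and bias) is fixed-point encoded and additively shared; the scalars alpha
#' and lambda stay plaintext at the proxies, as does the exponential base.
#'
#' @param sess an [mpc_session()]
#' @param model an [rkn_model()]
#' @param rng the model owner's [rng_stream()] (masking randomness)
#' @return an object of class `shared_rkn_model`
#' @export
outsource_model <- function(sess, model, rng = sess$rng$P0) {
  validate_rkn_model(model)
  if (2 * model$alpha >= 2^(exp_window(sess$ring, sess$exp_base) + 1L))
    stop("alpha too large for the exponential coverage window")
  sm <- structure(list(
    Z = mpc_share(sess, model$Z, rng),
    G = mpc_share(sess, model$G, rng),
    w = mpc_share(sess, matrix(model$w, nrow = 1L), rng),
    beta = mpc_share(sess, model$beta, rng),
    alpha = model$alpha, lambda = model$lambda,
    k = model$k, q = model$q, alphabet = model$alphabet),
    class = "shared_rkn_model")
  sm
}

#' Secret-share a protein sequence into a session
#'
#' The sequence is one-hot encoded, fixed-point encoded and additively
#' shared row by row.
#'
#' @param sess an [mpc_session()]
#' @param seq sequence string (or prebuilt one-hot matrix)
#' @param alphabet residue alphabet
#' @param rng the data owner's [rng_stream()]
#' @return an object of class `shared_sequence`
#' @export
outsource_sequence <- function(sess, seq, alphabet = AA_ALPHABET20,
                               rng = sess$rng$P1) {
  x <- if (is.character(seq)) one_hot_encode(seq, alphabet) else seq
  structure(list(onehot = mpc_share(sess, x, rng), len = nrow(x),
                 A = ncol(x)),
            class = "shared_sequence")
}

#' Private RKN forward pass
#'
#' Executes the RKN circuit on shares. Per position: one matrix product for
#' the `k*q` anchor-character dot products, a local affine step (subtract the
#' encoded 1, scale by alpha, fused into one truncation), one vectorized
#' exponential, one batched elementwise multiplication for
#' `b_j[t] * c_{j-1}[t-1]`, and a local lambda-scaled addition for the
#' recurrence. After the last position: one matrix product with the gram
#' inverse square root and one dot product with the classifier weights.
#'
#' @param sess an [mpc_session()]
#' @param smodel a `shared_rkn_model` from [outsource_model()]
#' @param sseq a `shared_sequence` from [outsource_sequence()]
#' @return an object of class `prediction_shares` (fields `s0`, `s1`)
#' @export
private_forward <- function(sess, smodel, sseq) {
  spec <- sess$ring
  k <- smodel$k; q <- smodel$q
  len <- sseq$len; A <- sseq$A
  if (!identical(A, length(smodel$alphabet))) stop("alphabet size mismatch")
  enc_alpha <- smodel$alpha

  # c rows 0..k, element layout (k+1) x q column-major... kept as flat
  # vectors: index (j, i) -> j + (k+1)*(i-1) avoided; use row-block layout
  # [j = 0 row | j = 1 row | ...], each of length q.
  one <- rg_encode(1, spec$n, spec$f)
  c_cur <- shared_bind(shared_public(sess, rep(one, q)),
                       mpc_share(sess, matrix(0, k, q), sess$rng$P0))

  for (t in seq_len(len)) {
    xt <- shared_subset(sseq$onehot, seq.int(t, by = len, length.out = A),
                        dims = c(A, 1L))
    dots <- mpc_matmul(sess, smodel$Z, xt)             # (k*q) x 1
    # fused affine: alpha * (dots - 1), one local truncation
    pow <- mpc_scale_public(sess, mpc_add_public(sess, dots, -1), enc_alpha)
    b <- mpc_exp(sess, pow)                            # row-block j-major
    # b index (j-1)*q + i ; c_{j-1} occupies the same flat positions in c_cur
    prev <- shared_subset(c_cur, 1:(k * q))            # rows 0..k-1
    hi <- shared_subset(c_cur, q + 1:(k * q))          # rows 1..k
    # lambda*c_j + b_j*c_{j-1}, fused into a single truncation
    upd <- mpc_mul_add_scaled(sess, b, prev, hi, smodel$lambda)
    c_cur <- shared_bind(shared_subset(c_cur, 1:q), upd)
  }

  ck <- shared_subset(c_cur, k * q + 1:q, dims = c(q, 1L))
  psi <- mpc_matmul(sess, smodel$G, ck)                # q x 1
  score <- mpc_matmul(sess, smodel$w, psi)             # 1 x 1
  pred <- mpc_add(sess, score, smodel$beta)
  structure(list(s0 = pred$s0, s1 = pred$s1, spec = spec),
            class = "prediction_shares")
}

#' Reconstruct a prediction from its two shares
#'
#' @param p a `prediction_shares` object (or two `ring64` scalars)
#' @param s1 second share if `p` is the first
#' @param spec a [ring_spec()] (taken from `p` when available)
#' @return numeric prediction score
#' @export
reconstruct_prediction <- function(p, s1 = NULL, spec = NULL) {
  if (inherits(p, "prediction_shares")) {
    spec <- p$spec; s0 <- p$s0; s1 <- p$s1
  } else {
    s0 <- p
    if (is.null(spec)) spec <- ring_spec()
  }
  raw <- reconstruct(s0, s1, spec, "L")
  as.numeric(rg_decode(unclass_ring(raw), spec$n, spec$f))
}

#' Compare private inference against the plaintext oracle
#'
#' Generates random synthetic models and sequences, runs both the three-party
#' private forward pass and the double-precision plaintext forward pass, and
#' reports the largest absolute prediction difference.
#'
#' @param trials number of (model, sequence) pairs
#' @param q_grid,k_grid anchor-count and motif-length values cycled over
#' @param len_range sequence length range (inclusive)
#' @param alpha,lambda model scalars
#' @param seed base seed; trial i uses seed + i for model, sequence and
#'   session randomness
#' @param ring a [ring_spec()]
#' @param transport transport to run the sessions on
#' @param progress print one line per trial
#' @return list with `max_abs_diff`, and a data.frame `details` (q, k, len,
#'   private and plaintext predictions, difference)
#' @export
verify_private_inference <- function(trials = 50L, q_grid = c(8L, 32L, 128L),
                                     k_grid = c(2L, 5L, 10L),
                                     len_range = c(30L, 200L),
                                     alpha = 0.6, lambda = 0.5, seed = 1L,
                                     ring = ring_spec(),
                                     transport = "inproc",
                                     progress = FALSE) {
  res <- vector("list", trials)
  for (i in seq_len(trials)) {
    si <- seed + i
    cfg_rng <- rng_stream(si * 7919L)
    qq <- q_grid[1L + rng_next_int(cfg_rng, 1L, length(q_grid))]
    kk <- k_grid[1L + rng_next_int(cfg_rng, 1L, length(k_grid))]
    len <- len_range[1] +
      rng_next_int(cfg_rng, 1L, len_range[2] - len_range[1] + 1L)
    model <- generate_rkn_model(q = qq, k = kk, alpha = alpha,
                                lambda = lambda, seed = si)
    seqs <- generate_sequences(1L, length = len, seed = si + 5000L)
    plain <- rkn_forward(model, seqs[[1]])$prediction

    sess <- mpc_session(ring, seeds = si, transport = transport)
    sm <- outsource_model(sess, model)
    sq <- outsource_sequence(sess, seqs[[1]])
    priv <- reconstruct_prediction(private_forward(sess, sm, sq))
    close_session(sess)

    res[[i]] <- data.frame(q = qq, k = kk, len = len, private = priv,
                           plaintext = plain, diff = abs(priv - plain))
    if (progress)
      message(sprintf("trial %d: q=%d k=%d len=%d |diff|=%.3g",
                      i, qq, kk, len, abs(priv - plain)))
  }
  details <- do.call(rbind, res)
  list(max_abs_diff = max(details$diff), details = details)
}
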