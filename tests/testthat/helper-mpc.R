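# shared test helpers: tiny-ring fixtures and oracle utilities

rs8 <- ring_spec(8L, 0L)      # raw integer arithmetic on an exhaustible ring
rs64 <- ring_spec()           # production spec: n = 64, f = 20

# unsigned value(s) of a ring64 vector / shared tensor as plain doubles
rval <- function(x) secureRKN:::rg_to_dbl(unclass(x))
reveal_num <- function(sess, st) rval(mpc_reveal(sess, st))

# shared tensor over K from raw values (for MOC input)
share_over_K <- function(sess, vals, rng = rng_stream(99L)) {
  mpc_share_raw(sess, ring_elem(vals, sess$ring, "K"), ring = "K", rng = rng)
}

# independent plaintext RKN oracle: naive scalar loops, kept deliberately
# separate from rkn_forward's vectorized implementation
rkn_oracle <- function(model, seq) {
  x <- one_hot_encode(seq, model$alphabet)
  k <- model$k; q <- model$q
  cc <- matrix(0, k + 1L, q); cc[1L, ] <- 1
  for (t in seq_len(nrow(x))) {
    prev <- cc
    for (j in seq_len(k)) {
      for (i in seq_len(q)) {
        z <- model$Z[(j - 1L) * q + i, ]
        b <- exp(model$alpha * (sum(z * x[t, ]) - 1))
        cc[j + 1L, i] <- model$lambda * prev[j + 1L, i] + b * prev[j, i]
      }
    }
  }
  psi <- as.numeric(model$G %*% cc[k + 1L, ])
  sum(model$w * psi) + model$beta
}

# number of length-k (ordered, gapped) subsequences of an n-character
# sequence, by direct recursion: the lambda = 1, alpha -> 0 limit of c_k
count_k_subsequences <- function(n, k) {
  if (k == 0L) return(1)
  if (n < k) return(0)
  count_k_subsequences(n - 1L, k) + count_k_subsequences(n - 1L, k - 1L)
}

chisq_uniform_p <- function(counts) {
  stats::chisq.test(counts, p = rep(1 / length(counts), length(counts)))$p.value
}
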