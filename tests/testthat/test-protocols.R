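# secure building blocks against plaintext oracles; exhaustive on the n=8
# ring where feasible, randomized sweeps at n=64

test_that("addition is local and exact", {
  sess <- mpc_session(rs8, seeds = 1)
  x <- mpc_share_raw(sess, ring_elem(c(2, 250), rs8))
  y <- mpc_share_raw(sess, ring_elem(c(3, 10), rs8))
  expect_equal(reveal_num(sess, mpc_add(sess, x, y)), c(5, (260 %% 256)))
  tr <- transcript(sess)
  expect_identical(sum(tr$messages[tr$protocol == "ADD"]), 0L)
  close_session(sess)
})

test_that("fixed-point multiplication matches plaintext within 2^-19", {
  sess <- mpc_session(rs64, seeds = 3)
  set.seed(12)
  x <- runif(1e4, -100, 100)
  y <- runif(1e4, -100, 100)
  sx <- mpc_share(sess, x); sy <- mpc_share(sess, y)
  got <- mpc_decode(sess, mpc_mul(sess, sx, sy))
  expect_lt(max(abs(got - x * y)), 2^-19 * 100)   # relative to |y| <= 100
  # the headline absolute contract on O(1) operands
  x1 <- runif(1e4, -1, 1); y1 <- runif(1e4, -1, 1)
  got1 <- mpc_decode(sess, mpc_mul(sess, mpc_share(sess, x1), mpc_share(sess, y1)))
  expect_lt(max(abs(got1 - x1 * y1)), 2^-19)
  # x * 0 = 0 and 2 * 3 = 6
  z <- mpc_decode(sess, mpc_mul(sess, mpc_share(sess, c(2, 5.5)),
                                mpc_share(sess, c(3, 0))))
  expect_equal(z, c(6, 0), tolerance = 2^-19)
  close_session(sess)
})

test_that("matrix product matches plaintext with one truncation per entry", {
  sess <- mpc_session(rs64, seeds = 4)
  set.seed(13)
  A <- matrix(runif(20, -2, 2), 5, 4)
  B <- matrix(runif(12, -2, 2), 4, 3)
  got <- mpc_decode(sess, mpc_matmul(sess, mpc_share(sess, A), mpc_share(sess, B)))
  expect_lt(max(abs(got - A %*% B)), 2^-19)
  # identity and one-hot selection
  I4 <- diag(4)
  gotI <- mpc_decode(sess, mpc_matmul(sess, mpc_share(sess, I4), mpc_share(sess, B)))
  expect_lt(max(abs(gotI - B)), 2^-19)
  e2 <- matrix(c(0, 1, 0, 0), 1, 4)
  v <- matrix(runif(4, -3, 3), 4, 1)
  gote <- mpc_decode(sess, mpc_matmul(sess, mpc_share(sess, e2), mpc_share(sess, v)))
  expect_lt(abs(gote - v[2]), 2^-19)
  close_session(sess)
})

test_that("private compare matches (x > r) exhaustively at n=8", {
  sess <- mpc_session(rs8, seeds = 5)
  rng <- rng_stream(50)
  grid <- expand.grid(x = 0:127, r = 0:127)
  bs <- share_bitwise(ring_elem(grid$x, rs8, "K"), rs8, rng)
  res <- private_compare(sess, bs, ring_elem(grid$r, rs8, "K"))
  expect_identical(bitwXor(res$c0, res$c1), as.integer(grid$x > grid$r))
  close_session(sess)
})

test_that("modulus conversion K -> L is exact for every secret at n=8", {
  # several share splits and helper randomness draws per secret
  for (seed in 1:3) {
    sess <- mpc_session(rs8, seeds = seed)
    st <- share_over_K(sess, 0:127, rng_stream(seed + 100L))
    out <- mpc_moc(sess, st)
    expect_identical(out$ring, "L")
    expect_equal(reveal_num(sess, out), 0:127)
    close_session(sess)
  }
})

test_that("MSB extracts the top bit for every ring element at n=8", {
  sess <- mpc_session(rs8, seeds = 6)
  st <- mpc_share_raw(sess, ring_elem(0:255, rs8))
  expect_equal(reveal_num(sess, mpc_msb(sess, st)),
               as.numeric(0:255 >= 128))
  close_session(sess)
  # fixed-point sign at n=64: negative values have MSB 1, zero has 0
  sess <- mpc_session(rs64, seeds = 6)
  st <- mpc_share(sess, c(-3, 0, 2.5, -1e-4))
  expect_equal(reveal_num(sess, mpc_msb(sess, st)), c(1, 0, 0, 1))
  close_session(sess)
})

test_that("comparison equals plaintext > on random signed pairs", {
  sess <- mpc_session(rs64, seeds = 7)
  set.seed(14)
  x <- c(round(runif(1e3, -50, 50), 3), 2, 1.25)
  y <- c(round(runif(1e3, -50, 50), 3), 1, 1.25)   # includes a tie -> 0
  got <- reveal_num(sess, mpc_cmp(sess, mpc_share(sess, x), mpc_share(sess, y)))
  expect_identical(got, as.numeric(x > y))
  close_session(sess)
})

test_that("MUX satisfies the reconstruction identity (1-b)x + by at n=8", {
  sess <- mpc_session(rs8, seeds = 8)
  set.seed(15)
  # every (x, y) value pair coverage via random sweep, both selector values,
  # random share splits
  for (rep in 1:4) {
    m <- 512
    x <- sample(0:255, m, replace = TRUE)
    y <- sample(0:255, m, replace = TRUE)
    b <- sample(0:1, m, replace = TRUE)
    rng <- rng_stream(300 + rep)
    sx <- mpc_share_raw(sess, ring_elem(x, rs8), rng = rng)
    sy <- mpc_share_raw(sess, ring_elem(y, rs8), rng = rng)
    sb <- mpc_share_raw(sess, ring_elem(b, rs8), rng = rng)
    got <- reveal_num(sess, mpc_mux(sess, sx, sy, sb))
    expect_identical(got, as.numeric(((1 - b) * x + b * y) %% 256))
  }
  close_session(sess)
})

test_that("exponential matches exp() and its multiplicative identity", {
  sess <- mpc_session(rs64, seeds = 9)
  x <- c(0, 1, -0.5, 3.25, -6)
  got <- mpc_decode(sess, mpc_exp(sess, mpc_share(sess, x)))
  expect_equal(got[1], 1, tolerance = 1e-5)
  expect_equal(got[2], exp(1), tolerance = 1e-4)
  expect_equal(got[3], exp(-0.5), tolerance = 1e-4)
  expect_lt(max(abs(got - exp(x)) / pmax(1, exp(x))), 1e-5)
  # exp(x) * exp(-x) reconstructs to 1 within twice the exp tolerance
  gneg <- mpc_decode(sess, mpc_exp(sess, mpc_share(sess, -x)))
  expect_lt(max(abs(got * gneg - 1)), 2e-4)
  # non-default base
  got2 <- mpc_decode(sess, mpc_exp(sess, mpc_share(sess, c(2, -1)), base = 2))
  expect_equal(got2, c(4, 0.5), tolerance = 1e-4)
  close_session(sess)
})

test_that("batched calls equal element-wise calls (batching soundness)", {
  x <- c(200, 3, 128, 77); y <- c(5, 250, 127, 77); b <- c(1, 0, 1, 0)
  batched <- {
    sess <- mpc_session(rs8, seeds = 10)
    out <- list(
      mux = reveal_num(sess, mpc_mux(sess,
        mpc_share_raw(sess, ring_elem(x, rs8), rng = rng_stream(1)),
        mpc_share_raw(sess, ring_elem(y, rs8), rng = rng_stream(2)),
        mpc_share_raw(sess, ring_elem(b, rs8), rng = rng_stream(3)))),
      msb = reveal_num(sess, mpc_msb(sess,
        mpc_share_raw(sess, ring_elem(x, rs8), rng = rng_stream(4)))))
    close_session(sess)
    out
  }
  elementwise <- lapply(seq_along(x), function(i) {
    sess <- mpc_session(rs8, seeds = 10 + i)
    out <- list(
      mux = reveal_num(sess, mpc_mux(sess,
        mpc_share_raw(sess, ring_elem(x[i], rs8), rng = rng_stream(1)),
        mpc_share_raw(sess, ring_elem(y[i], rs8), rng = rng_stream(2)),
        mpc_share_raw(sess, ring_elem(b[i], rs8), rng = rng_stream(3)))),
      msb = reveal_num(sess, mpc_msb(sess,
        mpc_share_raw(sess, ring_elem(x[i], rs8), rng = rng_stream(4)))))
    close_session(sess)
    out
  })
  expect_equal(batched$mux, vapply(elementwise, `[[`, numeric(1), "mux"))
  expect_equal(batched$msb, vapply(elementwise, `[[`, numeric(1), "msb"))
})

test_that("multiplication only reveals masked openings between proxies", {
  # structural check on the transcript: for MUL the proxies exchange exactly
  # one message each (the concatenated maskings), everything else is helper
  # traffic
  sess <- mpc_session(rs8, seeds = 11, log_helper = TRUE)
  x <- mpc_share_raw(sess, ring_elem(0:31, rs8))
  y <- mpc_share_raw(sess, ring_elem(31:0, rs8))
  invisible(mpc_mul(sess, x, y, truncate = FALSE))
  tr <- transcript(sess)
  expect_identical(tr$messages[tr$protocol == "MUL"], 4L)  # 2 deals + 2 opens
  close_session(sess)
})

test_that("truncation is wrap-safe even for adversarial share splits", {
  # place P0's pre-truncation share right at the ring boundary: the plain
  # local truncation would be off by ~2^(n-f); the flagged correction keeps
  # the off-by-one contract
  sess <- mpc_session(rs64, seeds = 12)
  v <- secureRKN:::rg_encode(c(3.5, -2.25) * 2^20, 64L, 20L) # raw v*2^(2f)
  for (z0small in c(0, 1, 5)) {
    z0 <- secureRKN:::rg_from_dbl(rep(z0small, 2), 64L)
    z1 <- secureRKN:::rg_sub(v, z0, 64L)
    tp <- secureRKN:::trunc_pair(sess, z0, z1, "MUL")
    got <- secureRKN:::rg_decode(secureRKN:::rg_add(tp$s0, tp$s1, 64L), 64L, 20L)
    expect_lt(max(abs(got - c(3.5, -2.25))), 2 * 2^-20)
  }
  close_session(sess)
})

test_that("exponential contribution tables are reciprocal and representable", {
  imax <- secureRKN:::exp_window(rs64, exp(1))
  expect_identical(imax, 4L)                   # e^(2^5) would overflow 2^43
  pvals <- (rs64$f + imax):0
  expect_length(pvals, 25L)                    # 5 integer + 20 fractional bits
  Cp <- secureRKN:::rg_decode(secureRKN:::rg_encode(exp(2^(pvals - rs64$f)), 64L, 20L), 64L, 20L)
  Cn <- secureRKN:::rg_decode(secureRKN:::rg_encode(exp(-(2^(pvals - rs64$f))), 64L, 20L), 64L, 20L)
  expect_lt(max(abs(Cp * Cn - 1) / Cp), 2^-19) # Cp[i]*Cn[i] = 1 within tolerance
})
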