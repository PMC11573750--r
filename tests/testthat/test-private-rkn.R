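# outsourcing and the private inference circuit

test_that("outsourced model and sequence reconstruct to their plaintexts", {
  model <- generate_rkn_model(q = 4, k = 2, seed = 50)
  sess <- mpc_session(rs64, seeds = 51)
  sm <- outsource_model(sess, model)
  expect_lt(max(abs(mpc_decode(sess, sm$Z) - model$Z)), 2^-20)
  expect_lt(max(abs(mpc_decode(sess, sm$G) - model$G)), 2^-20)
  expect_lt(max(abs(mpc_decode(sess, sm$w) - model$w)), 2^-20)
  expect_lt(abs(mpc_decode(sess, sm$beta) - model$beta), 2^-20)
  # scalars stay plaintext
  expect_identical(sm$alpha, model$alpha)
  expect_identical(sm$lambda, model$lambda)

  s <- "ACDEF"
  sq <- outsource_sequence(sess, s)
  expect_identical(sq$len, 5L)
  expect_identical(unname(sq$onehot$dims), c(5L, 20L))
  oh <- mpc_decode(sess, sq$onehot)
  expect_equal(oh, one_hot_encode(s), tolerance = 2^-20)
  expect_equal(rowSums(oh), rep(1, 5), tolerance = 2^-18)
  expect_error(outsource_sequence(sess, "AB1"), "unknown residue")
  close_session(sess)
})

test_that("a single share of the weights is uniform (no leakage)", {
  model <- generate_rkn_model(q = 4, k = 2, seed = 52)
  model$w <- rep(0, 4)                      # even an all-zero secret
  sess <- mpc_session(rs8, seeds = 53)
  masks <- secureRKN:::rng_next(sess$rng$P0, 4096, 8L)
  counts <- tabulate(rval(masks) + 1, nbins = 256)
  expect_gt(chisq_uniform_p(counts), 1e-3)
  close_session(sess)
})

test_that("private forward with zero weights reconstructs the bias", {
  model <- generate_rkn_model(q = 3, k = 2, seed = 54)
  model$w <- rep(0, 3)
  sess <- mpc_session(rs64, seeds = 55)
  pred <- reconstruct_prediction(private_forward(
    sess, outsource_model(sess, model),
    outsource_sequence(sess, generate_sequences(1, length = 8, seed = 56)[[1]])))
  expect_equal(pred, model$beta, tolerance = 2^-19 * 8)
  close_session(sess)
})

test_that("private and plaintext predictions agree on small random cases", {
  for (seed in 57:59) {
    model <- generate_rkn_model(q = 4, k = 2, seed = seed)
    s <- generate_sequences(1, length = 10, seed = seed + 10L)[[1]]
    sess <- mpc_session(rs64, seeds = seed)
    priv <- reconstruct_prediction(private_forward(
      sess, outsource_model(sess, model), outsource_sequence(sess, s)))
    close_session(sess)
    expect_equal(priv, rkn_forward(model, s)$prediction, tolerance = 2e-5)
  }
})

test_that("per-position protocol usage matches the circuit structure", {
  model <- generate_rkn_model(q = 3, k = 2, seed = 60)
  len <- 7L
  sess <- mpc_session(rs64, seeds = 61)
  sm <- outsource_model(sess, model)
  sq <- outsource_sequence(sess, generate_sequences(1, length = len, seed = 62)[[1]])
  reset_transcript(sess)
  invisible(private_forward(sess, sm, sq))
  expect_identical(count_invocations(sess, "EXP"), len)         # one per position
  expect_identical(count_invocations(sess, "MP"), len + 2L)     # + G, + w
  expect_identical(count_invocations(sess, "MUL"),
                   len * (1L + 5L))            # recurrence + 5 tree levels/EXP
  expect_identical(count_invocations(sess, "MSB"), 2L * len)
  expect_identical(count_invocations(sess, "MUX"), 2L * len)
  close_session(sess)
})

test_that("prediction shares are reproducible and transport-invariant", {
  model <- generate_rkn_model(q = 3, k = 2, seed = 63)
  s <- generate_sequences(1, length = 6, seed = 64)[[1]]
  run <- function(transport) {
    sess <- mpc_session(rs64, seeds = 65, transport = transport)
    p <- private_forward(sess, outsource_model(sess, model),
                         outsource_sequence(sess, s))
    close_session(sess)
    p
  }
  a <- run("inproc"); b <- run("inproc"); c <- run("socket")
  expect_true(all(secureRKN:::rg_eq(unclass(a$s0), unclass(b$s0))))
  expect_true(all(secureRKN:::rg_eq(unclass(a$s1), unclass(b$s1))))
  expect_true(all(secureRKN:::rg_eq(unclass(a$s0), unclass(c$s0))))
  expect_true(all(secureRKN:::rg_eq(unclass(a$s1), unclass(c$s1))))
})

test_that("reconstruct_prediction inverts sharing exactly", {
  sess <- mpc_session(rs64, seeds = 66)
  for (v in c(0.75, -3.125, 12)) {
    st <- mpc_share(sess, v)
    expect_equal(reconstruct_prediction(st$s0, st$s1, rs64), v)
  }
  close_session(sess)
})
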