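# plaintext RKN reference: encoding, forward pass, model container I/O

test_that("one-hot encoding places single ones at alphabet indices", {
  oh <- one_hot_encode("A")
  expect_equal(dim(oh), c(1L, 20L))
  expect_equal(oh[1, match("A", AA_ALPHABET20)], 1)
  expect_equal(sum(oh), 1)
  oh2 <- one_hot_encode("AC")
  expect_equal(rowSums(oh2), c(1, 1))
  expect_equal(sum(oh2[1, ] * oh2[2, ]), 0)       # orthogonal rows
  set.seed(30)
  s <- paste(sample(AA_ALPHABET20, 200, replace = TRUE), collapse = "")
  expect_true(all(rowSums(one_hot_encode(s)) == 1))
  expect_error(one_hot_encode("AXB"), "unknown residue")
  expect_equal(rowSums(one_hot_encode("AXC", unknown = "zero")), c(1, 0, 1))
  expect_error(one_hot_encode(""), "empty")
})

test_that("forward with zero classifier weights returns the bias", {
  model <- generate_rkn_model(q = 6, k = 3, seed = 31)
  model$w <- rep(0, 6)
  for (s in generate_sequences(3, len_range = c(5, 40), seed = 32))
    expect_equal(rkn_forward(model, s)$prediction, model$beta)
})

test_that("lambda = 0, k = 1, G = I: mapping depends only on the last residue", {
  model <- generate_rkn_model(q = 5, k = 1, lambda = 0, seed = 33)
  model$G <- diag(5)
  s1 <- "ACDEFGHIK"
  s2 <- "WYYWVVRSK"      # same final residue
  f1 <- rkn_forward(model, s1)
  f2 <- rkn_forward(model, s2)
  expect_equal(f1$mapping, f2$mapping)
  # and it equals the closed-form b_1[|x|]
  xT <- one_hot_encode("K")[1, ]
  b <- exp(model$alpha * (as.numeric(model$Z %*% xT) - 1))
  expect_equal(f1$mapping, b)
})

test_that("hand-unrolled k=1, |x|=2, q=1 case matches", {
  # one anchor of length 1 concentrated on residue A; alpha 0.8, lambda 0.3
  zrow <- matrix(0, 1, 20); zrow[1, match("A", AA_ALPHABET20)] <- 1
  model <- rkn_model(zrow, alpha = 0.8, lambda = 0.3, G = matrix(1, 1, 1),
                     w = 2, beta = -0.25, k = 1, q = 1)
  # sequence "AC": b[1] = e^0 = 1, b[2] = e^(0.8*(0-1))
  # c1[1] = 0.3*0 + 1*1 = 1 ; c1[2] = 0.3*1 + e^-0.8*1
  by_hand <- 2 * (0.3 + exp(-0.8) + 0.3 * 0) + -0.25
  expect_equal(rkn_forward(model, "AC")$prediction, 2 * (0.3 + exp(-0.8)) - 0.25)
  expect_equal(rkn_forward(model, "AC")$prediction, by_hand)
})

test_that("lambda = 1, alpha -> 0 limit counts k-subsequences", {
  for (k in 1:3) {
    model <- generate_rkn_model(q = 3, k = k, alpha = 1e-9, lambda = 1,
                                seed = 34)
    for (len in c(k, k + 2L, 8L)) {
      s <- generate_sequences(1, length = len, seed = 35 + len)[[1]]
      ck <- rkn_forward(model, s)$ck
      expect_equal(ck, rep(count_k_subsequences(len, k), 3), tolerance = 1e-6)
      expect_equal(ck[1], choose(len, k), tolerance = 1e-6)
    }
  }
})

test_that("forward agrees with an independent scalar-loop oracle", {
  for (seed in 36:38) {
    model <- generate_rkn_model(q = 4, k = 3, seed = seed)
    s <- generate_sequences(1, len_range = c(6, 15), seed = seed)[[1]]
    expect_equal(rkn_forward(model, s)$prediction, rkn_oracle(model, s),
                 tolerance = 1e-12)
  }
})

test_that("forward is deterministic (bit-identical reruns)", {
  model <- generate_rkn_model(q = 8, k = 4, seed = 39)
  s <- generate_sequences(1, length = 30, seed = 40)[[1]]
  expect_identical(rkn_forward(model, s), rkn_forward(model, s))
})

test_that("model directory round trip preserves the model", {
  model <- generate_rkn_model(q = 5, k = 2, seed = 41)
  dir <- withr::local_tempdir()
  write_model_dir(model, dir)
  back <- read_model_dir(dir)
  expect_equal(back$Z, model$Z, tolerance = 1e-12)
  expect_equal(back$G, model$G, tolerance = 1e-12)
  expect_equal(back$w, model$w, tolerance = 1e-12)
  expect_equal(back$beta, model$beta, tolerance = 1e-12)
  expect_identical(back$k, model$k)
  s <- generate_sequences(1, length = 12, seed = 42)[[1]]
  expect_equal(rkn_forward(back, s)$prediction, rkn_forward(model, s)$prediction,
               tolerance = 1e-9)
})

test_that("FASTA round trip preserves sequences", {
  seqs <- generate_sequences(4, len_range = c(10, 30), seed = 43)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_sequences(seqs, path)
  expect_identical(read_fasta_sequences(path), seqs)
})

test_that("model validation rejects broken inputs", {
  model <- generate_rkn_model(q = 3, k = 2, seed = 44)
  bad <- model; bad$Z <- bad$Z * 2
  expect_error(validate <- secureRKN:::validate_rkn_model(bad), "unit norm")
  bad <- model; bad$G <- bad$G[, 1:2]
  expect_error(secureRKN:::validate_rkn_model(bad), "symmetric q x q")
  expect_error(rkn_model(model$Z, -1, 0.5, model$G, model$w, 0, 2, 3),
               "alpha")
})

test_that("similarity layer matches its closed form", {
  model <- generate_rkn_model(q = 4, k = 2, seed = 45)
  # a one-hot row equal to an anchor column gives dot 1 -> b = 1
  i <- which.max(abs(model$Z[1, ]))
  unitrow <- numeric(20); unitrow[i] <- 1
  Zfix <- model$Z; Zfix[1, ] <- unitrow
  mfix <- rkn_model(Zfix / sqrt(rowSums(Zfix^2)), model$alpha, model$lambda,
                    model$G, model$w, model$beta, 2, 4)
  expect_equal(rkn_similarity(mfix, unitrow)[1], 1)
  # orthogonal row (dot 0) -> exp(-alpha)
  j <- which(unitrow == 0 & Zfix[1, ] == 0)[1]
  orow <- numeric(20); orow[j] <- 1
  expect_equal(rkn_similarity(mfix, orow)[1], exp(-mfix$alpha))
  # random row vs direct formula
  x <- one_hot_encode("W")[1, ]
  expect_equal(rkn_similarity(model, x),
               exp(model$alpha * (as.numeric(model$Z %*% x) - 1)))
})
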