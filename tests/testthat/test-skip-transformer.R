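# Multi-scale tokenization and channel cross-attention skip transformer.

test_that("tokenize yields equal-length sequences with preserved channels", {
  m <- caunet(desk_config())
  pyr <- encode(m, random_image_batch(64, n = 2, seed = 1))
  tk <- tokenize(pyr, 16)
  expect_equal(lapply(tk$tokens, dim),
               list(c(16, 8, 2), c(16, 16, 2), c(16, 32, 2), c(16, 64, 2)))
  expect_equal(dim(tk$tsum), c(16, 8 + 16 + 32 + 64, 2))
  expect_error(tokenize(pyr, 15), "square")

  # constant feature maps pool to constant token rows
  cpyr <- lapply(c(32, 16, 8, 4), function(s) array(2.5, c(s, s, 3, 1)))
  ctk <- tokenize(cpyr, 16)
  expect_true(all(vapply(ctk$tokens, function(t) all(t == 2.5), TRUE)))
})

test_that("attention entries lie in (0,1) and shapes are preserved", {
  m <- caunet(desk_config())
  pyr <- encode(m, random_image_batch(64, n = 2, seed = 2))
  tokens <- sc_transformer(m, pyr)
  expect_equal(lapply(tokens, dim),
               list(c(16, 8, 2), c(16, 16, 2), c(16, 32, 2), c(16, 64, 2)))
  expect_true(all(vapply(tokens, function(t) all(is.finite(t)), TRUE)))

  # the exported attention core on random matrices
  set.seed(3)
  Ti <- matrix(rnorm(16 * 8), 16, 8)
  Ts <- matrix(rnorm(16 * 24), 16, 24)
  ca <- channel_cross_attention(Ti, Ts, matrix(rnorm(8 * 16), 8, 16) / 4,
                                matrix(rnorm(24 * 16), 24, 16) / 4,
                                matrix(rnorm(24 * 16), 24, 16) / 4)
  expect_true(all(ca$M > 0 & ca$M < 1))
  expect_equal(dim(ca$CA), c(16, 16))
  expect_error(channel_cross_attention(Ti, Ts[1:8, ], diag(8), diag(24),
                                       diag(24)), "disagree")
})

test_that("tiny hand-set attention matches a step-by-step matrix oracle", {
  # d = 2, C_i = 2, one head, hand-set projections
  T1 <- matrix(c(1, -1, 0.5, 2), 2, 2)
  Ts <- cbind(T1, matrix(c(0.2, 0.4, -0.3, 0.1), 2, 2))  # C_sum = 4
  Wq <- matrix(c(0.3, -0.2, 0.1, 0.4), 2, 2)
  Wk <- matrix(c(0.1, 0.2, -0.1, 0.3, 0.2, 0, 0.1, -0.2), 4, 2)
  Wv <- matrix(c(0.2, -0.1, 0.3, 0.1, 0, 0.25, -0.15, 0.05), 4, 2)

  # independent transcription of the attention equations
  Q <- T1 %*% Wq
  K <- Ts %*% Wk
  V <- Ts %*% Wv
  S <- t(Q) %*% K / 4
  mu <- mean(S)
  Sn <- (S - mu) / sqrt(mean((S - mu)^2) + 1e-5)
  M <- 1 / (1 + exp(-Sn))
  CA_expected <- V %*% t(M)

  got <- channel_cross_attention(T1, Ts, Wq, Wk, Wv)
  expect_equal(got$CA, CA_expected, tolerance = 1e-6)
  expect_equal(got$M, M, tolerance = 1e-6)

  # the batched network path computes the same arithmetic
  cfg <- list(token_len = 2, heads = 1, widths = c(2, 1, 1, 1))
  tokens3 <- list(array(T1, c(2, 2, 1)), array(Ts[, 3, drop = FALSE], c(2, 1, 1)),
                  array(0, c(2, 1, 1)), array(0, c(2, 1, 1)))
  Qh <- caunet:::ag_bmm3(tokens3[[1]], Wq)
  tsum <- array(Ts, c(2, 4, 1))
  Kh <- caunet:::ag_bmm3(tsum, Wk)
  Vh <- caunet:::ag_bmm3(tsum, Wv)
  Sh <- caunet:::ag_scale(caunet:::ag_bmm_tA(Qh, Kh), 1 / 4)
  Mh <- caunet:::ag_sigmoid(caunet:::ag_instnorm3(Sh))
  CAh <- caunet:::ag_bmm_tB(Vh, Mh)
  expect_equal(CAh[, , 1], CA_expected, tolerance = 1e-6)
})

test_that("multi-head combination is the arithmetic mean", {
  set.seed(4)
  hs <- lapply(1:4, function(i) array(rnorm(12), c(2, 3, 2)))
  expect_equal(mca(hs), Reduce(`+`, hs) / 4)
  expect_equal(mca(hs[1]), hs[[1]])  # single head is the identity
  one <- lapply(1:3, function(i) hs[[1]])
  expect_equal(mca(one), hs[[1]])    # mean of equal heads
  expect_error(mca(list()), "at least one")
})

test_that("sc_layer preserves shapes and collapses to MCA with zero MLP", {
  cfg <- desk_config()
  m <- caunet(cfg)
  pyr <- encode(m, random_image_batch(64, n = 1, seed = 5))
  tk <- tokenize(pyr, 16)
  out <- sc_layer(m, tk$tokens, layer = 1)
  expect_equal(lapply(out, dim), lapply(tk$tokens, dim))

  # zero the MLP second linear: O_i reduces to the reconstructed MCA_i
  m0 <- caunet(cfg)
  for (i in 1:4) {
    m0$params[[paste0("sct.l1.mlp", i, ".w2")]][] <- 0
    m0$params[[paste0("sct.l1.mlp", i, ".b2")]][] <- 0
  }
  out0 <- sc_layer(m0, tk$tokens, layer = 1)
  # recompute the MCA reconstruction by hand for scale 1
  d <- 16; N <- cfg$heads; dh <- d / N
  csum <- sum(cfg$widths)
  Wk <- m0$params[["sct.l1.k.w"]]; Wv <- m0$params[["sct.l1.v.w"]]
  Wq <- m0$params[["sct.l1.q1.w"]]; Wo <- m0$params[["sct.l1.o1.w"]]
  tsum <- tk$tsum
  K <- caunet:::ag_bmm3(tsum, Wk); V <- caunet:::ag_bmm3(tsum, Wv)
  Q <- caunet:::ag_bmm3(tk$tokens[[1]], Wq)
  heads <- lapply(seq_len(N), function(h) {
    cols <- (h - 1) * dh + seq_len(dh)
    S <- caunet:::ag_bmm_tA(Q[, cols, , drop = FALSE],
                            K[, cols, , drop = FALSE])
    M <- caunet:::ag_sigmoid(caunet:::ag_instnorm3(S / csum))
    caunet:::ag_bmm_tB(V[, cols, , drop = FALSE], M)
  })
  MCAc <- caunet:::ag_bmm3(Reduce(`+`, heads) / N, Wo)
  expect_equal(out0[[1]], MCAc, tolerance = 1e-10)
})

test_that("stacked transformer: L = 1 equals one layer; default depth runs", {
  cfg <- desk_config()
  cfg1 <- caunet_config(num_classes = 2, input_size = 64,
                        widths = c(8, 16, 32, 64), groups = 4,
                        se_reduction = 4, heads = 2, layers = 1,
                        token_len = 16, seed = cfg$seed)
  m <- caunet(cfg1)
  pyr <- encode(m, random_image_batch(64, n = 1, seed = 6))
  tk <- tokenize(pyr, 16)
  expect_equal(sc_transformer(m, pyr), sc_layer(m, tk$tokens, 1))
  expect_error(caunet_config(input_size = 64, widths = c(8, 16, 32, 64),
                             layers = 0, token_len = 16), "layers")

  # gradients reach all projection matrices from a scalar loss
  caunet:::ag_start()
  xn <- caunet:::new_node(random_image_batch(64, n = 1, seed = 7))
  pyr <- encode(m, xn, train = TRUE)
  tokens <- sc_transformer(m, pyr)
  y <- random_mask(4, 2, n = 1, seed = 8)
  # a scalar touching every scale's refined tokens
  loss <- Reduce(function(a, b) caunet:::ag_add(a, b), lapply(1:4, function(i) {
    ci <- c(8, 16, 32, 64)[i]
    caunet:::ag_focal_from_logits(
      caunet:::ag_tokens_to_map(tokens[[i]], 4, 4, 4, 4), y, rep(0.5, ci), 2)
  }))
  caunet:::ag_backward(loss)
  g <- caunet:::ag_leaf_grads()
  caunet:::ag_stop()
  sct <- grep("^sct\\.", caunet:::param_names(m), value = TRUE)
  expect_true(all(sct %in% names(g)))
})
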