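# Equation-level behaviour of the layer primitives, each checked against an
# independent scalar/loop reference implementation.

test_that("stem convolution matches a direct sliding-window sum", {
  B <- 1L; L <- 8L
  # single window-3 filter, all-ones weights, zero bias, input of ones, d_v=1:
  # interior positions sum 3 ones; edges see zero padding
  M <- matrix(1, B * L, 1)
  stem <- list(list(W = matrix(1, 3, 1), b = 0))
  out <- remex:::conv_stem_forward(M, stem, windows = 3L, B, L)$out
  expect_equal(as.vector(out), c(2, rep(3, 6), 2))
  # all-zero weights and bias -> f(0) = 0 everywhere
  stem0 <- list(list(W = matrix(0, 3, 1), b = 0))
  expect_true(all(remex:::conv_stem_forward(M, stem0, 3L, B, L)$out == 0))
  # same-length padding for every window
  M2 <- matrix(rnorm(2 * 16 * 5), 2 * 16, 5)
  stem3 <- lapply(c(3, 5, 7), function(h) list(W = matrix(rnorm(h * 5), h * 5, 4), b = rnorm(4)))
  out3 <- remex:::conv_stem_forward(M2, stem3, c(3L, 5L, 7L), 2L, 16L)$out
  expect_equal(dim(out3), c(32L, 12L))
})

test_that("residual block: identity on zero weights, ReLU clamp, oracle match", {
  B <- 2L; L <- 6L; nC <- 4L
  zero_blk <- list(w1 = matrix(0, 3, nC), b1 = numeric(nC),
                   w2 = matrix(0, 3, nC), b2 = numeric(nC))
  C <- matrix(abs(rnorm(B * L * nC)), B * L, nC)
  expect_equal(remex:::res_block_forward(C, zero_blk, B, L)$out, C)
  Cneg <- C; Cneg[3, 2] <- -1
  out <- remex:::res_block_forward(Cneg, zero_blk, B, L)$out
  expect_equal(out[3, 2], 0)              # g = ReLU clamps the negative entry
  expect_equal(out, pmax(Cneg, 0))        # all other entries pass through
})

test_that("residual block agrees with the literal three-equation reference", {
  set.seed(42)
  B <- 2L; L <- 5L; nC <- 3L
  for (rep in 1:5) {
    blk <- list(w1 = matrix(rnorm(3 * nC, sd = 0.5), 3, nC), b1 = rnorm(nC, sd = 0.2),
                w2 = matrix(rnorm(3 * nC, sd = 0.5), 3, nC), b2 = rnorm(nC, sd = 0.2))
    C <- matrix(rnorm(B * L * nC), B * L, nC)
    got <- remex:::res_block_forward(C, blk, B, L)$out
    want <- res_block_oracle(C, blk, B, L)
    expect_lt(max(abs(got - want)), 1e-6)
    expect_equal(dim(got), dim(C))
  }
})

test_that("removing shortcuts changes outputs (no silently dead shortcut)", {
  set.seed(7)
  nC <- 3L
  blk <- list(w1 = matrix(rnorm(3 * nC), 3, nC), b1 = rnorm(nC),
              w2 = matrix(rnorm(3 * nC), 3, nC), b2 = rnorm(nC))
  C <- matrix(rnorm(10 * nC), 10, nC)
  with_sc <- remex:::res_block_forward(C, blk, 1L, 10L, shortcut = TRUE)$out
  without <- remex:::res_block_forward(C, blk, 1L, 10L, shortcut = FALSE)$out
  expect_gt(max(abs(with_sc - without)), 1e-6)
})

test_that("gru_step limits: z -> 1 gives the candidate, z -> 0 keeps the state", {
  H <- 3L; d <- 2L
  base <- function(bz) list(
    Wz = matrix(0, H + d, H), Wr = matrix(0.3, H + d, H),
    Wh = matrix(0.3, H + d, H), bz = rep(bz, H), br = numeric(H),
    bh = numeric(H))
  x <- c(0.5, -0.2); h <- c(0.3, -0.1, 0.8)
  up <- gru_step(x, h, base(30))    # z ~ 1
  expect_equal(up$h, up$hcand, tolerance = 1e-9)
  down <- gru_step(x, h, base(-30)) # z ~ 0
  expect_equal(down$h, h, tolerance = 1e-9)
  expect_true(all(up$z > 0 & up$z < 1 & up$r > 0 & up$r < 1))
})

test_that("gru_step matches the scalar gate equations over random draws", {
  # fixed 1-d case: all weights 0.5, x = 1, h = 0
  p1 <- list(Wz = matrix(0.5, 2, 1), Wr = matrix(0.5, 2, 1),
             Wh = matrix(0.5, 2, 1), bz = 0, br = 0, bh = 0)
  z <- 1 / (1 + exp(-0.5)); hc <- tanh(0.5)
  expect_lt(abs(gru_step(1, 0, p1)$h - z * hc), 1e-9)
  set.seed(99)
  for (rep in 1:100) {
    d <- sample(1:3, 1L)   # 1-d hidden cell, 1-3 dimensional input
    p <- list(Wz = matrix(rnorm(1 + d), 1 + d, 1),
              Wr = matrix(rnorm(1 + d), 1 + d, 1),
              Wh = matrix(rnorm(1 + d), 1 + d, 1),
              bz = rnorm(1), br = rnorm(1), bh = rnorm(1))
    x <- rnorm(d); h <- rnorm(1)
    up <- gru_step(x, h, p)
    want <- gru_scalar_oracle(x, h, p$Wz[, 1], p$Wr[, 1], p$Wh[, 1],
                              p$bz, p$br, p$bh)
    expect_lt(abs(up$h - want), 1e-9)
    expect_true(all(up$z > 0 & up$z < 1 & up$r > 0 & up$r < 1))
  }
})

test_that("batched GRU equals sequential gru_step on an unmasked sequence", {
  set.seed(3)
  H <- 4L; d <- 3L; L <- 5L
  p <- list(Wz = matrix(rnorm((H + d) * H, sd = 0.4), H + d, H),
            Wr = matrix(rnorm((H + d) * H, sd = 0.4), H + d, H),
            Wh = matrix(rnorm((H + d) * H, sd = 0.4), H + d, H),
            bz = rnorm(H, sd = 0.2), br = rnorm(H, sd = 0.2), bh = rnorm(H, sd = 0.2))
  X <- matrix(rnorm(L * d), L, d)
  out <- remex:::gru_dir_forward(X, matrix(1, 1, L), p, B = 1L, L = L)$H
  h <- numeric(H)
  for (t in seq_len(L)) {
    h <- gru_step(X[t, ], h, p)$h
    expect_equal(out[t, ], h, tolerance = 1e-12)
  }
})

test_that("bidirectional GRU stitches states and ignores padding", {
  set.seed(5)
  cfg <- mini_model_cfg(L_max = 10L)
  H <- cfg$gru$hidden; d <- remex:::model_dims(cfg)$d_v
  layer <- init_model_params(cfg, 10L, 3L, seed = 2L)$gru[[1]]
  X <- matrix(rnorm(10 * d), 10, d)
  mask_full <- matrix(c(rep(1, 6), rep(0, 4)), 1, 10)
  out <- remex:::bigru_layer_forward(X, mask_full, layer, 1L, 10L)
  expect_equal(ncol(out$H), 2L * H)           # stitched dimension
  expect_true(all(out$H[7:10, ] == 0))        # beyond true length: zero
  # padding invariance: same prefix, different padding content
  X2 <- X; X2[7:10, ] <- rnorm(4 * d)
  out2 <- remex:::bigru_layer_forward(X2, mask_full, layer, 1L, 10L)
  expect_equal(out$H[1:6, ], out2$H[1:6, ], tolerance = 1e-12)
  # single-position sequence: output is [forward step, backward step] from zero
  m1 <- matrix(c(1, rep(0, 9)), 1, 10)
  o1 <- remex:::bigru_layer_forward(X, m1, layer, 1L, 10L)
  fstep <- gru_step(X[1, ], numeric(H), layer$fwd)$h
  bstep <- gru_step(X[1, ], numeric(H), layer$bwd)$h
  expect_equal(o1$H[1, ], c(fstep, bstep), tolerance = 1e-12)
})

test_that("palindromic input with tied directions gives mirrored states", {
  set.seed(8)
  H <- 3L; d <- 2L; L <- 3L
  dir <- list(Wz = matrix(rnorm((H + d) * H), H + d, H),
              Wr = matrix(rnorm((H + d) * H), H + d, H),
              Wh = matrix(rnorm((H + d) * H), H + d, H),
              bz = rnorm(H), br = rnorm(H), bh = rnorm(H))
  layer <- list(fwd = dir, bwd = dir)   # weight-tied directions
  x <- rnorm(d)
  X <- rbind(x, rnorm(d), x); X[2, ] <- X[2, ]  # palindrome: x, y, x
  X[3, ] <- X[1, ]
  out <- remex:::bigru_layer_forward(X, matrix(1, 1, L), layer, 1L, L)$H
  for (t in seq_len(L)) {
    expect_equal(out[t, seq_len(H)], out[L + 1 - t, H + seq_len(H)],
                 tolerance = 1e-12)
  }
})

test_that("attention weights form a masked probability vector", {
  set.seed(21)
  B <- 3L; L <- 6L; d <- 4L
  H <- matrix(rnorm(B * L * d), B * L, d)
  att <- list(w = rnorm(d), b = 0.3)
  mask <- matrix(1, B, L); mask[1, 5:6] <- 0; mask[2, 2:6] <- 0
  fw <- remex:::attention_forward(H, mask, att, B, L)
  expect_equal(rowSums(fw$a), rep(1, B), tolerance = 1e-6)
  expect_true(all(fw$a >= 0))
  expect_true(all(fw$a[mask == 0] == 0))        # masked weight exactly 0
  # length-1 sequence: weight 1 and S = that row
  expect_equal(fw$a[2, 1], 1)
  expect_equal(fw$S[2, ], H[(2 - 1) * L + 1, ])
  # identical rows -> uniform weights over the prefix
  H2 <- H; for (t in 1:L) H2[(3 - 1) * L + t, ] <- H[(3 - 1) * L + 1, ]
  fw2 <- remex:::attention_forward(H2, mask, att, B, L)
  expect_equal(fw2$a[3, ], rep(1 / L, L), tolerance = 1e-12)
  # zero-length sequence is an error
  mask0 <- mask; mask0[1, ] <- 0
  expect_error(remex:::attention_forward(H, mask0, att, B, L), "empty")
})

test_that("two-position attention matches the hand softmax", {
  d <- 3L
  w <- c(1, 0, 0)
  H <- rbind(c(atanh(0.5), 0, 0), c(atanh(-0.5), 0, 0))
  fw <- remex:::attention_forward(H, matrix(1, 1, 2), list(w = w, b = 0), 1L, 2L)
  a_want <- exp(c(0.5, -0.5)) / sum(exp(c(0.5, -0.5)))
  expect_lt(max(abs(fw$a[1, ] - a_want)), 1e-9)
  expect_lt(max(abs(fw$S[1, ] - (a_want[1] * H[1, ] + a_want[2] * H[2, ]))), 1e-9)
})

test_that("attention is permutation-covariant in the weights and invariant in S", {
  set.seed(13)
  L <- 5L; d <- 3L
  H <- matrix(rnorm(L * d), L, d)
  att <- list(w = rnorm(d), b = -0.1)
  fw <- remex:::attention_forward(H, matrix(1, 1, L), att, 1L, L)
  perm <- sample(L)
  fwp <- remex:::attention_forward(H[perm, , drop = FALSE], matrix(1, 1, L),
                                   att, 1L, L)
  expect_equal(fwp$a[1, ], fw$a[1, perm], tolerance = 1e-12)
  expect_equal(fwp$S, fw$S, tolerance = 1e-12)
})

test_that("classifier head: uniform under zero weights, rows sum to one", {
  set.seed(2)
  S <- matrix(rnorm(4 * 6), 4, 6)
  cls0 <- list(W = matrix(0, 6, 12), b = numeric(12))
  p0 <- remex:::classifier_forward(S, cls0)$probs
  expect_equal(p0, matrix(1 / 12, 4, 12), tolerance = 1e-12)
  cls <- list(W = matrix(rnorm(6 * 12), 6, 12), b = rnorm(12))
  p <- remex:::classifier_forward(S, cls)$probs
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  expect_true(all(p > 0))
})
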