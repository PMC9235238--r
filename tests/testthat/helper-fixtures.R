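# Shared fixtures, built in code at test time.

# A tiny hand-written corpus: one Test-disease sentence with a gold TeRD
# relation, one sentence with two disease mentions (no admissible pair).
tiny_corpus <- function() {
  validate_corpus(tibble::tibble(
    sid = c("t1", "t2"),
    text = c("xxGASTROyyyTUMORzz", "aaTUMORbbPOLYPcc"),
    entities = list(
      tibble::tibble(id = c("e1", "e2"), type = c("test", "disease"),
                     start = c(2L, 11L), end = c(8L, 16L)),
      tibble::tibble(id = c("e1", "e2"), type = c("disease", "disease"),
                     start = c(2L, 9L), end = c(7L, 14L))
    ),
    relations = list(
      tibble::tibble(e1 = "e1", e2 = "e2", label = "TeRD"),
      tibble::tibble(e1 = character(), e2 = character(), label = character())
    )
  ))
}

# Random annotated sentence with n_a mentions of type a and n_b of type b,
# for brute-force pair-count properties.
random_two_type_sentence <- function(n_a, n_b, type_a, type_b, sid = "r1") {
  n <- n_a + n_b
  len <- 3L * n + 2L
  text <- paste(sample(letters, len, replace = TRUE), collapse = "")
  starts <- seq(0L, by = 3L, length.out = n)
  validate_corpus(tibble::tibble(
    sid = sid, text = text,
    entities = list(tibble::tibble(
      id = paste0("e", seq_len(n)),
      type = c(rep(type_a, n_a), rep(type_b, n_b))[sample.int(n)],
      start = starts, end = starts + 2L
    )),
    relations = list(tibble::tibble(e1 = character(), e2 = character(),
                                    label = character()))
  ))
}

# Miniature model configuration (all dims small) for fast structural and
# gradient tests.
mini_model_cfg <- function(L_max = 16L, depth = 5L, gru_layers = 1L,
                           dropout = 0) {
  model_config(
    embedding = embedding_spec(d_w = 8L, d_p = 4L, p_max = 10L, L_max = L_max),
    conv = conv_spec(windows = 3L, filters = 6L),
    resnet = resnet_config(depth = depth),
    gru = bigru_config(hidden = 6L, layers = gru_layers),
    dropout = dropout
  )
}

# Trivially separable two-class fixture: two sentences whose inter-entity
# trigger deterministically implies the label, each instance replicated.
separable_fixture <- function(copies = 50L, seed = 1L) {
  cfg <- synth_config(n_sentences = 2L, labels = c("TeRD", "TeAP"),
                      class_proportions = c(0.5, 0.5),
                      noise_rate = 0, unknown_fraction = 0, seed = seed)
  corpus <- NULL
  # regenerate until both labels occur (2 sentences, unknown_fraction 0)
  for (s in seed + 0:20) {
    cfg$seed <- s
    corpus <- generate_corpus(cfg)
    inst <- generate_candidate_pairs(corpus)
    if (length(unique(inst$label[inst$label != "unknown"])) == 2L) break
  }
  inst <- generate_candidate_pairs(corpus)
  inst <- inst[inst$label != "unknown", ]
  inst <- inst[rep(seq_len(nrow(inst)), copies), ]
  inst$instance_id <- paste0(inst$instance_id, "#", seq_len(nrow(inst)))
  vocab <- build_vocabulary(corpus)
  # matches mini_model_cfg(L_max = 64L)
  spec <- embedding_spec(d_w = 8L, d_p = 4L, p_max = 10L, L_max = 64L)
  labels <- c("TeRD", "TeAP", "unknown")
  list(corpus = corpus, instances = inst, vocab = vocab, spec = spec,
       labels = labels,
       enc = encode_instances(inst, corpus, vocab, spec, labels))
}

# Scalar reference implementation of the GRU update equations, written
# directly from the gate formulas (independent of the batched code path).
gru_scalar_oracle <- function(x, h, Wz, Wr, Wh, bz, br, bh) {
  z <- 1 / (1 + exp(-(sum(Wz * c(h, x)) + bz)))
  r <- 1 / (1 + exp(-(sum(Wr * c(h, x)) + br)))
  hc <- tanh(sum(Wh * c(r * h, x)) + bh)
  (1 - z) * h + z * hc
}

# Literal step-by-step reference for the residual block equations applied
# position-by-position (same-length zero padding), one channel at a time.
res_block_oracle <- function(C, blk, B, L, shortcut = TRUE) {
  n <- nrow(C); nC <- ncol(C)
  getpos <- function(M, b, t, c) {
    if (t < 1 || t > L) 0 else M[(b - 1) * L + t, c]
  }
  conv_dw <- function(M, w, bias) {
    out <- matrix(0, n, nC)
    for (b in seq_len(B)) for (t in seq_len(L)) for (c in seq_len(nC)) {
      acc <- bias[c]
      for (j in 1:3) acc <- acc + w[j, c] * getpos(M, b, t + j - 2L, c)
      out[(b - 1) * L + t, c] <- acc
    }
    out
  }
  c_l <- pmax(conv_dw(C, blk$w1, blk$b1), 0)          # first convolution + ReLU
  c_l1 <- pmax(conv_dw(c_l, blk$w2, blk$b2), 0)       # second convolution + ReLU
  # identity mapping h(c) = c combined under the output activation g
  if (shortcut) pmax(c_l1 + C, 0) else pmax(c_l1, 0)
}
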