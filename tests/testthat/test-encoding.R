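test_that("relative distances follow the worked (+7, -5) convention", {
  expect_equal(relative_position(9, 2), 7)
  expect_equal(relative_position(0, 5), -5)
  expect_equal(relative_position(4, 4), 0)      # anchor self-distance
  expect_equal(relative_position(200, 0, p_max = 100), 100)  # clipping
})

test_that("relative position is translation-equivariant and clipping is
           idempotent and monotone", {
  set.seed(12)
  for (rep in 1:20) {
    i <- sample(0:300, 1L); s <- sample(0:300, 1L); k <- sample(-100:100, 1L)
    expect_equal(relative_position(i + k, s + k, p_max = 50),
                 relative_position(i, s, p_max = 50))
  }
  d <- seq(-300, 300, by = 7)
  once <- relative_position(d, 0, p_max = 100)
  expect_equal(relative_position(once, 0, p_max = 100), once)  # idempotent
  expect_true(all(diff(once) >= 0))                            # monotone
})

test_that("embedded dimension is d_w + 2 d_p (350 at defaults)", {
  expect_equal(embedded_dim(embedding_spec()), 350L)
  expect_equal(embedded_dim(embedding_spec(d_w = 32, d_p = 8)), 48L)
})

test_that("encoding yields PAD-filled id sequences with offset position ids", {
  corp <- tiny_corpus()
  inst <- generate_candidate_pairs(corp)[1, ]
  vocab <- build_vocabulary(corp)
  spec <- embedding_spec(d_w = 8, d_p = 4, p_max = 100, L_max = 24)
  enc <- encode_instances(inst, corp, vocab, spec)
  n <- nchar(corp$text[1])
  expect_equal(enc$len, n)
  expect_equal(unname(enc$char[1, (n + 1):24]), rep(0L, 24 - n))  # PAD suffix
  pad_pos <- 2L * 100L + 1L
  expect_equal(unname(enc$pos1[1, (n + 1):24]), rep(pad_pos, 24 - n))
  # entity anchors: e1 at 2, e2 at 11; character 9 is +7 from e1, character 6
  # is -5 from e2; offset rule id = d + p_max
  expect_equal(enc$pos1[1, 10], 7L + 100L)
  expect_equal(enc$pos2[1, 7], -5L + 100L)
  expect_equal(enc$pos1[1, 3], 0L + 100L)  # anchor itself
})

test_that("characters outside the vocabulary fall back to UNK", {
  corp <- tiny_corpus()
  inst <- generate_candidate_pairs(corp)[1, ]
  vocab <- build_vocabulary(tiny_corpus()[2, ])  # vocabulary from t2 only
  enc <- encode_instances(inst, corp, vocab, embedding_spec(L_max = 24))
  expect_true(any(enc$char[1, seq_len(enc$len)] == vocab$unk_id))
})

test_that("truncation keeps an entity-centred window or rejects the instance", {
  text <- paste0(strrep("x", 30), "AB", strrep("y", 5), "CD", strrep("z", 30))
  corp <- validate_corpus(tibble::tibble(
    sid = "s", text = text,
    entities = list(tibble::tibble(id = c("t", "d"), type = c("test", "disease"),
                                   start = c(30L, 37L), end = c(32L, 39L))),
    relations = list(tibble::tibble(e1 = character(), e2 = character(),
                                    label = character()))))
  inst <- generate_candidate_pairs(corp)
  vocab <- build_vocabulary(corp)
  enc <- encode_instances(inst, corp, vocab, embedding_spec(L_max = 20))
  expect_equal(n_instances(enc), 1L)
  expect_equal(enc$len, 20L)
  # both entity anchors present: distance-0 ids occur in both position rows
  expect_true(100L %in% enc$pos1[1, ])
  expect_true(100L %in% enc$pos2[1, ])
  # window too small for the pair -> dropped with a warning
  expect_warning(
    enc2 <- encode_instances(inst, corp, vocab, embedding_spec(L_max = 6)),
    "truncation")
  expect_equal(n_instances(enc2), 0L)
})

test_that("embedding lookup has shape (L_max, d_v) with zero PAD composite", {
  corp <- tiny_corpus()
  inst <- generate_candidate_pairs(corp)[1, ]
  vocab <- build_vocabulary(corp)
  spec <- embedding_spec(d_w = 8, d_p = 4, p_max = 10, L_max = 24)
  enc <- encode_instances(inst, corp, vocab, spec)
  cfg <- mini_model_cfg(L_max = 24)
  params <- init_model_params(cfg, vocab_size(vocab), 12L, seed = 1L)
  batch <- remex:::make_batch(enc, 1L)
  M <- remex:::embed_batch(params, batch)$M
  expect_equal(dim(M), c(24L, 16L))  # L_max x d_v
  expect_true(all(M[(enc$len + 1):24, ] == 0))
})

test_that("subset and bind preserve encoded content", {
  corp <- generate_corpus(synth_config(n_sentences = 10, seed = 2))
  inst <- generate_candidate_pairs(corp)
  vocab <- build_vocabulary(corp)
  enc <- encode_instances(inst, corp, vocab, embedding_spec(d_w = 4, d_p = 2,
                                                           p_max = 10, L_max = 64))
  a <- enc_subset(enc, 1:3)
  b <- enc_subset(enc, 4:n_instances(enc))
  ab <- enc_bind(a, b)
  expect_equal(ab$char, enc$char)
  expect_equal(ab$label_id, enc$label_id)
  expect_equal(ab$instance_id, enc$instance_id)
})
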