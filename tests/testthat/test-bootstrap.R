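# Small learnable fixture shared by the bootstrapping tests: two-label
# synthetic corpus, miniature model, short training schedule.
bs_fixture <- function(n_seed, n_pool, n_test = 0L, seed = 21L) {
  cfg <- synth_config(n_sentences = 80L, labels = c("TeRD", "TeAP"),
                      class_proportions = c(0.5, 0.5), noise_rate = 0,
                      unknown_fraction = 0.4, seed = seed)
  fix <- make_semisup_fixture(cfg, n_seed, n_pool, max(n_test, 1L))
  vocab <- build_vocabulary(fix$corpus)
  spec <- embedding_spec(d_w = 8L, d_p = 4L, p_max = 10L, L_max = 64L)
  labels <- c("TeRD", "TeAP", "unknown")
  mcfg <- model_config(embedding = spec, conv = conv_spec(windows = 3L, filters = 8L),
                       resnet = resnet_config(depth = 5L),
                       gru = bigru_config(hidden = 8L, layers = 1L), dropout = 0)
  tcfg <- train_config(batch_size = 32L, learning_rate = 1e-2, epochs = 6L,
                       patience = 6L, validation_fraction = 0, seed = 5L)
  list(
    seed = encode_instances(fix$seed, fix$corpus, vocab, spec, labels),
    pool = encode_instances(fix$unlabeled, fix$corpus, vocab, spec, labels),
    truth = fix$unlabeled_truth,
    test = encode_instances(fix$test, fix$corpus, vocab, spec, labels),
    test_gold = fix$test$label,
    mcfg = mcfg, tcfg = tcfg, labels = labels
  )
}

test_that("accumulate-then-merge: small confident pool fills R without retrain", {
  fx <- bs_fixture(n_seed = 60L, n_pool = 50L)
  st <- remex:::bootstrap_init(fx$seed, fx$pool, bootstrap_config(retrain_trigger = 1000L),
                               fx$mcfg, fx$tcfg)
  st <- bootstrap_round(st)
  log1 <- st$log[[1]]
  # every accepted instance moved U -> R; trigger not reached -> no retrain
  expect_false(log1$retrained)
  expect_equal(log1$n_reliable, log1$accepted)
  expect_equal(log1$n_unlabeled, 50L - log1$accepted)
  expect_gt(log1$accepted, 0L)
})

test_that("retrains fire at the trigger and the instance multiset is conserved", {
  fx <- bs_fixture(n_seed = 60L, n_pool = 120L)
  bc <- bootstrap_config(lambda = 0.7, retrain_trigger = 50L, max_rounds = 20L)
  expect_no_warning(
    run <- run_bootstrap(fx$seed, fx$pool, bc, fx$mcfg, fx$tcfg,
                         hidden_truth = fx$truth)
  )
  log <- run$log
  # conservation: |L| + |U| + |R| constant every round
  expect_true(all(log$n_labeled + log$n_unlabeled + log$n_reliable ==
                    60L + 120L))
  # monotone pool shrinkage
  expect_true(all(diff(log$n_unlabeled) <= 0))
  expect_true(any(log$retrained))
  expect_equal(run$n_unlabeled_left, 0L)
  # final labeled set covers everything exactly once
  expect_equal(sort(run$labeled$instance_id),
               sort(c(fx$seed$instance_id, fx$pool$instance_id)))
  expect_equal(sum(run$labeled$provenance == "pseudo"), 120L)
})

test_that("a threshold at or above 1 accepts nothing and stalls", {
  fx <- bs_fixture(n_seed = 60L, n_pool = 30L)
  bc <- bootstrap_config(lambda = 1, retrain_trigger = 10L)
  expect_warning(run <- run_bootstrap(fx$seed, fx$pool, bc, fx$mcfg, fx$tcfg),
                 "stalled")
  expect_true(run$stalled)
  expect_equal(run$n_unlabeled_left, 30L)
  expect_equal(sum(run$labeled$provenance == "pseudo"), 0L)
})

test_that("an empty unlabeled pool returns the seed model after zero rounds", {
  fx <- bs_fixture(n_seed = 60L, n_pool = 10L)
  empty <- enc_subset(fx$pool, integer(0))
  run <- run_bootstrap(fx$seed, empty, bootstrap_config(), fx$mcfg, fx$tcfg)
  expect_equal(run$rounds, 0L)
  expect_equal(nrow(run$log), 0L)
  seed_model <- train_relation_model(fx$seed, fx$mcfg, fx$tcfg)
  expect_identical(run$model$params, seed_model$params)
})

test_that("a pure-noise pool stalls with near-uniform confidences", {
  # random labels over all 12 classes, no signal in the text
  cfg <- synth_config(n_sentences = 120L, unknown_fraction = 1, seed = 33L)
  corp <- generate_corpus(cfg)
  inst <- generate_candidate_pairs(corp)
  labels12 <- schema_labels(include_unknown = TRUE)
  set.seed(41)
  inst$label <- sample(labels12, nrow(inst), replace = TRUE)
  vocab <- build_vocabulary(corp)
  spec <- embedding_spec(d_w = 8L, d_p = 4L, p_max = 20L, L_max = 64L)
  n <- nrow(inst)
  seed_inst <- inst[seq_len(min(100L, n - 50L)), ]
  pool_inst <- inst[(min(100L, n - 50L) + 1L):n, ]
  pool_inst$label <- NA_character_
  enc_seed <- encode_instances(seed_inst, corp, vocab, spec, labels12)
  enc_pool <- encode_instances(pool_inst, corp, vocab, spec, labels12)
  mcfg <- model_config(embedding = spec, conv = conv_spec(windows = 3L, filters = 6L),
                       resnet = resnet_config(depth = 5L),
                       gru = bigru_config(hidden = 6L, layers = 1L), dropout = 0.5)
  tcfg <- train_config(batch_size = 32L, learning_rate = 5e-4, epochs = 2L,
                       patience = 2L, validation_fraction = 0, seed = 9L)
  expect_warning(
    run <- run_bootstrap(enc_seed, enc_pool, bootstrap_config(lambda = 0.7),
                         mcfg, tcfg),
    "stalled")
  expect_equal(run$n_unlabeled_left, n_instances(enc_pool))
  # confidences sit near the uniform bound 1/12, far below the threshold
  seed_model <- train_relation_model(enc_seed, mcfg, tcfg)
  pr <- predict(seed_model, enc_pool)
  expect_lt(max(pr$.confidence), 0.7)
})

test_that("bootstrap run tidiers summarise the log", {
  fx <- bs_fixture(n_seed = 60L, n_pool = 40L)
  run <- suppressWarnings(
    run_bootstrap(fx$seed, fx$pool, bootstrap_config(retrain_trigger = 20L,
                                                     max_rounds = 10L),
                  fx$mcfg, fx$tcfg, hidden_truth = fx$truth))
  expect_s3_class(tidy(run), "tbl_df")
  expect_true(all(c("round", "accepted", "pseudo_error") %in% names(tidy(run))))
  expect_equal(glance(run)$rounds, run$rounds)
  expect_s3_class(autoplot(run), "ggplot")
})
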