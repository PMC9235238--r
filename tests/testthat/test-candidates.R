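test_that("candidate pairs: gold labels carried, inadmissible pairs dropped", {
  corp <- tiny_corpus()
  inst <- generate_candidate_pairs(corp)
  # sentence t1: one test + one disease with a gold TeRD relation
  expect_equal(sum(inst$sid == "t1"), 1L)
  expect_equal(inst$label[inst$sid == "t1"], "TeRD")
  # canonical order: test mention first
  expect_equal(inst$e1_type[inst$sid == "t1"], "test")
  # sentence t2: disease-disease is not a schema category
  expect_equal(sum(inst$sid == "t2"), 0L)
  # zero entities -> no instances
  empty <- validate_corpus(tibble::tibble(
    sid = "z", text = "abc",
    entities = list(tibble::tibble(id = character(), type = character(),
                                   start = integer(), end = integer())),
    relations = list(tibble::tibble(e1 = character(), e2 = character(),
                                    label = character()))))
  expect_equal(nrow(generate_candidate_pairs(empty)), 0L)
})

test_that("canonical orientation holds regardless of textual order", {
  # disease appears before test in text; instance must still put test first
  corp <- validate_corpus(tibble::tibble(
    sid = "s", text = "TUMORxxxSCAN",
    entities = list(tibble::tibble(id = c("d", "t"),
                                   type = c("disease", "test"),
                                   start = c(0L, 8L), end = c(5L, 12L))),
    relations = list(tibble::tibble(e1 = character(), e2 = character(),
                                    label = character()))))
  inst <- generate_candidate_pairs(corp)
  expect_equal(inst$e1, "t")
  expect_equal(inst$e1_type, "test")
  expect_equal(inst$label, "unknown")
})

test_that("pair count is n_a * n_b for a two-type sentence (brute force)", {
  set.seed(31)
  cats <- clinical_schema()$categories
  for (rep in 1:10) {
    k <- sample(nrow(cats), 1L)
    n_a <- sample(1:3, 1L); n_b <- sample(1:3, 1L)
    corp <- random_two_type_sentence(n_a, n_b, cats$e1_type[k], cats$e2_type[k])
    inst <- generate_candidate_pairs(corp)
    # brute-force: enumerate all unordered mention pairs, count admissible
    ents <- corp$entities[[1]]
    combos <- utils::combn(nrow(ents), 2L)
    expected <- sum(vapply(seq_len(ncol(combos)), function(j) {
      !is.null(pair_category(clinical_schema(),
                             ents$type[combos[1, j]], ents$type[combos[2, j]]))
    }, logical(1)))
    expect_equal(nrow(inst), expected)
    expect_equal(nrow(inst), n_a * n_b)
  }
})

test_that("every gold relation appears as exactly one non-unknown instance", {
  cfg <- synth_config(n_sentences = 30L, noise_rate = 0, seed = 5L)
  corp <- generate_corpus(cfg)
  inst <- generate_candidate_pairs(corp)
  n_gold <- sum(vapply(corp$relations, nrow, integer(1)))
  expect_equal(sum(inst$label != "unknown"), n_gold)
  for (i in seq_len(nrow(corp))) {
    rels <- corp$relations[[i]]
    for (k in seq_len(nrow(rels))) {
      hits <- inst$sid == corp$sid[i] &
        ((inst$e1 == rels$e1[k] & inst$e2 == rels$e2[k]) |
         (inst$e1 == rels$e2[k] & inst$e2 == rels$e1[k]))
      expect_equal(sum(hits), 1L)
      expect_equal(inst$label[hits], rels$label[k])
    }
  }
})

test_that("unknown downsampling caps the negative class only", {
  cfg <- synth_config(n_sentences = 60L, seed = 9L)
  inst <- generate_candidate_pairs(generate_corpus(cfg))
  n_rel <- sum(inst$label != "unknown")
  down <- downsample_unknown(inst, max_ratio = 1, seed = 2L)
  expect_equal(sum(down$label != "unknown"), n_rel)
  expect_lte(sum(down$label == "unknown"), ceiling(n_rel))
  # idempotent when already under the cap
  expect_equal(nrow(downsample_unknown(down, max_ratio = 2, seed = 2L)),
               nrow(down))
})

test_that("train/test split is exact, stratified and deterministic", {
  inst <- tibble::tibble(instance_id = as.character(1:10), label = rep("A", 10))
  inst$label[1:5] <- "B"
  sp <- split_train_test(inst, c(0.8, 0.2), seed = 7L)
  expect_equal(nrow(sp$train), 8L)
  expect_equal(nrow(sp$test), 2L)
  expect_equal(nrow(dplyr::inner_join(sp$train, sp$test, by = "instance_id")), 0L)
  sp2 <- split_train_test(inst, c(0.8, 0.2), seed = 7L)
  expect_identical(sp$train$instance_id, sp2$train$instance_id)

  # 100 instances, 50/50 labels: each side balanced within 1
  big <- tibble::tibble(instance_id = as.character(1:100),
                        label = rep(c("A", "B"), each = 50))
  sp3 <- split_train_test(big, c(0.8, 0.2), seed = 1L)
  tab <- table(sp3$test$label)
  expect_lte(abs(tab[["A"]] - tab[["B"]]), 1L)
  expect_equal(nrow(sp3$test), 20L)

  # singleton label goes to train with a warning
  one <- dplyr::bind_rows(big, tibble::tibble(instance_id = "x", label = "C"))
  expect_warning(sp4 <- split_train_test(one, c(0.8, 0.2), seed = 1L), "C")
  expect_true("x" %in% sp4$train$instance_id)
})

test_that("instances serialize to JSONL without a label field when unlabeled", {
  inst <- generate_candidate_pairs(tiny_corpus())
  inst$label[1] <- NA_character_
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_instances(inst, f)
  expect_false(grepl("label", readLines(f)[1], fixed = TRUE))
  back <- read_instances(f)
  expect_equal(back$instance_id, inst$instance_id)
  expect_equal(back$label, inst$label)
})
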