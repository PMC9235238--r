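# Default relation-frequency profile for class proportions: heavily
# imbalanced, as clinical schemas are (TeAP most frequent, TeAS rarest).
default_class_counts <- c(
  DAP = 304, SAP = 518, SNAP = 893, TeRD = 342, TeAP = 1194, TeCP = 572,
  TeRS = 190, TeAS = 110, TrAD = 679, TrRD = 227, TrAP = 128
)

# Dedicated trigger alphabet, disjoint from the filler/entity symbol pool.
trigger_symbols <- c("α", "β", "γ", "δ", "ε",
                     "ζ", "η", "θ", "ι", "κ",
                     "λ")

#' Trigger patterns for a label set
#'
#' Each relation label gets a distinct 3-character trigger pattern drawn from
#' a dedicated symbol alphabet that never occurs in filler or entity
#' surfaces, so a trigger can never arise by chance.
#'
#' @param labels Relation labels (non-`"unknown"`).
#' @return Tibble with `label` and `trigger`.
#' @export
trigger_table <- function(labels = schema_labels()) {
  full <- schema_labels()
  stopifnot(all(labels %in% full))
  pos <- match(labels, full)
  tibble::tibble(label = labels, trigger = strrep(trigger_symbols[pos], 3L))
}

#' Synthetic-corpus configuration
#'
#' The generator emulates the statistical structure of an annotated clinical
#' relation corpus over a symbolic alphabet: period-free sentences of random
#' filler symbols, 2-5 typed entity mentions each, and for related entity
#' pairs a label-specific trigger pattern planted as the exact inter-entity
#' gap (possibly corrupted at `noise_rate`), which makes the label a
#' deterministic function of the substring between the pair when noise is off.
#'
#' @param n_sentences Number of sentences to generate.
#' @param alphabet_size Number of filler/entity symbols (default 60).
#' @param sentence_length Length-2 range of sentence lengths (default
#'   `c(15, 60)`).
#' @param entity_length Length-2 range of mention lengths (default `c(1, 4)`).
#' @param labels Relation labels in play (default: all 11 schema labels).
#' @param class_proportions Sampling proportions over `labels` (default: a
#'   heavily imbalanced clinical-style frequency profile, TeAP most frequent,
#'   TeAS rarest).
#' @param noise_rate Probability that a planted trigger is corrupted (one
#'   symbol replaced by filler; default 0.05). The gold label is kept.
#' @param unknown_fraction Probability that an eligible adjacent entity pair
#'   is left triggerless, hence `"unknown"` (default 0.6).
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_sentences = 100L, alphabet_size = 60L,
                         sentence_length = c(15L, 60L),
                         entity_length = c(1L, 4L),
                         labels = schema_labels(),
                         class_proportions = NULL,
                         noise_rate = 0.05, unknown_fraction = 0.6,
                         seed = 1L) {
  stopifnot(n_sentences >= 0L, alphabet_size >= 10L,
            length(sentence_length) == 2L, sentence_length[1] <= sentence_length[2],
            length(entity_length) == 2L, entity_length[1] >= 1L,
            entity_length[1] <= entity_length[2],
            noise_rate >= 0, noise_rate <= 1,
            unknown_fraction >= 0, unknown_fraction <= 1)
  if (is.null(class_proportions)) {
    class_proportions <- default_class_counts[labels] / sum(default_class_counts[labels])
  }
  stopifnot(length(class_proportions) == length(labels),
            abs(sum(class_proportions) - 1) < 1e-8)
  pool <- c(letters, LETTERS, as.character(0:9))
  stopifnot(alphabet_size <= length(pool))
  # worst-case layout: 5 entities, 2 planted triggers, minimal filler
  worst <- 5L * entity_length[2] + 2L * 3L + 2L + 2L
  if (worst > sentence_length[2]) {
    rlang::abort(paste0("sentence-length range too small to fit entities and ",
                        "triggers (needs up to ", worst, " characters)"))
  }
  structure(
    list(n_sentences = as.integer(n_sentences),
         alphabet = pool[seq_len(alphabet_size)],
         sentence_length = as.integer(sentence_length),
         entity_length = as.integer(entity_length),
         labels = labels,
         class_proportions = unname(class_proportions),
         triggers = trigger_table(labels),
         noise_rate = noise_rate, unknown_fraction = unknown_fraction,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

rand_filler <- function(n, config) {
  paste(sample(config$alphabet, n, replace = TRUE), collapse = "")
}

# Generate one sentence: entities in textual order, disjoint adjacent pairs
# (1,2) and (3,4) are the planned candidate pairs; a related pair's gap is
# exactly its (possibly corrupted) trigger.
synth_sentence <- function(sid, config, schema) {
  n_e <- sample(2:5, 1L)
  n_pairs <- n_e %/% 2L
  cats <- schema$categories
  types <- character(n_e)
  gaps <- character(n_pairs)
  gold <- list()
  for (p in seq_len(n_pairs)) {
    i <- 2L * p - 1L
    related <- stats::runif(1) < 1 - config$unknown_fraction
    if (related) {
      lab <- sample(config$labels, 1L, prob = config$class_proportions)
      row <- schema$labels[schema$labels$label == lab, ]
      tt <- c(row$e1_type, row$e2_type)
      trig <- config$triggers$trigger[config$triggers$label == lab]
      if (stats::runif(1) < config$noise_rate) {
        k <- sample(3L, 1L)
        substr(trig, k, k) <- sample(config$alphabet, 1L)
      }
      gaps[p] <- trig
    } else {
      crow <- cats[sample(nrow(cats), 1L), ]
      tt <- c(crow$e1_type, crow$e2_type)
      lab <- NA_character_
      gaps[p] <- rand_filler(sample(2:5, 1L), config)
    }
    if (stats::runif(1) < 0.5) tt <- rev(tt)
    types[i] <- tt[1]; types[i + 1L] <- tt[2]
    if (!is.na(lab)) gold[[p]] <- list(first = i, second = i + 1L, label = lab)
  }
  if (n_e %% 2L == 1L) types[n_e] <- sample(schema$entity_types, 1L)
  surfaces <- vapply(seq_len(n_e), function(i) {
    rand_filler(sample(config$entity_length[1]:config$entity_length[2], 1L), config)
  }, character(1))
  # segments: F0 e1 g1 e2 F1 e3 g2 e4 F2 e5 F3 (gaps only inside planned pairs)
  seg_is_filler <- logical(0); seg_text <- character(0); ent_seg <- integer(n_e)
  add <- function(txt, filler) {
    seg_text <<- c(seg_text, txt); seg_is_filler <<- c(seg_is_filler, filler)
    length(seg_text)
  }
  add(rand_filler(1L, config), TRUE)
  for (i in seq_len(n_e)) {
    ent_seg[i] <- add(surfaces[i], FALSE)
    if (i %% 2L == 1L && i < 2L * n_pairs) {
      add(gaps[(i + 1L) %/% 2L], FALSE)       # planned-pair gap: trigger/filler
    } else if (i < n_e) {
      add(rand_filler(sample(1:3, 1L), config), TRUE)
    }
  }
  add(rand_filler(1L, config), TRUE)
  base_len <- sum(nchar(seg_text))
  lo <- max(base_len, config$sentence_length[1])
  target <- if (lo >= config$sentence_length[2]) lo else
    sample(lo:config$sentence_length[2], 1L)
  extra <- target - base_len
  if (extra > 0L) {
    fill_segs <- which(seg_is_filler)
    grow <- tabulate(sample(fill_segs, extra, replace = TRUE),
                     nbins = length(seg_text))
    for (s in fill_segs) {
      if (grow[s] > 0L) seg_text[s] <- paste0(seg_text[s], rand_filler(grow[s], config))
    }
  }
  starts <- cumsum(c(0L, nchar(seg_text)))
  ents <- tibble::tibble(
    id = paste0("e", seq_len(n_e)),
    type = types,
    start = starts[ent_seg],
    end = starts[ent_seg] + nchar(surfaces)
  )
  rels <- purrr::map_dfr(purrr::compact(gold), function(g) {
    # canonical orientation: e1 is the mention whose type matches the
    # category's first type
    lab_row <- schema$labels[schema$labels$label == g$label, ]
    a <- g$first; b <- g$second
    if (types[a] != lab_row$e1_type) { tmp <- a; a <- b; b <- tmp }
    tibble::tibble(e1 = paste0("e", a), e2 = paste0("e", b), label = g$label)
  })
  if (!nrow(rels)) rels <- empty_relations()
  tibble::tibble(sid = sid, text = paste(seg_text, collapse = ""),
                 entities = list(ents), relations = list(rels))
}

#' Generate a synthetic annotated corpus
#'
#' @param config A [synth_config()].
#' @param schema A [clinical_schema()].
#' @return A validated corpus tibble (see [read_corpus()]); byte-identical
#'   across runs with the same config.
#' @export
generate_corpus <- function(config, schema = clinical_schema()) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_sentences == 0L) return(empty_corpus())
  corpus <- with_seed(config$seed, {
    dplyr::bind_rows(lapply(seq_len(config$n_sentences), function(i) {
      synth_sentence(sprintf("s%05d", i), config, schema)
    }))
  })
  validate_corpus(corpus, schema)
}

#' Non-neural trigger-matching oracle
#'
#' Labels an instance by the exact substring strictly between its two
#' mentions: if that substring equals the trigger pattern of a label
#' admissible for the pair's category, the oracle predicts that label,
#' otherwise `"unknown"`. On noise-free synthetic corpora this recovers every
#' gold label, upper-bounding any trained model.
#'
#' @param instances Instance tibble (see [generate_candidate_pairs()]).
#' @param corpus The corpus the instances refer to.
#' @param config The [synth_config()] used to generate the corpus (supplies
#'   the trigger table).
#' @return Tibble with `instance_id` and `.pred_label`.
#' @export
trigger_oracle <- function(instances, corpus, config) {
  trig <- config$triggers
  crow <- match(instances$sid, corpus$sid)
  pred <- vapply(seq_len(nrow(instances)), function(k) {
    i <- crow[k]
    ents <- corpus$entities[[i]]
    s1 <- ents$start[match(instances$e1[k], ents$id)]
    e1 <- ents$end[match(instances$e1[k], ents$id)]
    s2 <- ents$start[match(instances$e2[k], ents$id)]
    e2 <- ents$end[match(instances$e2[k], ents$id)]
    gap_lo <- min(e1, e2); gap_hi <- max(s1, s2)
    if (gap_lo > gap_hi) return("unknown")  # overlapping mentions
    gap <- substr(corpus$text[i], gap_lo + 1L, gap_hi)
    hit <- trig$label[trig$trigger == gap]
    if (length(hit) == 1L && hit %in%
        admissible_labels(clinical_schema(), instances$e1_type[k],
                          instances$e2_type[k], include_unknown = FALSE)) {
      hit
    } else {
      "unknown"
    }
  }, character(1))
  tibble::tibble(instance_id = instances$instance_id, .pred_label = pred)
}

# Exact-size stratified sample of indices by label (largest remainder).
stratified_take <- function(labels_vec, avail_idx, k) {
  if (k == 0L) return(integer(0))
  labs <- labels_vec[avail_idx]
  counts <- table(labs)
  exact <- as.numeric(counts) * k / length(avail_idx)
  take <- floor(exact)
  rem <- k - sum(take)
  if (rem > 0L) {
    ord <- order(exact - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  } else if (rem < 0L) {
    ord <- order(exact - take)
    cut <- ord[take[ord] > 0L][seq_len(-rem)]
    take[cut] <- take[cut] - 1L
  }
  take <- pmin(take, as.integer(counts))
  short <- k - sum(take)
  out <- unlist(purrr::map2(names(counts), take, function(lab, m) {
    idx <- avail_idx[labs == lab]
    if (m > 0L) sample(idx, m) else integer(0)
  }), use.names = FALSE)
  if (short > 0L) out <- c(out, sample(setdiff(avail_idx, out), short))
  out
}

#' Build a semi-supervised fixture: seed, unlabeled pool and test set
#'
#' Generates enough synthetic sentences to yield the requested instance
#' counts (after capping the `"unknown"` class at `neg_ratio` times the
#' related count), then draws three disjoint, label-stratified instance sets.
#' The unlabeled pool's labels are hidden: returned separately for
#' drift auditing and blanked (`NA`) in the pool itself.
#'
#' @param config A [synth_config()]; `n_sentences` is treated as a starting
#'   batch size and grown until the counts are met.
#' @param n_seed,n_unlabeled,n_test Exact set sizes.
#' @param neg_ratio Cap on `"unknown"` instances relative to related ones
#'   (see [downsample_unknown()]).
#' @return List with `corpus`, instance tibbles `seed`, `unlabeled`, `test`,
#'   and `unlabeled_truth` (character vector aligned with `unlabeled`).
#' @export
make_semisup_fixture <- function(config, n_seed, n_unlabeled, n_test,
                                 neg_ratio = 2) {
  schema <- clinical_schema()
  total <- n_seed + n_unlabeled + n_test
  n_sent <- max(config$n_sentences, 10L)
  inst <- NULL; corpus <- NULL
  for (attempt in 1:12) {
    cfg <- config
    cfg$n_sentences <- n_sent
    corpus <- generate_corpus(cfg, schema)
    inst <- generate_candidate_pairs(corpus, schema)
    inst <- downsample_unknown(inst, max_ratio = neg_ratio,
                               seed = child_seed(config$seed, 7L))
    if (nrow(inst) >= total) break
    n_sent <- n_sent * 2L
  }
  if (nrow(inst) < total) {
    rlang::abort("could not generate enough instances for the requested sizes")
  }
  sets <- with_seed(child_seed(config$seed, 8L), {
    test_i <- stratified_take(inst$label, seq_len(nrow(inst)), n_test)
    rest <- setdiff(seq_len(nrow(inst)), test_i)
    unl_i <- stratified_take(inst$label, rest, n_unlabeled)
    rest2 <- setdiff(rest, unl_i)
    seed_i <- stratified_take(inst$label, rest2, n_seed)
    # pigeonhole repair: every class present overall gets a seed instance
    # when the seed set is large enough to hold one of each
    labs_all <- unique(inst$label[c(test_i, unl_i, seed_i)])
    if (n_seed >= length(labs_all)) {
      for (lab in labs_all) {
        if (!any(inst$label[seed_i] == lab)) {
          donor_pool <- intersect(unl_i, which(inst$label == lab))
          if (!length(donor_pool)) donor_pool <- intersect(test_i, which(inst$label == lab))
          if (!length(donor_pool)) next
          donor <- donor_pool[1L]
          rich <- names(sort(table(inst$label[seed_i]), decreasing = TRUE))[1L]
          give <- seed_i[inst$label[seed_i] == rich][1L]
          if (donor %in% unl_i) {
            unl_i <- c(setdiff(unl_i, donor), give)
          } else {
            test_i <- c(setdiff(test_i, donor), give)
          }
          seed_i <- c(setdiff(seed_i, give), donor)
        }
      }
    }
    list(test = sort(test_i), unl = sort(unl_i), seed = sort(seed_i))
  })
  unlabeled <- inst[sets$unl, , drop = FALSE]
  truth <- unlabeled$label
  unlabeled$label <- NA_character_
  list(corpus = corpus,
       seed = inst[sets$seed, , drop = FALSE],
       unlabeled = unlabeled,
       unlabeled_truth = truth,
       test = inst[sets$test, , drop = FALSE])
}

#' Write / read relation instances as JSONL
#'
#' One instance per line with fields `instance_id`, `sid`, `e1`, `e2`,
#' `e1_type`, `e2_type`, `category` and, only when present, `label` —
#' unlabeled instances carry no label field at all.
#'
#' @param instances Instance tibble.
#' @param path File path.
#' @return `path` (writer, invisibly) or the instance tibble (reader).
#' @export
write_instances <- function(instances, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(instances))) {
    rec <- list(instance_id = instances$instance_id[i], sid = instances$sid[i],
                e1 = instances$e1[i], e2 = instances$e2[i],
                e1_type = instances$e1_type[i], e2_type = instances$e2_type[i],
                category = instances$category[i])
    if (!is.na(instances$label[i])) rec$label <- instances$label[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_instances
#' @export
read_instances <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  purrr::map_dfr(lines, function(line) {
    rec <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    tibble::tibble(instance_id = rec$instance_id, sid = rec$sid,
                   e1 = rec$e1, e2 = rec$e2,
                   e1_type = rec$e1_type, e2_type = rec$e2_type,
                   category = rec$category,
                   label = rec$label %||% NA_character_)
  })
}
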