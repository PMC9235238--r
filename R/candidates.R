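#' Generate candidate relation instances from a corpus
#'
#' Every unordered mention pair whose entity-type pair is one of the schema's
#' seven categories becomes a classification instance. Pairs matching a gold
#' relation carry its label; all other admissible pairs carry `"unknown"`;
#' pairs whose type pair is not a schema category are not emitted. Instances
#' are stored in the category's canonical type order (e.g. the test mention
#' first in Test-disease) regardless of textual order, so the classifier never
#' sees mirrored duplicates.
#'
#' @param corpus A corpus tibble from [read_corpus()] / [generate_corpus()]
#'   (or any subset of its rows).
#' @param schema A [clinical_schema()] object.
#' @return An instance tibble with one row per candidate pair: `instance_id`,
#'   `sid`, `e1`, `e2` (entity ids in canonical type order), `e1_type`,
#'   `e2_type`, `category`, `label`.
#' @export
generate_candidate_pairs <- function(corpus, schema = clinical_schema()) {
  rows <- purrr::pmap(
    list(corpus$sid, corpus$entities, corpus$relations),
    function(sid, ents, rels) {
      n <- nrow(ents)
      if (n < 2L) return(NULL)
      combos <- utils::combn(n, 2L)
      out <- vector("list", ncol(combos))
      for (k in seq_len(ncol(combos))) {
        i <- combos[1L, k]; j <- combos[2L, k]
        pc <- pair_category(schema, ents$type[i], ents$type[j])
        if (is.null(pc)) next
        if (pc$flipped) { tmp <- i; i <- j; j <- tmp }
        gold <- rels$label[(rels$e1 == ents$id[i] & rels$e2 == ents$id[j]) |
                           (rels$e1 == ents$id[j] & rels$e2 == ents$id[i])]
        label <- if (length(gold)) gold[1] else schema$unknown
        out[[k]] <- tibble::tibble(
          sid = sid, e1 = ents$id[i], e2 = ents$id[j],
          e1_type = ents$type[i], e2_type = ents$type[j],
          category = pc$category, label = label
        )
      }
      dplyr::bind_rows(out)
    }
  )
  inst <- dplyr::bind_rows(rows)
  if (!nrow(inst)) {
    inst <- tibble::tibble(
      sid = character(), e1 = character(), e2 = character(),
      e1_type = character(), e2_type = character(),
      category = character(), label = character()
    )
  }
  dplyr::mutate(inst,
                instance_id = paste(.data$sid, .data$e1, .data$e2, sep = ":"),
                .before = 1L)
}

#' Downsample "unknown" candidate instances
#'
#' Candidate-pair generation produces far more no-relation pairs than related
#' ones; this caps the `"unknown"` class at `max_ratio` times the number of
#' non-`"unknown"` instances (sampling without replacement, deterministic
#' given `seed`). Non-`"unknown"` instances are always kept.
#'
#' @param instances An instance tibble (see [generate_candidate_pairs()]).
#' @param max_ratio Maximum `unknown` : non-`unknown` ratio (default 2).
#' @param seed Integer seed for the subsample.
#' @param unknown Label string marking no-relation instances.
#' @return The filtered instance tibble (original row order preserved).
#' @export
downsample_unknown <- function(instances, max_ratio = 2, seed = 1L,
                               unknown = "unknown") {
  is_unk <- instances$label %in% unknown
  n_keep <- ceiling(max_ratio * sum(!is_unk))
  if (sum(is_unk) <= n_keep) return(instances)
  unk_idx <- which(is_unk)
  keep <- with_seed(seed, sample(unk_idx, n_keep))
  instances[sort(c(which(!is_unk), keep)), , drop = FALSE]
}

#' Stratified train/test split of relation instances
#'
#' Splits instances into disjoint, exhaustive train and test sets in the
#' given proportions, stratified by `label` so per-class metrics are stable
#' even for rare classes. Deterministic given `seed`. A label with fewer than
#' 2 instances is assigned entirely to the training side with a warning.
#'
#' @param instances An instance tibble with a `label` column.
#' @param ratio Length-2 numeric vector of (train, test) proportions summing
#'   to 1; default `c(0.8, 0.2)`.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(instances, ratio = c(0.8, 0.2), seed = 1L) {
  stopifnot(nrow(instances) > 0L, length(ratio) == 2L)
  if (abs(sum(ratio) - 1) > 1e-8) rlang::abort("split ratio must sum to 1")
  labs <- instances$label
  counts <- table(labs)
  singletons <- names(counts)[counts < 2L]
  if (length(singletons)) {
    rlang::warn(paste0("label(s) with fewer than 2 instances assigned to train: ",
                       paste(singletons, collapse = ", ")))
  }
  eligible <- setdiff(names(counts), singletons)
  exact <- as.numeric(counts[eligible]) * ratio[2]
  n_test <- floor(exact)
  extra <- round(sum(exact)) - sum(n_test)
  if (extra > 0) {
    order_frac <- order(exact - n_test, decreasing = TRUE)
    bump <- order_frac[seq_len(extra)]
    n_test[bump] <- n_test[bump] + 1L
  }
  test_idx <- with_seed(seed, {
    unlist(purrr::map2(eligible, n_test, function(lab, k) {
      idx <- which(labs == lab)
      if (k == 0L) integer() else sample(idx, k)
    }), use.names = FALSE)
  })
  list(
    train = instances[sort(setdiff(seq_along(labs), test_idx)), , drop = FALSE],
    test = instances[sort(test_idx), , drop = FALSE]
  )
}
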