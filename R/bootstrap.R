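#' Bootstrapping (self-training) configuration
#'
#' @param lambda Confidence threshold: an unlabeled instance is accepted into
#'   the reliable buffer when its predicted-class probability is strictly
#'   greater than `lambda` (default 0.7). Values >= 1 are allowed and accept
#'   nothing (useful as a sanity switch).
#' @param retrain_trigger Reliable-buffer size that triggers merging into the
#'   labeled set and retraining (default 1000); 0 forces a retrain after any
#'   round that accepted instances.
#' @param max_rounds Stall guard on the number of rounds (default 50).
#' @param cap_per_round Optional cap on acceptances per round (default `Inf`);
#'   when capping, instances are ranked by confidence descending, ties broken
#'   by instance id.
#' @param accept_unknown Accept `"unknown"` pseudo-labels into the labeled
#'   set (default `TRUE`)?
#' @param relabel Fixed to `FALSE`: pseudo-labels are frozen once merged and
#'   never re-predicted.
#' @return A `bootstrap_config` object.
#' @export
bootstrap_config <- function(lambda = 0.7, retrain_trigger = 1000L,
                             max_rounds = 50L, cap_per_round = Inf,
                             accept_unknown = TRUE, relabel = FALSE) {
  stopifnot(lambda > 0, retrain_trigger >= 0L, max_rounds >= 1L,
            cap_per_round >= 1)
  if (isTRUE(relabel)) rlang::abort("relabel = TRUE is not supported: pseudo-labels are frozen once merged")
  structure(list(lambda = lambda, retrain_trigger = as.integer(retrain_trigger),
                 max_rounds = as.integer(max_rounds),
                 cap_per_round = cap_per_round,
                 accept_unknown = isTRUE(accept_unknown), relabel = FALSE),
            class = "bootstrap_config")
}

# Internal: build the initial bootstrap state (trains the seed model).
bootstrap_init <- function(seed_enc, unlabeled_enc, bconfig, model_cfg,
                           tconfig, hidden_truth = NULL,
                           retrain_tconfig = tconfig) {
  if (!all(is.na(unlabeled_enc$label_id))) {
    rlang::abort("unlabeled pool must carry NA labels")
  }
  model <- train_relation_model(seed_enc, model_cfg, tconfig)
  list(model = model, L = seed_enc, pool = unlabeled_enc,
       status = rep("U", n_instances(unlabeled_enc)),
       pseudo = rep(NA_integer_, n_instances(unlabeled_enc)),
       truth = hidden_truth, round = 0L,
       n_pseudo_total = 0L, n_pseudo_wrong = 0L,
       bconfig = bconfig, model_cfg = model_cfg, tconfig = tconfig,
       rtconfig = retrain_tconfig,
       log = list(), stalled = FALSE)
}

#' One bootstrapping round
#'
#' Predicts every instance still in the unlabeled pool `U`; instances whose
#' confidence exceeds the threshold move (with their predicted label) into the
#' reliable buffer `R`. Whenever `|R|` reaches the retrain trigger, `R` is
#' merged into the labeled set `L` and the model is retrained from scratch on
#' the grown set. The instance multiset is conserved: `L`, `U` and `R` stay
#' pairwise disjoint and their sizes sum to a constant.
#'
#' @param state A bootstrap state as produced by [run_bootstrap()]'s
#'   initialisation (internal structure; exposed for stepwise inspection).
#' @return The updated state, with one row appended to `state$log`.
#' @export
bootstrap_round <- function(state) {
  bc <- state$bconfig
  state$round <- state$round + 1L
  u_idx <- which(state$status == "U")
  accepted <- integer(0)
  if (length(u_idx)) {
    pool_u <- enc_subset(state$pool, u_idx)
    pr <- predict_encoded(state$model$params, state$model_cfg, pool_u,
                          batch_size = max(state$tconfig$batch_size, 128L))
    ok <- pr$confidence > bc$lambda
    if (!bc$accept_unknown) {
      unk_id <- match("unknown", state$pool$labels)
      ok <- ok & pr$label_id != unk_id
    }
    cand <- which(ok)
    if (length(cand) && is.finite(bc$cap_per_round) &&
        length(cand) > bc$cap_per_round) {
      ord <- order(-pr$confidence[cand], pool_u$instance_id[cand],
                   method = "radix")
      cand <- cand[ord[seq_len(bc$cap_per_round)]]
    }
    accepted <- u_idx[cand]
    state$status[accepted] <- "R"
    state$pseudo[accepted] <- pr$label_id[cand]
  }
  err <- NA_real_
  if (!is.null(state$truth) && length(accepted)) {
    wrong <- state$pool$labels[state$pseudo[accepted]] != state$truth[accepted]
    err <- mean(wrong)
    state$n_pseudo_total <- state$n_pseudo_total + length(accepted)
    state$n_pseudo_wrong <- state$n_pseudo_wrong + sum(wrong)
  }
  retrained <- FALSE
  r_idx <- which(state$status == "R")
  if (length(r_idx) && length(r_idx) >= bc$retrain_trigger) {
    state <- bootstrap_merge_retrain(state)
    retrained <- TRUE
  }
  state$log[[state$round]] <- tibble::tibble(
    round = state$round,
    n_labeled = n_instances(state$L),
    n_unlabeled = sum(state$status == "U"),
    n_reliable = sum(state$status == "R"),
    accepted = length(accepted),
    retrained = retrained,
    pseudo_error = err,
    pseudo_error_total = if (is.null(state$truth) || state$n_pseudo_total == 0L)
      NA_real_ else state$n_pseudo_wrong / state$n_pseudo_total
  )
  if (!length(accepted)) state$stalled <- TRUE
  state
}

# Merge the reliable buffer into L and retrain from scratch.
bootstrap_merge_retrain <- function(state) {
  r_idx <- which(state$status == "R")
  merged <- enc_subset(state$pool, r_idx)
  merged$label_id <- state$pseudo[r_idx]
  state$L <- enc_bind(state$L, merged)
  state$status[r_idx] <- "L"
  tc <- state$rtconfig
  tc$seed <- child_seed(tc$seed, 1000L + state$round)
  state$model <- train_relation_model(state$L, state$model_cfg, tc)
  state
}

#' Run the bootstrapping semi-supervised training loop
#'
#' Trains an initial model on the labeled seed set, then repeatedly predicts
#' the unlabeled pool, moves confident predictions (probability strictly above
#' `lambda`) into a reliable buffer, and — each time the buffer reaches the
#' retrain trigger — merges it into the labeled set and retrains from scratch.
#' The loop ends when the pool is empty, when a round accepts nothing (stall,
#' with a warning), or at `max_rounds`; any residual reliable buffer is then
#' merged and a final retrain performed.
#'
#' @param seed_enc Labeled seed instances ([encode_instances()]).
#' @param unlabeled_enc Unlabeled pool (label ids all `NA`).
#' @param bconfig A [bootstrap_config()].
#' @param model_cfg A [model_config()].
#' @param tconfig A [train_config()] for the initial seed-set training; its
#'   seed also drives all retrains.
#' @param retrain_tconfig A [train_config()] for the retrains on the grown
#'   labeled set (default: same as `tconfig`); merged sets are usually much
#'   larger than the seed set and tolerate a larger batch.
#' @param hidden_truth Optional character vector of true labels for the pool
#'   (same order), used only to audit the per-round pseudo-label error rate
#'   (semantic-drift measurement); never visible to training.
#' @return A `bootstrap_run` object: list with `model` (final), `log`
#'   (per-round tibble: `round`, `n_labeled`, `n_unlabeled`, `n_reliable`,
#'   `accepted`, `retrained`, `pseudo_error` — the error rate among that
#'   round's acceptances — and `pseudo_error_total`, the cumulative error
#'   rate of all pseudo-labels so far, i.e. the semantic-drift trajectory),
#'   `labeled` (tibble of final labeled set: `instance_id`, `label`,
#'   `provenance`), `stalled`, `rounds`.
#' @export
run_bootstrap <- function(seed_enc, unlabeled_enc, bconfig = bootstrap_config(),
                          model_cfg = model_config(), tconfig = train_config(),
                          hidden_truth = NULL, retrain_tconfig = tconfig) {
  n_seed <- n_instances(seed_enc)
  if (!n_seed) rlang::abort("seed set is empty")
  state <- bootstrap_init(seed_enc, unlabeled_enc, bconfig, model_cfg, tconfig,
                          hidden_truth, retrain_tconfig)
  while (sum(state$status == "U") > 0L && state$round < bconfig$max_rounds) {
    state <- bootstrap_round(state)
    if (state$stalled) {
      if (any(state$status == "R")) {
        # nothing cleared the bar under the current model, but accepted
        # instances are still waiting: merge them, retrain, and try again
        # before declaring a stall
        state <- bootstrap_merge_retrain(state)
        state$stalled <- FALSE
      } else {
        rlang::warn(paste0("bootstrapping stalled at round ", state$round,
                           ": no instance cleared the threshold; ",
                           sum(state$status == "U"), " instances left unlabeled"))
        break
      }
    }
  }
  if (any(state$status == "R")) state <- bootstrap_merge_retrain(state)
  labeled <- tibble::tibble(
    instance_id = c(seed_enc$instance_id,
                    state$pool$instance_id[state$status == "L"]),
    label = c(seed_enc$labels[seed_enc$label_id],
              state$pool$labels[state$pseudo[state$status == "L"]]),
    provenance = c(rep("seed", n_seed), rep("pseudo", sum(state$status == "L")))
  )
  structure(
    list(model = state$model, log = dplyr::bind_rows(state$log),
         labeled = labeled, stalled = state$stalled, rounds = state$round,
         n_unlabeled_left = sum(state$status == "U")),
    class = "bootstrap_run"
  )
}

#' @export
print.bootstrap_run <- function(x, ...) {
  cat("<bootstrap_run> ", x$rounds, " rounds; ", sum(x$labeled$provenance == "pseudo"),
      " pseudo-labels merged; ", x$n_unlabeled_left, " left unlabeled",
      if (x$stalled) " (stalled)", "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bootstrap_run <- function(x, ...) x$log

#' @exportS3Method generics::glance
glance.bootstrap_run <- function(x, ...) {
  tibble::tibble(rounds = x$rounds,
                 n_pseudo = sum(x$labeled$provenance == "pseudo"),
                 n_unlabeled_left = x$n_unlabeled_left,
                 stalled = x$stalled,
                 max_pseudo_error = suppressWarnings(max(x$log$pseudo_error, na.rm = TRUE)))
}

#' Plot the evolution of the labeled / unlabeled / reliable sets
#'
#' @param object A `bootstrap_run`.
#' @param ... Unused.
#' @return A ggplot of set sizes per round.
#' @exportS3Method ggplot2::autoplot
autoplot.bootstrap_run <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log,
                            c("n_labeled", "n_unlabeled", "n_reliable"),
                            names_to = "set", values_to = "size")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$round, y = .data$size,
                                   colour = .data$set)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "round", y = "instances", colour = NULL,
                  title = "Bootstrapping set sizes")
}
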