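#' Training configuration
#'
#' Defaults match the full-size operating point (batch 64, learning rate
#' 0.015, Adam, dropout via [model_config()]) with early stopping on a
#' held-out validation micro-F1. For small synthetic corpora a learning rate
#' of 1e-3 to 5e-3 is usually the better choice; 0.015 is aggressive for
#' Adam and suits only large, noisy corpora.
#'
#' @param batch_size Minibatch size (default 64).
#' @param learning_rate Adam step size (default 0.015).
#' @param epochs Maximum epochs (default 30).
#' @param patience Early-stopping patience in epochs on the validation
#'   micro-F1 (default 5).
#' @param validation_fraction Fraction of the training set held out for early
#'   stopping (default 0.1; 0 disables validation and stopping is on training
#'   loss).
#' @param class_weights `NULL` (none, default) or `"inverse"` for
#'   inverse-frequency class weights (useful against a dominant `"unknown"`
#'   class).
#' @param seed Integer seed controlling initialisation, shuffling and dropout.
#' @param verbose Print a per-epoch line with loss and validation metric?
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 0.015, epochs = 30L,
                         patience = 5L, validation_fraction = 0.1,
                         class_weights = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(batch_size >= 1L, learning_rate > 0, epochs >= 1L, patience >= 1L,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 class_weights = class_weights,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

make_dropmasks <- function(cfg, B, L) {
  p <- cfg$dropout
  if (p <= 0) return(NULL)
  dims <- model_dims(cfg)
  gaps <- max(0L, cfg$gru$layers - 1L)
  list(
    gru = lapply(seq_len(gaps), function(i) {
      matrix(stats::rbinom(B * L * dims$d_g, 1L, 1 - p) / (1 - p), B * L, dims$d_g)
    }),
    fused = matrix(stats::rbinom(B * dims$d_fused, 1L, 1 - p) / (1 - p),
                   B, dims$d_fused)
  )
}

# Micro-averaged P/R/F1 over all classes except `unknown`.
micro_prf <- function(pred, gold, unknown = "unknown") {
  tp <- sum(pred == gold & gold != unknown)
  fp <- sum(pred != unknown & pred != gold)
  fn <- sum(gold != unknown & pred != gold)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

#' Train the hybrid residual-recurrent relation classifier
#'
#' Minimises mean cross-entropy over the label set (the `"unknown"` class
#' included) with Adam, early-stopping on a held-out validation micro-F1
#' (`"unknown"` excluded, as in evaluation), and returns the
#' best-by-validation parameters. Deterministic given the config seed.
#'
#' @param enc Labeled [encode_instances()] set (no `NA` labels).
#' @param model_cfg A [model_config()].
#' @param config A [train_config()].
#' @param char_init Optional pretrained character table from
#'   [pretrain_char_embeddings()] (fine-tuned during training).
#' @return A `relation_model` object: list with `params`, `model_cfg`,
#'   `labels`, `vocab_size`, `history` (per-epoch tibble), `best_epoch`,
#'   `arch` (architecture descriptor string).
#' @export
train_relation_model <- function(enc, model_cfg = model_config(),
                                 config = train_config(), char_init = NULL) {
  n <- n_instances(enc)
  if (n == 0L) rlang::abort("training set is empty")
  if (anyNA(enc$label_id)) rlang::abort("training instances must all be labeled")
  if (length(unique(enc$label_id)) < 2L) {
    rlang::abort("training set has a single label; at least 2 distinct labels required")
  }
  if (!identical(enc$spec, model_cfg$embedding)) {
    rlang::abort("embedding spec mismatch: instances were encoded with a different embedding_spec than model_cfg$embedding")
  }
  r <- length(enc$labels)
  cw <- NULL
  if (identical(config$class_weights, "inverse")) {
    freq <- tabulate(enc$label_id, nbins = r)
    cw <- ifelse(freq > 0, n / (sum(freq > 0) * pmax(freq, 1)), 0)
  }
  # stratified validation split
  val_idx <- integer(0)
  if (config$validation_fraction > 0 && n >= 10L) {
    val_idx <- with_seed(child_seed(config$seed, 1L), {
      unlist(lapply(unique(enc$label_id), function(l) {
        idx <- which(enc$label_id == l)
        k <- floor(length(idx) * config$validation_fraction)
        if (k >= 1L && length(idx) - k >= 1L) sample(idx, k) else integer(0)
      }), use.names = FALSE)
    })
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  params <- init_model_params(model_cfg, enc$vocab_size, r,
                              seed = child_seed(config$seed, 2L),
                              char_init = char_init)
  opt <- adam_init(params)
  best <- list(metric = -Inf, loss = Inf, params = params, epoch = 0L)
  history <- vector("list", config$epochs)
  wait <- 0L
  L <- ncol(enc$char)
  for (epoch in seq_len(config$epochs)) {
    ep_seed <- child_seed(config$seed, 100L + epoch)
    losses <- with_seed(ep_seed, {
      perm <- sample(tr_idx)
      batch_losses <- numeric(0)
      for (lo in seq(1L, length(perm), by = config$batch_size)) {
        idx <- perm[lo:min(lo + config$batch_size - 1L, length(perm))]
        batch <- make_batch(enc, idx)
        masks <- make_dropmasks(model_cfg, batch$B, L)
        res <- model_loss_grads(params, batch, model_cfg, masks, cw)
        if (!is.finite(res$loss)) {
          rlang::abort(paste0("training diverged (non-finite loss) at epoch ", epoch))
        }
        st <- adam_step(params, res$grads, opt, config$learning_rate)
        params <- st$params; opt <- st$state
        batch_losses <- c(batch_losses, res$loss)
      }
      batch_losses
    })
    ep_loss <- mean(losses)
    if (length(val_idx)) {
      vp <- predict_encoded(params, model_cfg, enc, val_idx, config$batch_size)
      metric <- micro_prf(enc$labels[vp$label_id],
                          enc$labels[enc$label_id[val_idx]])[["f1"]]
    } else {
      metric <- -ep_loss
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, loss = ep_loss,
                                       val_f1 = if (length(val_idx)) metric else NA_real_)
    if (config$verbose) {
      message(sprintf("epoch %d | loss %.4f | val %.4f", epoch, ep_loss, metric))
    }
    # improvement = better validation metric, or equal metric at lower
    # training loss (keeps sharpening the probabilities after the held-out
    # F1 saturates, which matters for confidence-thresholded self-training)
    if (metric > best$metric + 1e-9 ||
        (metric >= best$metric - 1e-9 && ep_loss < best$loss - 1e-6)) {
      best <- list(metric = max(metric, best$metric), loss = ep_loss,
                   params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(
    list(params = best$params, model_cfg = model_cfg, labels = enc$labels,
         vocab_size = enc$vocab_size,
         history = dplyr::bind_rows(history), best_epoch = best$epoch,
         arch = arch_descriptor(model_cfg, enc$vocab_size, r)),
    class = "relation_model"
  )
}

arch_descriptor <- function(cfg, vocab_size, r) {
  dims <- model_dims(cfg)
  paste0("dv", dims$d_v, "-conv", paste(cfg$conv$windows, collapse = "."),
         "x", cfg$conv$filters, "-depth", cfg$resnet$depth,
         "-gru", cfg$gru$hidden, "x", cfg$gru$layers,
         "-r", r, "-V", vocab_size)
}

# Internal batched prediction over encoded instances; returns a list with
# label_id and confidence vectors aligned to `idx`.
predict_encoded <- function(params, cfg, enc, idx = seq_len(n_instances(enc)),
                            batch_size = 64L) {
  lid <- integer(length(idx))
  conf <- numeric(length(idx))
  for (lo in seq(1L, length(idx), by = batch_size)) {
    sel <- lo:min(lo + batch_size - 1L, length(idx))
    batch <- make_batch(enc, idx[sel])
    probs <- model_probs(params, batch, cfg)
    lid[sel] <- max.col(probs, ties.method = "first")
    conf[sel] <- probs[cbind(seq_len(nrow(probs)), lid[sel])]
  }
  list(label_id = lid, confidence = conf)
}

#' Predict relation labels with confidences
#'
#' Evaluation-mode (dropout off, deterministic) batched prediction. The
#' confidence is the maximum softmax component, the quantity thresholded by
#' the bootstrapping loop.
#'
#' @param object A fitted `relation_model`.
#' @param enc Encoded instances (same vocabulary, spec and label set).
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return Tibble with `instance_id`, `.pred_label`, `.confidence`.
#' @export
predict.relation_model <- function(object, enc, batch_size = 64L, ...) {
  stopifnot(inherits(enc, "encoded_instances"))
  if (enc$vocab_size != object$vocab_size) {
    rlang::abort("vocabulary mismatch between model and encoded instances")
  }
  if (!identical(enc$labels, object$labels)) {
    rlang::abort("label-set mismatch between model and encoded instances")
  }
  pr <- predict_encoded(object$params, object$model_cfg, enc,
                        batch_size = batch_size)
  tibble::tibble(instance_id = enc$instance_id,
                 .pred_label = object$labels[pr$label_id],
                 .confidence = pr$confidence)
}

#' @export
print.relation_model <- function(x, ...) {
  cat("<relation_model> ", x$arch, "\n", sep = "")
  cat("  best epoch ", x$best_epoch, " of ", nrow(x$history), " run; ",
      "val micro-F1 ", formatC(max(x$history$val_f1, na.rm = TRUE), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Tidy the training history of a fitted relation model
#'
#' @param x A `relation_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `val_f1`.
#' @exportS3Method generics::tidy
tidy.relation_model <- function(x, ...) x$history

#' One-row summary of a fitted relation model
#'
#' @param x A `relation_model`.
#' @param ... Unused.
#' @return Tibble with `epochs_run`, `best_epoch`, `best_val_f1`, `n_params`,
#'   `conv_layers`.
#' @exportS3Method generics::glance
glance.relation_model <- function(x, ...) {
  leaves <- tree_leaves(x$params)
  tibble::tibble(
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_f1 = suppressWarnings(max(x$history$val_f1, na.rm = TRUE)),
    n_params = sum(vapply(leaves, function(l) length(l$value), numeric(1))),
    conv_layers = count_conv_layers(x$params)
  )
}

#' Plot the training history of a relation model
#'
#' @param object A `relation_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.relation_model <- function(object, ...) {
  hist <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history")
}
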