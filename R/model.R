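#' Convolutional stem specification
#'
#' @param windows Odd convolution window sizes for the parallel stem branches
#'   (default `c(3, 5, 7)`).
#' @param filters Filters per window (default 128); the residual stack then
#'   operates on `length(windows) * filters` channels.
#' @return A `conv_spec` object.
#' @export
conv_spec <- function(windows = c(3L, 5L, 7L), filters = 128L) {
  stopifnot(all(windows %% 2L == 1L), all(windows > 0L), filters > 0L)
  structure(list(windows = as.integer(windows), filters = as.integer(filters)),
            class = "conv_spec")
}

#' Residual encoder configuration
#'
#' Total convolution-layer count: one (multi-window) stem convolution plus two
#' depthwise convolutions per residual block, so `depth` must be odd and the
#' block count is `(depth - 1) / 2`. Depth 11 (five blocks) is the default
#' operating point; depth 9 corresponds to four blocks.
#'
#' @param depth Odd total number of convolution layers (default 11).
#' @param shortcuts Keep the identity shortcut connections (default `TRUE`;
#'   `FALSE` is an ablation switch).
#' @return A `resnet_config` object.
#' @export
resnet_config <- function(depth = 11L, shortcuts = TRUE) {
  depth <- as.integer(depth)
  if (depth < 1L || depth %% 2L == 0L) {
    rlang::abort("resnet depth must be odd: 1 stem convolution + 2 per block")
  }
  structure(list(depth = depth, n_blocks = (depth - 1L) %/% 2L,
                 shortcuts = isTRUE(shortcuts)),
            class = "resnet_config")
}

#' Bidirectional GRU configuration
#'
#' @param hidden Hidden units per direction (default 512).
#' @param layers Stacked bidirectional layers (default 3); each layer consumes
#'   the previous layer's stitched (forward + backward) output.
#' @return A `bigru_config` object.
#' @export
bigru_config <- function(hidden = 512L, layers = 3L) {
  stopifnot(hidden > 0L, layers >= 1L)
  structure(list(hidden = as.integer(hidden), layers = as.integer(layers)),
            class = "bigru_config")
}

#' Full model configuration
#'
#' Bundles the embedding, convolutional, residual and recurrent settings with
#' the dropout rate. The defaults are the full-size operating point:
#' character dim 300, position dim 25, windows 3/5/7 with 128 filters,
#' depth-11 residual encoder, 512 hidden units x 3 BiGRU layers, dropout 0.5.
#'
#' @param embedding An [embedding_spec()].
#' @param conv A [conv_spec()].
#' @param resnet A [resnet_config()].
#' @param gru A [bigru_config()].
#' @param dropout Dropout rate applied between stacked GRU layers and on the
#'   fused representation before the classifier (default 0.5).
#' @return A `model_config` object.
#' @export
model_config <- function(embedding = embedding_spec(), conv = conv_spec(),
                         resnet = resnet_config(), gru = bigru_config(),
                         dropout = 0.5) {
  stopifnot(dropout >= 0, dropout < 1)
  structure(list(embedding = embedding, conv = conv, resnet = resnet,
                 gru = gru, dropout = dropout),
            class = "model_config")
}

#' Channel dimensions implied by a model configuration
#'
#' @param cfg A [model_config()].
#' @return List with `d_v` (embedded), `d_c` (residual branch), `d_g`
#'   (recurrent branch) and `d_fused = d_c + d_g`.
#' @export
model_dims <- function(cfg) {
  d_c <- length(cfg$conv$windows) * cfg$conv$filters
  d_g <- 2L * cfg$gru$hidden
  list(d_v = embedded_dim(cfg$embedding), d_c = d_c, d_g = d_g,
       d_fused = d_c + d_g)
}

#' Count convolution layers in a configured encoder
#'
#' Structural audit: walks the parameter tree of an initialised model and
#' counts one for the (multi-window) stem plus one per depthwise convolution
#' inside the residual blocks.
#'
#' @param params A parameter tree from [init_model_params()] (or a fitted
#'   model's `$params`).
#' @return Integer convolution-layer count.
#' @export
count_conv_layers <- function(params) {
  if (inherits(params, "relation_model")) params <- params$params
  1L + 2L * length(params$blocks)
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Initialise model parameters
#'
#' Position tables are initialised uniform(-0.25, 0.25); the character table
#' from `char_init` (a pretrained table, fine-tuned during training) when
#' given, otherwise uniform(-0.25, 0.25). PAD rows (character id 0 and the PAD
#' position id) start at zero and are held there by the optimiser. Weight
#' matrices use Glorot-uniform initialisation.
#'
#' @param cfg A [model_config()].
#' @param vocab_size Character vocabulary size.
#' @param n_labels Number of output classes `r` (including `"unknown"`).
#' @param seed Integer seed (deterministic initialisation).
#' @param char_init Optional `vocab_size x d_w` pretrained character table.
#' @return A nested list of numeric parameter tensors.
#' @export
init_model_params <- function(cfg, vocab_size, n_labels, seed = 1L,
                              char_init = NULL) {
  dims <- model_dims(cfg)
  es <- cfg$embedding
  with_seed(seed, {
    E_char <- if (is.null(char_init)) {
      matrix(stats::runif(vocab_size * es$d_w, -0.25, 0.25), vocab_size, es$d_w)
    } else {
      stopifnot(nrow(char_init) == vocab_size, ncol(char_init) == es$d_w)
      unname(as.matrix(char_init))
    }
    E_char[1L, ] <- 0
    n_pos <- 2L * es$p_max + 2L
    E_p1 <- matrix(stats::runif(n_pos * es$d_p, -0.25, 0.25), n_pos, es$d_p)
    E_p2 <- matrix(stats::runif(n_pos * es$d_p, -0.25, 0.25), n_pos, es$d_p)
    E_p1[n_pos, ] <- 0
    E_p2[n_pos, ] <- 0
    stem <- lapply(cfg$conv$windows, function(h) {
      list(W = glorot(h * dims$d_v, cfg$conv$filters),
           b = numeric(cfg$conv$filters))
    })
    blocks <- lapply(seq_len(cfg$resnet$n_blocks), function(i) {
      list(w1 = matrix(stats::runif(3L * dims$d_c, -0.25, 0.25), 3L, dims$d_c),
           b1 = numeric(dims$d_c),
           w2 = matrix(stats::runif(3L * dims$d_c, -0.25, 0.25), 3L, dims$d_c),
           b2 = numeric(dims$d_c))
    })
    H <- cfg$gru$hidden
    gru <- lapply(seq_len(cfg$gru$layers), function(l) {
      d_in <- if (l == 1L) dims$d_v else dims$d_g
      one_dir <- function() {
        list(Wz = glorot(H + d_in, H), Wr = glorot(H + d_in, H),
             Wh = glorot(H + d_in, H),
             bz = numeric(H), br = numeric(H), bh = numeric(H))
      }
      list(fwd = one_dir(), bwd = one_dir())
    })
    list(
      emb = list(char = E_char, p1 = E_p1, p2 = E_p2),
      stem = stem,
      blocks = blocks,
      gru = gru,
      att_c = list(w = stats::runif(dims$d_c, -0.05, 0.05), b = 0),
      att_g = list(w = stats::runif(dims$d_g, -0.05, 0.05), b = 0),
      cls = list(W = glorot(dims$d_fused, n_labels), b = numeric(n_labels))
    )
  })
}

# Build a minibatch from encoded instances (1-based internal ids).
make_batch <- function(enc, idx) {
  B <- length(idx)
  L <- ncol(enc$char)
  mask <- matrix(0, B, L)
  lens <- enc$len[idx]
  for (b in seq_len(B)) if (lens[b] > 0L) mask[b, seq_len(lens[b])] <- 1
  list(char = enc$char[idx, , drop = FALSE] + 1L,
       pos1 = enc$pos1[idx, , drop = FALSE] + 1L,
       pos2 = enc$pos2[idx, , drop = FALSE] + 1L,
       len = lens, mask = mask,
       y = enc$label_id[idx], B = B, L = L)
}

embed_batch <- function(params, batch) {
  cid <- as.vector(t(batch$char))
  p1 <- as.vector(t(batch$pos1))
  p2 <- as.vector(t(batch$pos2))
  M <- cbind(params$emb$char[cid, , drop = FALSE],
             params$emb$p1[p1, , drop = FALSE],
             params$emb$p2[p2, , drop = FALSE])
  list(M = M, cid = cid, p1 = p1, p2 = p2)
}

# Full forward pass. `dropmasks` (training only) is a list with elements
# `gru` (list over layer gaps) and `fused`; NULL disables dropout.
model_forward <- function(params, batch, cfg, dropmasks = NULL) {
  B <- batch$B; L <- batch$L
  emb <- embed_batch(params, batch)
  cache <- list(emb = emb)
  # residual convolutional branch
  st <- conv_stem_forward(emb$M, params$stem, cfg$conv$windows, B, L)
  cache$stem <- st$caches
  Hc <- st$out
  cache$block_caches <- vector("list", length(params$blocks))
  for (i in seq_along(params$blocks)) {
    rb <- res_block_forward(Hc, params$blocks[[i]], B, L,
                            shortcut = cfg$resnet$shortcuts)
    cache$block_caches[[i]] <- rb$cache
    Hc <- rb$out
  }
  cache$Hc <- Hc
  # recurrent branch
  Hg <- emb$M
  cache$gru_caches <- vector("list", length(params$gru))
  cache$gru_inputs <- vector("list", length(params$gru))
  for (l in seq_along(params$gru)) {
    if (l > 1L && !is.null(dropmasks)) Hg <- Hg * dropmasks$gru[[l - 1L]]
    cache$gru_inputs[[l]] <- Hg
    gl <- bigru_layer_forward(Hg, batch$mask, params$gru[[l]], B, L)
    cache$gru_caches[[l]] <- gl[c("fw", "bw")]
    Hg <- gl$H
  }
  cache$Hg <- Hg
  # attention pooling per branch, fusion by concatenation
  ac <- attention_forward(Hc, batch$mask, params$att_c, B, L)
  ag <- attention_forward(Hg, batch$mask, params$att_g, B, L)
  cache$ac <- ac; cache$ag <- ag
  S <- cbind(ac$S, ag$S)
  if (!is.null(dropmasks)) S <- S * dropmasks$fused
  cache$S <- S
  cache$dropmasks <- dropmasks
  cache
}

# Loss + gradients for one batch. Returns list(loss, probs, grads).
model_loss_grads <- function(params, batch, cfg, dropmasks = NULL,
                             class_weights = NULL) {
  B <- batch$B; L <- batch$L
  cache <- model_forward(params, batch, cfg, dropmasks)
  cl <- classifier_loss(cache$S, params$cls, batch$y, class_weights)
  bk <- classifier_backward(cl$dlogits, cache$S, params$cls)
  dS <- bk$dS
  if (!is.null(dropmasks)) dS <- dS * dropmasks$fused
  dims <- model_dims(cfg)
  dSc <- dS[, seq_len(dims$d_c), drop = FALSE]
  dSg <- dS[, dims$d_c + seq_len(dims$d_g), drop = FALSE]
  ab_c <- attention_backward(dSc, cache$Hc, params$att_c, cache$ac$cache, B, L)
  ab_g <- attention_backward(dSg, cache$Hg, params$att_g, cache$ag$cache, B, L)
  # residual branch backward
  dHc <- ab_c$dH
  block_grads <- vector("list", length(params$blocks))
  for (i in rev(seq_along(params$blocks))) {
    rb <- res_block_backward(dHc, params$blocks[[i]], cache$block_caches[[i]], B, L)
    block_grads[[i]] <- rb$grads
    dHc <- rb$dC
  }
  sb <- conv_stem_backward(dHc, cache$emb$M, params$stem, cache$stem, B, L)
  dM <- sb$dM
  # recurrent branch backward
  dHg <- ab_g$dH
  gru_grads <- vector("list", length(params$gru))
  for (l in rev(seq_along(params$gru))) {
    gb <- bigru_layer_backward(dHg, cache$gru_inputs[[l]], cache$gru_caches[[l]],
                               params$gru[[l]], B, L)
    gru_grads[[l]] <- gb$grads
    dHg <- gb$dX
    if (l > 1L && !is.null(dropmasks)) dHg <- dHg * dropmasks$gru[[l - 1L]]
  }
  dM <- dM + dHg
  # embedding tables
  es <- cfg$embedding
  dchar <- dM[, seq_len(es$d_w), drop = FALSE]
  dp1 <- dM[, es$d_w + seq_len(es$d_p), drop = FALSE]
  dp2 <- dM[, es$d_w + es$d_p + seq_len(es$d_p), drop = FALSE]
  dE <- function(dmat, ids, nr) {
    out <- matrix(0, nr, ncol(dmat))
    agg <- rowsum(dmat, ids)
    out[as.integer(rownames(agg)), ] <- agg
    out
  }
  grads <- list(
    emb = list(char = dE(dchar, cache$emb$cid, nrow(params$emb$char)),
               p1 = dE(dp1, cache$emb$p1, nrow(params$emb$p1)),
               p2 = dE(dp2, cache$emb$p2, nrow(params$emb$p2))),
    stem = sb$grads,
    blocks = block_grads,
    gru = gru_grads,
    att_c = ab_c$grads,
    att_g = ab_g$grads,
    cls = bk$grads
  )
  list(loss = cl$loss, probs = cl$probs, grads = grads)
}

# Forward-only class probabilities (evaluation mode, no dropout).
model_probs <- function(params, batch, cfg) {
  cache <- model_forward(params, batch, cfg, dropmasks = NULL)
  classifier_forward(cache$S, params$cls)$probs
}

# ---- parameter-tree utilities ----

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

# Enumerate numeric leaves with their access paths (list of index vectors).
tree_leaves <- function(a, path = character()) {
  if (is.list(a)) {
    nm <- names(a)
    out <- list()
    for (i in seq_along(a)) {
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      out <- c(out, tree_leaves(a[[i]], c(path, key)))
    }
    out
  } else {
    list(list(path = path, value = a))
  }
}

tree_key <- function(a, k) {
  if (!is.null(names(a)) && k %in% names(a)) k else as.integer(k)
}

tree_get <- function(a, path) {
  for (k in path) a <- a[[tree_key(a, k)]]
  a
}

tree_set <- function(a, path, value) {
  if (!length(path)) return(value)
  key <- tree_key(a, path[1])
  a[[key]] <- tree_set(a[[key]], path[-1], value)
  a
}

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  # keep PAD rows at zero (character id 0 and the PAD position id)
  params$emb$char[1L, ] <- 0
  params$emb$p1[nrow(params$emb$p1), ] <- 0
  params$emb$p2[nrow(params$emb$p2), ] <- 0
  list(params = params, state = state)
}

#' Finite-difference gradient check
#'
#' Compares the analytic gradient of the mean cross-entropy loss with central
#' finite differences, leaf by leaf, on a given batch (dropout disabled).
#' Intended for miniature configurations where a full check is affordable.
#'
#' @param params Parameter tree from [init_model_params()].
#' @param enc Encoded instances to build the check batch from.
#' @param cfg The matching [model_config()].
#' @param idx Instance indices forming the batch (default: all).
#' @param eps Base perturbation size (default 1e-6); each element is also
#'   checked at `50 * eps` and the better agreement kept, since the small step
#'   suffers floating-point cancellation on tiny gradients while the large one
#'   can straddle a ReLU kink.
#' @param max_per_leaf Maximum number of (randomly chosen) elements checked
#'   per parameter tensor (default 20).
#' @param seed Seed for the element subsample.
#' @param jitter Uniform jitter added to every parameter before the check
#'   (default 0.05): freshly initialised models hold many preactivations
#'   exactly at the ReLU kink (zero biases, zero PAD embeddings), where the
#'   one-sided derivative makes any finite-difference comparison ill-posed;
#'   the check is therefore run at a generic nearby point.
#' @return Tibble with one row per parameter tensor: `group`, `n_checked`,
#'   `max_rel_err` (relative error `|ga - gn| / max(1e-6, |ga| + |gn|)`; the
#'   denominator floor marks gradients below the finite-difference resolution
#'   of double precision as agreeing).
#' @export
gradient_check <- function(params, enc, cfg, idx = seq_len(n_instances(enc)),
                           eps = 1e-6, max_per_leaf = 20L, seed = 1L,
                           jitter = 0.05) {
  if (jitter > 0) {
    params <- with_seed(child_seed(seed, 3L), {
      tree_map2(function(p, unused) {
        p + stats::runif(length(p), -jitter, jitter)
      }, params, params)
    })
  }
  batch <- make_batch(enc, idx)
  res <- model_loss_grads(params, batch, cfg)
  leaves <- tree_leaves(res$grads)
  loss_at <- function(p) model_loss_grads(p, batch, cfg)$loss
  rows <- with_seed(seed, {
    purrr::map(leaves, function(leaf) {
      g_analytic <- leaf$value
      n <- length(g_analytic)
      sel <- if (n > max_per_leaf) sample.int(n, max_per_leaf) else seq_len(n)
      fd <- function(j, h) {
        theta <- tree_get(params, leaf$path)
        theta_p <- theta; theta_p[j] <- theta_p[j] + h
        theta_m <- theta; theta_m[j] <- theta_m[j] - h
        lp <- loss_at(tree_set(params, leaf$path, theta_p))
        lm <- loss_at(tree_set(params, leaf$path, theta_m))
        (lp - lm) / (2 * h)
      }
      rel <- vapply(sel, function(j) {
        ga <- g_analytic[j]
        # two step sizes: the small one can hit floating-point cancellation on
        # tiny gradients, the large one can straddle a ReLU kink; a genuine
        # gradient bug disagrees at both
        err <- vapply(c(eps, 50 * eps), function(h) {
          gn <- fd(j, h)
          abs(ga - gn) / max(1e-6, abs(ga) + abs(gn))
        }, numeric(1))
        min(err)
      }, numeric(1))
      tibble::tibble(group = paste(leaf$path, collapse = "/"),
                     n_checked = length(sel), max_rel_err = max(rel))
    })
  })
  dplyr::bind_rows(rows)
}
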