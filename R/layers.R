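# Neural layer primitives: forward passes with caches and matching backward
# passes. All sequence tensors are stored as (B*L) x d matrices in b-major
# row order: row of (batch b, position t) is (b-1)*L + t. Same-length zero
# padding keeps every branch aligned to the input positions so attention
# weights index the original characters.

sigmoid <- function(x) 1 / (1 + exp(-x))

rep_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# broadcast a length-d vector over the rows of an n x d matrix
add_row <- function(M, v) M + matrix(v, nrow(M), length(v), byrow = TRUE)
mul_row <- function(M, v) M * matrix(v, nrow(M), length(v), byrow = TRUE)

# Cached row-index maps for within-sequence shifts by k positions; rows that
# fall outside their sequence are listed in `bad` and must be zeroed.
.shift_cache <- new.env(parent = emptyenv())

shift_map <- function(B, L, k) {
  key <- paste(B, L, k, sep = "_")
  hit <- .shift_cache[[key]]
  if (!is.null(hit)) return(hit)
  tp <- seq_len(L) + k
  valid <- tp >= 1L & tp <= L
  idx <- rep((seq_len(B) - 1L) * L, each = L) + rep(pmax(pmin(tp, L), 1L), B)
  out <- list(idx = idx, bad = which(rep(!valid, B)))
  .shift_cache[[key]] <- out
  out
}

# out row (b, t) = M row (b, t + k), zero outside the sequence
shift_rows <- function(M, B, L, k) {
  if (k == 0L) return(M)
  sm <- shift_map(B, L, k)
  out <- M[sm$idx, , drop = FALSE]
  if (length(sm$bad)) out[sm$bad, ] <- 0
  out
}

# ---- multi-window convolutional stem (full-channel filters) ----

conv_stem_forward <- function(M, stem, windows, B, L) {
  outs <- vector("list", length(stem))
  caches <- vector("list", length(stem))
  d <- ncol(M)
  for (wi in seq_along(stem)) {
    h <- windows[wi]
    off <- seq_len(h) - (h + 1L) %/% 2L
    pre <- rep_row(stem[[wi]]$b, B * L)
    for (j in seq_len(h)) {
      Wj <- stem[[wi]]$W[((j - 1L) * d + 1L):(j * d), , drop = FALSE]
      pre <- pre + shift_rows(M, B, L, off[j]) %*% Wj
    }
    outs[[wi]] <- pmax(pre, 0)
    caches[[wi]] <- list(active = pre > 0, off = off)
  }
  list(out = do.call(cbind, outs), caches = caches)
}

conv_stem_backward <- function(dH, M, stem, caches, B, L) {
  d <- ncol(M)
  dM <- matrix(0, nrow(M), d)
  grads <- vector("list", length(stem))
  col0 <- 0L
  for (wi in seq_along(stem)) {
    nf <- length(stem[[wi]]$b)
    dpre <- dH[, (col0 + 1L):(col0 + nf), drop = FALSE] * caches[[wi]]$active
    col0 <- col0 + nf
    off <- caches[[wi]]$off
    h <- length(off)
    dW <- matrix(0, h * d, nf)
    for (j in seq_len(h)) {
      Ms <- shift_rows(M, B, L, off[j])
      dW[((j - 1L) * d + 1L):(j * d), ] <- crossprod(Ms, dpre)
      Wj <- stem[[wi]]$W[((j - 1L) * d + 1L):(j * d), , drop = FALSE]
      dM <- dM + shift_rows(tcrossprod(dpre, Wj), B, L, -off[j])
    }
    grads[[wi]] <- list(W = dW, b = colSums(dpre))
  }
  list(dM = dM, grads = grads)
}

# ---- residual block: two depthwise (per-channel) window-3 convolutions,
# ReLU after each, identity shortcut combined before the output ReLU ----

res_block_forward <- function(C, blk, B, L, shortcut = TRUE) {
  n <- nrow(C)
  off <- c(-1L, 0L, 1L)
  pre1 <- rep_row(blk$b1, n)
  for (j in 1:3) {
    pre1 <- pre1 + mul_row(shift_rows(C, B, L, off[j]), blk$w1[j, ])
  }
  a1 <- pmax(pre1, 0)
  pre2 <- rep_row(blk$b2, n)
  for (j in 1:3) {
    pre2 <- pre2 + mul_row(shift_rows(a1, B, L, off[j]), blk$w2[j, ])
  }
  a2 <- pmax(pre2, 0)                       # f after the second convolution
  z <- if (shortcut) a2 + C else a2         # identity mapping h(c) = c
  list(out = pmax(z, 0),                    # output combiner g
       cache = list(C = C, a1 = a1, m1 = pre1 > 0, m2 = pre2 > 0, mz = z > 0,
                    shortcut = shortcut))
}

res_block_backward <- function(dout, blk, cache, B, L) {
  n <- nrow(dout); nC <- ncol(dout)
  off <- c(-1L, 0L, 1L)
  dzg <- dout * cache$mz
  dC <- if (cache$shortcut) dzg else matrix(0, n, nC)
  dz <- dzg * cache$m2
  dw2 <- matrix(0, 3, nC)
  da1 <- matrix(0, n, nC)
  for (j in 1:3) {
    dw2[j, ] <- colSums(shift_rows(cache$a1, B, L, off[j]) * dz)
    da1 <- da1 + mul_row(shift_rows(dz, B, L, -off[j]), blk$w2[j, ])
  }
  db2 <- colSums(dz)
  dpre1 <- da1 * cache$m1
  dw1 <- matrix(0, 3, nC)
  for (j in 1:3) {
    dw1[j, ] <- colSums(shift_rows(cache$C, B, L, off[j]) * dpre1)
    dC <- dC + mul_row(shift_rows(dpre1, B, L, -off[j]), blk$w1[j, ])
  }
  db1 <- colSums(dpre1)
  list(dC = dC, grads = list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2))
}

# ---- single GRU step (exported for oracle-level testing) ----

#' One gated-recurrent-unit update
#'
#' Computes the standard GRU update for a single time step:
#' `z = sigmoid(Wz [h, x] + bz)`, `r = sigmoid(Wr [h, x] + br)`,
#' `hcand = tanh(Wh [r * h, x] + bh)`, `h' = (1 - z) * h + z * hcand`,
#' where `*` is the elementwise product and `[h, x]` concatenation.
#'
#' @param x Input vector (length `d`).
#' @param h_prev Previous hidden state (length `H`).
#' @param params List with matrices `Wz`, `Wr`, `Wh` of shape `(H + d) x H`
#'   and bias vectors `bz`, `br`, `bh` of length `H`.
#' @return List with `h` (new state) and gate values `z`, `r`, `hcand`.
#' @export
gru_step <- function(x, h_prev, params) {
  H <- length(params$bz)
  stopifnot(nrow(params$Wz) == H + length(x))
  a <- c(h_prev, x)
  z <- sigmoid(drop(a %*% params$Wz) + params$bz)
  r <- sigmoid(drop(a %*% params$Wr) + params$br)
  hcand <- tanh(drop(c(r * h_prev, x) %*% params$Wh) + params$bh)
  h <- (1 - z) * h_prev + z * hcand
  list(h = h, z = z, r = r, hcand = hcand)
}

# ---- batched, mask-aware GRU over a padded sequence. The gate weight
# matrices act on the concatenation [h, x]; their input-projection halves are
# applied to the whole sequence in one BLAS call outside the time loop. ----

gru_dir_forward <- function(Xmat, mask, params, B, L, reverse = FALSE) {
  H <- length(params$bz)
  d <- nrow(params$Wz) - H
  hseq <- seq_len(H)
  Wz_h <- params$Wz[hseq, , drop = FALSE]; Wz_x <- params$Wz[H + seq_len(d), , drop = FALSE]
  Wr_h <- params$Wr[hseq, , drop = FALSE]; Wr_x <- params$Wr[H + seq_len(d), , drop = FALSE]
  Wh_h <- params$Wh[hseq, , drop = FALSE]; Wh_x <- params$Wh[H + seq_len(d), , drop = FALSE]
  XZ <- add_row(Xmat %*% Wz_x, params$bz)
  XR <- add_row(Xmat %*% Wr_x, params$br)
  XH <- add_row(Xmat %*% Wh_x, params$bh)
  h <- matrix(0, B, H)
  Hout <- matrix(0, B * L, H)
  steps <- if (reverse) rev(seq_len(L)) else seq_len(L)
  cache <- vector("list", L)
  for (t in steps) {
    rows <- (seq_len(B) - 1L) * L + t
    z <- sigmoid(h %*% Wz_h + XZ[rows, , drop = FALSE])
    r <- sigmoid(h %*% Wr_h + XR[rows, , drop = FALSE])
    hc <- tanh((r * h) %*% Wh_h + XH[rows, , drop = FALSE])
    hnew <- (1 - z) * h + z * hc
    m <- mask[, t]
    Hout[rows, ] <- hnew * m
    cache[[t]] <- list(hprev = h, z = z, r = r, hc = hc, m = m)
    h <- hnew * m + h * (1 - m)
  }
  list(H = Hout, cache = cache)
}

gru_dir_backward <- function(dH, Xmat, cache, params, B, L, reverse = FALSE) {
  H <- length(params$bz)
  d <- nrow(params$Wz) - H
  hseq <- seq_len(H)
  Wz_h <- params$Wz[hseq, , drop = FALSE]; Wz_x <- params$Wz[H + seq_len(d), , drop = FALSE]
  Wr_h <- params$Wr[hseq, , drop = FALSE]; Wr_x <- params$Wr[H + seq_len(d), , drop = FALSE]
  Wh_h <- params$Wh[hseq, , drop = FALSE]; Wh_x <- params$Wh[H + seq_len(d), , drop = FALSE]
  dWz_h <- matrix(0, H, H); dWr_h <- dWz_h; dWh_h <- dWz_h
  DZ <- matrix(0, B * L, H); DR <- DZ; DH <- DZ
  dcarry <- matrix(0, B, H)
  steps <- if (reverse) seq_len(L) else rev(seq_len(L))
  for (t in steps) {
    ca <- cache[[t]]
    rows <- (seq_len(B) - 1L) * L + t
    m <- ca$m
    dhnew <- (dH[rows, , drop = FALSE] + dcarry) * m
    dhprev <- dcarry * (1 - m)
    dz <- dhnew * (ca$hc - ca$hprev)
    dhc <- dhnew * ca$z
    dhprev <- dhprev + dhnew * (1 - ca$z)
    dpre_h <- dhc * (1 - ca$hc^2)
    DH[rows, ] <- dpre_h
    dWh_h <- dWh_h + crossprod(ca$r * ca$hprev, dpre_h)
    drh <- tcrossprod(dpre_h, Wh_h)
    dhprev <- dhprev + drh * ca$r
    dr <- drh * ca$hprev
    dzpre <- dz * ca$z * (1 - ca$z)
    drpre <- dr * ca$r * (1 - ca$r)
    DZ[rows, ] <- dzpre
    DR[rows, ] <- drpre
    dWz_h <- dWz_h + crossprod(ca$hprev, dzpre)
    dWr_h <- dWr_h + crossprod(ca$hprev, drpre)
    dhprev <- dhprev + tcrossprod(dzpre, Wz_h) + tcrossprod(drpre, Wr_h)
    dcarry <- dhprev
  }
  dX <- tcrossprod(DZ, Wz_x) + tcrossprod(DR, Wr_x) + tcrossprod(DH, Wh_x)
  grads <- list(
    Wz = rbind(dWz_h, crossprod(Xmat, DZ)),
    Wr = rbind(dWr_h, crossprod(Xmat, DR)),
    Wh = rbind(dWh_h, crossprod(Xmat, DH)),
    bz = colSums(DZ), br = colSums(DR), bh = colSums(DH)
  )
  list(dX = dX, grads = grads)
}

bigru_layer_forward <- function(Xmat, mask, layer, B, L) {
  fw <- gru_dir_forward(Xmat, mask, layer$fwd, B, L, reverse = FALSE)
  bw <- gru_dir_forward(Xmat, mask, layer$bwd, B, L, reverse = TRUE)
  list(H = cbind(fw$H, bw$H), fw = fw$cache, bw = bw$cache)
}

bigru_layer_backward <- function(dH, Xmat, cache, layer, B, L) {
  H <- length(layer$fwd$bz)
  f <- gru_dir_backward(dH[, seq_len(H), drop = FALSE], Xmat, cache$fw,
                        layer$fwd, B, L, reverse = FALSE)
  b <- gru_dir_backward(dH[, H + seq_len(H), drop = FALSE], Xmat, cache$bw,
                        layer$bwd, B, L, reverse = TRUE)
  list(dX = f$dX + b$dX, grads = list(fwd = f$grads, bwd = b$grads))
}

# ---- attention pooling: scalar score tanh(w . H_i + b) per position,
# masked softmax over the unpadded prefix, weighted sum ----

attention_forward <- function(Hmat, mask, att, B, L) {
  if (any(rowSums(mask) == 0)) rlang::abort("attention over an empty (zero-length) sequence")
  u <- tanh(as.vector(Hmat %*% att$w) + att$b)
  sc <- matrix(u, B, L, byrow = TRUE)
  sc[mask == 0] <- -Inf
  mx <- apply(sc, 1L, max)
  e <- exp(sc - mx)
  e[mask == 0] <- 0
  a <- e / rowSums(e)
  wv <- as.vector(t(a))
  S <- rowsum(Hmat * wv, group = rep(seq_len(B), each = L))
  dimnames(S) <- NULL
  list(S = S, a = a, cache = list(u = u, a = a, wv = wv))
}

attention_backward <- function(dS, Hmat, att, cache, B, L) {
  grp <- rep(seq_len(B), each = L)
  dSexp <- dS[grp, , drop = FALSE]
  dH <- dSexp * cache$wv
  da <- matrix(rowSums(Hmat * dSexp), B, L, byrow = TRUE)
  a <- cache$a
  dsc <- a * (da - rowSums(da * a))
  du <- as.vector(t(dsc))
  dpre <- du * (1 - cache$u^2)
  dw <- as.vector(crossprod(Hmat, dpre))
  db <- sum(dpre)
  dH <- dH + outer(dpre, att$w)
  list(dH = dH, grads = list(w = dw, b = db))
}

# ---- dense softmax head with cross-entropy ----

softmax_rows <- function(Z) {
  e <- exp(Z - apply(Z, 1L, max))
  e / rowSums(e)
}

classifier_forward <- function(S, cls) {
  logits <- add_row(S %*% cls$W, cls$b)
  list(probs = softmax_rows(logits))
}

# Mean cross-entropy over the batch; returns loss, probs and dlogits.
classifier_loss <- function(S, cls, y, class_weights = NULL) {
  B <- nrow(S)
  probs <- classifier_forward(S, cls)$probs
  p_true <- probs[cbind(seq_len(B), y)]
  w <- if (is.null(class_weights)) rep(1, B) else class_weights[y]
  loss <- -sum(w * log(pmax(p_true, 1e-300))) / sum(w)
  onehot <- matrix(0, B, ncol(probs))
  onehot[cbind(seq_len(B), y)] <- 1
  dlogits <- (probs - onehot) * (w / sum(w))
  list(loss = loss, probs = probs, dlogits = dlogits)
}

classifier_backward <- function(dlogits, S, cls) {
  list(dS = tcrossprod(dlogits, cls$W),
       grads = list(W = crossprod(S, dlogits), b = colSums(dlogits)))
}
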