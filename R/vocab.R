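#' Build a character vocabulary from a corpus
#'
#' Characters occurring at least `min_count` times get contiguous ids after
#' the two reserved entries: PAD (id 0) and UNK (id 1). Ordering is by
#' frequency (descending), ties broken by code point, so two corpora with the
#' same counts yield identical vocabularies.
#'
#' @param corpus A corpus tibble (see [read_corpus()]).
#' @param min_count Minimum occurrence count for a character to get its own id.
#' @return A `char_vocab` object: list with `ids` (named integer vector of
#'   0-based ids, names are characters; includes `<pad>` and `<unk>`),
#'   `pad_id` (0) and `unk_id` (1).
#' @export
build_vocabulary <- function(corpus, min_count = 1L) {
  stopifnot(nrow(corpus) > 0L)
  chars <- unlist(strsplit(corpus$text, "", fixed = TRUE), use.names = FALSE)
  counts <- table(chars)
  keep <- counts[counts >= min_count]
  ord <- order(-as.integer(keep), names(keep), method = "radix")
  syms <- names(keep)[ord]
  ids <- seq_along(syms) + 1L
  all_ids <- c(0L, 1L, ids)
  names(all_ids) <- c("<pad>", "<unk>", syms)
  structure(list(ids = all_ids, pad_id = 0L, unk_id = 1L), class = "char_vocab")
}

#' @export
print.char_vocab <- function(x, ...) {
  cat("<char_vocab> ", length(x$ids), " entries (incl. <pad>, <unk>)\n", sep = "")
  invisible(x)
}

#' Vocabulary size
#' @param vocab A `char_vocab`.
#' @return Integer number of entries (including PAD and UNK).
#' @export
vocab_size <- function(vocab) length(vocab$ids)

# Map a character vector of single characters to 0-based vocabulary ids.
chars_to_ids <- function(chars, vocab) {
  ids <- unname(vocab$ids[chars])
  ids[is.na(ids)] <- vocab$unk_id
  as.integer(ids)
}

#' Pretrain character embeddings with skip-gram negative sampling
#'
#' A compact word2vec-style trainer over the corpus characters: skip-gram
#' objective with negative sampling (unigram distribution raised to 3/4),
#' mini-batched vectorised SGD. Used to initialise the trainable character
#' table of the relation model; the PAD row is kept at zero.
#'
#' @param corpus A corpus tibble.
#' @param vocab A [build_vocabulary()] result.
#' @param dim Embedding dimension (default 300).
#' @param window Symmetric context window (default 5).
#' @param epochs Passes over the pair list (default 10).
#' @param negative Negative samples per positive pair (default 5).
#' @param learning_rate SGD step size (default 0.05).
#' @param seed Integer seed; runs are deterministic given seed and corpus.
#' @return A `vocab_size x dim` numeric matrix, one row per vocabulary entry
#'   (row order = vocabulary id order), PAD row all-zero, with rownames set to
#'   the vocabulary characters.
#' @export
pretrain_char_embeddings <- function(corpus, vocab, dim = 300L, window = 5L,
                                     epochs = 10L, negative = 5L,
                                     learning_rate = 0.05, seed = 1L) {
  V <- vocab_size(vocab)
  with_seed(seed, {
    W_in <- matrix(stats::runif(V * dim, -0.5 / dim, 0.5 / dim), V, dim)
    W_out <- matrix(0, V, dim)
    seqs <- lapply(strsplit(corpus$text, "", fixed = TRUE),
                   function(ch) chars_to_ids(ch, vocab) + 1L)  # 1-based rows
    centers <- integer(0); contexts <- integer(0)
    for (s in seqs) {
      n <- length(s)
      if (n < 2L) next
      for (k in seq_len(window)) {
        if (n > k) {
          centers <- c(centers, s[seq_len(n - k)], s[(k + 1L):n])
          contexts <- c(contexts, s[(k + 1L):n], s[seq_len(n - k)])
        }
      }
    }
    if (!length(centers)) {
      rlang::warn("corpus too small for the chosen window; falling back to random initialization")
      W_in[vocab$pad_id + 1L, ] <- 0
      rownames(W_in) <- names(vocab$ids)
      return(W_in)
    }
    freq <- tabulate(unlist(seqs, use.names = FALSE), nbins = V)
    neg_prob <- freq^0.75
    neg_prob <- neg_prob / sum(neg_prob)
    n_pairs <- length(centers)
    chunk <- 2048L
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n_pairs)
      for (lo in seq(1L, n_pairs, by = chunk)) {
        sel <- perm[lo:min(lo + chunk - 1L, n_pairs)]
        ctr <- centers[sel]; pos <- contexts[sel]
        m <- length(sel)
        neg <- matrix(sample.int(V, m * negative, replace = TRUE, prob = neg_prob),
                      m, negative)
        vin <- W_in[ctr, , drop = FALSE]
        # positive pairs
        vpos <- W_out[pos, , drop = FALSE]
        gpos <- 1 / (1 + exp(-rowSums(vin * vpos))) - 1   # sigmoid(x) - label
        dvin <- gpos * vpos
        dpos <- gpos * vin
        # negative pairs
        for (j in seq_len(negative)) {
          vneg <- W_out[neg[, j], , drop = FALSE]
          gneg <- 1 / (1 + exp(-rowSums(vin * vneg)))
          dvin <- dvin + gneg * vneg
          agg <- rowsum(gneg * vin, neg[, j])
          rid <- as.integer(rownames(agg))
          W_out[rid, ] <- W_out[rid, ] - learning_rate * agg
        }
        agg <- rowsum(dvin, ctr)
        rid <- as.integer(rownames(agg))
        W_in[rid, ] <- W_in[rid, ] - learning_rate * agg
        agg <- rowsum(dpos, pos)
        rid <- as.integer(rownames(agg))
        W_out[rid, ] <- W_out[rid, ] - learning_rate * agg
      }
    }
    W_in[vocab$pad_id + 1L, ] <- 0
    rownames(W_in) <- names(vocab$ids)
    W_in
  })
}

#' Write / read an embedding table in word2vec text format
#'
#' Header line `"|V| dim"`, then one line per token: the token followed by
#' `dim` numbers, space-separated.
#'
#' @param emb Numeric matrix with rownames (tokens).
#' @param path File path.
#' @return `path` (write) or the matrix (read), invisibly for the writer.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(emb), ncol(emb)), con)
  for (i in seq_len(nrow(emb))) {
    writeLines(paste(rownames(emb)[i],
                     paste(sprintf("%.8g", emb[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  emb <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(emb) <- vapply(parts, `[[`, "", 1L)
  stopifnot(nrow(emb) == hdr[1], ncol(emb) == hdr[2])
  emb
}
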