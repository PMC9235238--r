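#' Embedding layer specification
#'
#' Each character is represented by the concatenation of a character embedding
#' (dimension `d_w`) and two position embeddings (dimension `d_p` each), one
#' per target entity, giving a per-character vector of dimension
#' `d_v = d_w + 2 d_p` (350 at the defaults).
#'
#' @param d_w Character-embedding dimension (default 300).
#' @param d_p Position-embedding dimension (default 25).
#' @param p_max Maximum absolute relative distance before clipping
#'   (default 100); the position table has `2 * p_max + 2` rows (distances
#'   `-p_max..p_max` plus a dedicated PAD position).
#' @param L_max Maximum sentence length in characters (default 200); longer
#'   sentences are truncated to a window centred on the entity pair.
#' @return An `embedding_spec` object.
#' @export
embedding_spec <- function(d_w = 300L, d_p = 25L, p_max = 100L, L_max = 200L) {
  stopifnot(d_w > 0, d_p > 0, p_max > 0, L_max > 0)
  structure(list(d_w = as.integer(d_w), d_p = as.integer(d_p),
                 p_max = as.integer(p_max), L_max = as.integer(L_max)),
            class = "embedding_spec")
}

#' Per-character embedded dimension `d_v = d_w + 2 d_p`
#' @param spec An [embedding_spec()].
#' @return Integer.
#' @export
embedded_dim <- function(spec) spec$d_w + 2L * spec$d_p

#' Relative distance from a character to an entity anchor
#'
#' The anchor is the first character of the mention; the distance is
#' `i - e_start`, clipped to `[-p_max, p_max]`. A character 7 positions right
#' of the first entity's anchor and 5 positions left of the second's gets
#' distances `(+7, -5)`.
#'
#' @param i Character index (0-based), vectorised.
#' @param e_start Entity start index (0-based).
#' @param p_max Clipping bound (default `Inf` = no clipping).
#' @return Integer-valued distances.
#' @examples
#' relative_position(9, 2)  # +7
#' relative_position(0, 5)  # -5
#' @export
relative_position <- function(i, e_start, p_max = Inf) {
  pmin(pmax(i - e_start, -p_max), p_max)
}

#' Non-negative position id for a relative distance
#'
#' Offsets a (clipped) distance by `p_max`, giving ids in `[0, 2 p_max]`;
#' the PAD position id is `2 p_max + 1`.
#'
#' @param d Relative distance(s), already clipped or not.
#' @param p_max Clipping bound.
#' @return Integer ids.
#' @export
position_id <- function(d, p_max) {
  as.integer(pmin(pmax(d, -p_max), p_max) + p_max)
}

pad_position_id <- function(p_max) 2L * p_max + 1L

#' Encode relation instances as padded id sequences
#'
#' Realizes the embedding-layer input: for each instance, the sentence's
#' characters become vocabulary ids (UNK fallback) and each character gets two
#' position ids (relative distance to each target entity's first character,
#' clipped to `p_max` and offset to be non-negative). Sequences are PAD-filled
#' to `L_max`; sentences longer than `L_max` are truncated to a window centred
#' on the entity pair, and an instance whose entity span would be destroyed by
#' truncation is dropped with a warning.
#'
#' @param instances Instance tibble (see [generate_candidate_pairs()]); the
#'   `label` column may contain `NA` for not-yet-labeled instances.
#' @param corpus The corpus tibble the instances refer to.
#' @param vocab A [build_vocabulary()] result.
#' @param spec An [embedding_spec()].
#' @param labels Label set in output order (default: the 11 schema labels
#'   plus `"unknown"`); instance labels must be in this set or `NA`.
#' @return An `encoded_instances` object: list with integer matrices `char`,
#'   `pos1`, `pos2` (`n x L_max`, 0-based ids), integer vectors `len` and
#'   `label_id` (1-based index into `labels`, `NA` when unlabeled), plus
#'   `labels`, `instance_id`, `spec`, `vocab_size`.
#' @export
encode_instances <- function(instances, corpus, vocab, spec = embedding_spec(),
                             labels = schema_labels(include_unknown = TRUE)) {
  stopifnot(inherits(vocab, "char_vocab"), inherits(spec, "embedding_spec"))
  bad <- setdiff(stats::na.omit(unique(instances$label)), labels)
  if (length(bad)) {
    rlang::abort(paste0("instance labels outside the label set: ",
                        paste(bad, collapse = ", ")))
  }
  L <- spec$L_max
  n <- nrow(instances)
  crow <- match(instances$sid, corpus$sid)
  if (anyNA(crow)) rlang::abort("instance references a sentence id absent from the corpus")
  char <- matrix(0L, n, L); pos1 <- matrix(0L, n, L); pos2 <- matrix(0L, n, L)
  pos1[] <- pad_position_id(spec$p_max); pos2[] <- pad_position_id(spec$p_max)
  len <- integer(n)
  keep <- rep(TRUE, n)
  for (k in seq_len(n)) {
    i <- crow[k]
    text <- corpus$text[i]
    ents <- corpus$entities[[i]]
    s1 <- ents$start[match(instances$e1[k], ents$id)]
    e1e <- ents$end[match(instances$e1[k], ents$id)]
    s2 <- ents$start[match(instances$e2[k], ents$id)]
    e2e <- ents$end[match(instances$e2[k], ents$id)]
    nch <- nchar(text)
    off <- 0L
    if (nch > L) {
      lo <- min(s1, s2); hi <- max(e1e, e2e)
      centre <- floor((lo + hi) / 2)
      off <- max(0L, min(centre - L %/% 2L, nch - L))
      if (s1 < off || s2 < off || e1e > off + L || e2e > off + L) {
        rlang::warn(paste0("instance '", instances$instance_id[k],
                           "': entity span destroyed by truncation; instance dropped"))
        keep[k] <- FALSE
        next
      }
      text <- substr(text, off + 1L, off + L)
      nch <- L
    }
    ch <- strsplit(text, "", fixed = TRUE)[[1]]
    idx <- seq_len(nch)
    char[k, idx] <- chars_to_ids(ch, vocab)
    p <- idx - 1L
    pos1[k, idx] <- position_id(relative_position(p, s1 - off, spec$p_max), spec$p_max)
    pos2[k, idx] <- position_id(relative_position(p, s2 - off, spec$p_max), spec$p_max)
    len[k] <- nch
  }
  lid <- match(instances$label, labels)
  structure(
    list(char = char[keep, , drop = FALSE], pos1 = pos1[keep, , drop = FALSE],
         pos2 = pos2[keep, , drop = FALSE], len = len[keep],
         label_id = lid[keep], labels = labels,
         instance_id = instances$instance_id[keep],
         spec = spec, vocab_size = vocab_size(vocab)),
    class = "encoded_instances"
  )
}

#' Number of encoded instances
#' @param enc An `encoded_instances` object.
#' @return Integer.
#' @export
n_instances <- function(enc) nrow(enc$char)

#' Subset encoded instances by row index
#' @param enc An `encoded_instances` object.
#' @param i Integer (or logical) index vector.
#' @return An `encoded_instances` object.
#' @export
enc_subset <- function(enc, i) {
  out <- enc
  out$char <- enc$char[i, , drop = FALSE]
  out$pos1 <- enc$pos1[i, , drop = FALSE]
  out$pos2 <- enc$pos2[i, , drop = FALSE]
  out$len <- enc$len[i]
  out$label_id <- enc$label_id[i]
  out$instance_id <- enc$instance_id[i]
  out
}

#' Concatenate compatible encoded instance sets
#' @param ... `encoded_instances` objects sharing spec, labels and vocabulary.
#' @return An `encoded_instances` object.
#' @export
enc_bind <- function(...) {
  parts <- list(...)
  ref <- parts[[1]]
  for (p in parts[-1]) {
    stopifnot(identical(p$labels, ref$labels),
              identical(p$spec, ref$spec),
              p$vocab_size == ref$vocab_size)
  }
  out <- ref
  out$char <- do.call(rbind, lapply(parts, `[[`, "char"))
  out$pos1 <- do.call(rbind, lapply(parts, `[[`, "pos1"))
  out$pos2 <- do.call(rbind, lapply(parts, `[[`, "pos2"))
  out$len <- unlist(lapply(parts, `[[`, "len"), use.names = FALSE)
  out$label_id <- unlist(lapply(parts, `[[`, "label_id"), use.names = FALSE)
  out$instance_id <- unlist(lapply(parts, `[[`, "instance_id"), use.names = FALSE)
  out
}

#' @export
print.encoded_instances <- function(x, ...) {
  cat("<encoded_instances> ", n_instances(x), " instances, L_max=", x$spec$L_max,
      ", d_v=", embedded_dim(x$spec), ", ", length(x$labels), " labels\n", sep = "")
  invisible(x)
}
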