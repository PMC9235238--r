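#' Read an annotated relation corpus (JSONL)
#'
#' One sentence per line:
#' `{"sid", "text", "entities": [{"id", "type", "start", "end"}],
#'   "relations": [{"e1", "e2", "label"}]}`.
#' Spans are 0-based half-open code-point intervals into `text`. Every
#' sentence is validated against the schema on load: spans must fall inside
#' the sentence, entity ids must be unique and referenced relations must carry
#' a label admissible for the pair's category.
#'
#' @param path Path to a UTF-8 JSONL file.
#' @param schema A [clinical_schema()] object.
#' @return A corpus tibble with columns `sid`, `text`, `entities`
#'   (list-column of tibbles `id`, `type`, `start`, `end`, `surface`) and
#'   `relations` (list-column of tibbles `e1`, `e2`, `label`), one row per
#'   sentence, input order preserved.
#' @seealso [write_corpus()], [generate_candidate_pairs()]
#' @export
read_corpus <- function(path, schema = clinical_schema()) {
  if (!file.exists(path)) {
    rlang::abort(paste0("corpus file does not exist: ", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_corpus())
  rows <- purrr::imap(lines, function(line, i) {
    rec <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = FALSE),
      error = function(e) {
        rlang::abort(paste0("malformed JSON on line ", i, ": ", conditionMessage(e)))
      }
    )
    for (fld in c("sid", "text")) {
      if (is.null(rec[[fld]])) {
        rlang::abort(paste0("line ", i, ": missing field '", fld, "'"))
      }
    }
    ents <- purrr::map_dfr(rec$entities, function(e) {
      tibble::tibble(
        id = as.character(e$id), type = as.character(e$type),
        start = as.integer(e$start), end = as.integer(e$end)
      )
    })
    if (!nrow(ents)) ents <- empty_entities()
    rels <- purrr::map_dfr(rec$relations, function(r) {
      tibble::tibble(e1 = as.character(r$e1), e2 = as.character(r$e2),
                     label = as.character(r$label))
    })
    if (!nrow(rels)) rels <- empty_relations()
    tibble::tibble(
      sid = as.character(rec$sid), text = as.character(rec$text),
      entities = list(ents), relations = list(rels)
    )
  })
  corpus <- dplyr::bind_rows(rows)
  validate_corpus(corpus, schema)
}

#' Write a corpus tibble as JSONL
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, f))` reproduces
#' `x` up to key ordering.
#'
#' @param corpus A corpus tibble (see [read_corpus()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    ents <- corpus$entities[[i]]
    rec <- list(
      sid = corpus$sid[i],
      text = corpus$text[i],
      entities = purrr::pmap(
        list(ents$id, ents$type, ents$start, ents$end),
        function(id, type, start, end) list(id = id, type = type, start = start, end = end)
      ),
      relations = purrr::pmap(
        list(corpus$relations[[i]]$e1, corpus$relations[[i]]$e2,
             corpus$relations[[i]]$label),
        function(e1, e2, label) list(e1 = e1, e2 = e2, label = label)
      )
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = FALSE)
  }
  invisible(path)
}

empty_entities <- function() {
  tibble::tibble(id = character(), type = character(),
                 start = integer(), end = integer(), surface = character())
}

empty_relations <- function() {
  tibble::tibble(e1 = character(), e2 = character(), label = character())
}

empty_corpus <- function() {
  tibble::tibble(sid = character(), text = character(),
                 entities = list(), relations = list())
}

#' Validate a corpus tibble against the schema
#'
#' Checks span bounds, id uniqueness, entity types, relation references and
#' label admissibility; fills in the `surface` column of each entity table
#' from the sentence text.
#'
#' @inheritParams write_corpus
#' @param schema A [clinical_schema()] object.
#' @return The validated corpus tibble (with `surface` populated).
#' @export
validate_corpus <- function(corpus, schema = clinical_schema()) {
  corpus$entities <- purrr::pmap(
    list(corpus$sid, corpus$text, corpus$entities),
    function(sid, text, ents) {
      n <- nchar(text)
      bad <- which(!(ents$start >= 0 & ents$start < ents$end & ents$end <= n))
      if (length(bad)) {
        rlang::abort(paste0("sentence '", sid, "': entity '", ents$id[bad[1]],
                            "' span [", ents$start[bad[1]], ",", ents$end[bad[1]],
                            ") outside sentence of length ", n))
      }
      if (anyDuplicated(ents$id)) {
        rlang::abort(paste0("sentence '", sid, "': duplicate entity ids"))
      }
      bad <- which(!ents$type %in% schema$entity_types)
      if (length(bad)) {
        rlang::abort(paste0("sentence '", sid, "': unknown entity type '",
                            ents$type[bad[1]], "'"))
      }
      ents$surface <- substr(rep(text, nrow(ents)), ents$start + 1L, ents$end)
      ents
    }
  )
  purrr::pwalk(
    list(corpus$sid, corpus$entities, corpus$relations),
    function(sid, ents, rels) {
      missing <- setdiff(c(rels$e1, rels$e2), ents$id)
      if (length(missing)) {
        rlang::abort(paste0("sentence '", sid, "': relation references unknown entity '",
                            missing[1], "'"))
      }
      for (k in seq_len(nrow(rels))) {
        t1 <- ents$type[match(rels$e1[k], ents$id)]
        t2 <- ents$type[match(rels$e2[k], ents$id)]
        if (!is_admissible(schema, rels$label[k], t1, t2)) {
          pc <- pair_category(schema, t1, t2)
          cat_name <- if (is.null(pc)) paste0("(", t1, ", ", t2, ") [not a schema category]") else pc$category
          rlang::abort(paste0("sentence '", sid, "': label '", rels$label[k],
                              "' not admissible for pair category ", cat_name))
        }
      }
    }
  )
  corpus
}

#' Split a clinical document into sentences
#'
#' Sentences are delimited by the ideographic full stop `"。"`; the ASCII
#' period is deliberately not a boundary because decimal values are common in
#' clinical text. Delimiters are dropped and empty segments suppressed.
#'
#' @param document A character string (length-1).
#' @return Character vector of sentences (possibly empty).
#' @examples
#' segment_sentences("A。B。")  # c("A", "B")
#' @export
segment_sentences <- function(document) {
  stopifnot(length(document) == 1L)
  parts <- strsplit(document, "。", fixed = TRUE)[[1]]
  parts[nzchar(parts)]
}
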