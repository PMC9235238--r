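#' Clinical relation schema
#'
#' The schema ties the five clinical entity types (`treatment`, `disease`,
#' `symptom`, `test`, `position`) to seven admissible entity-pair categories,
#' each carrying a fixed set of relation labels (eleven labels in total), plus
#' the reserved `"unknown"` label that is admissible for every pair category
#' and marks a candidate pair with no relation.
#'
#' Pair categories are unordered over entity types, but each category has a
#' canonical orientation (e.g. Test-disease puts the test mention first);
#' candidate instances are always stored in that orientation so the classifier
#' never sees mirrored duplicates of the same pair.
#'
#' @return An object of class `relation_schema`: a list with
#'   - `labels`: tibble with columns `label`, `category`, `e1_type`, `e2_type`;
#'   - `categories`: tibble with `category`, `e1_type`, `e2_type`;
#'   - `entity_types`: character vector of the five entity types;
#'   - `unknown`: the reserved no-relation label (`"unknown"`).
#' @examples
#' sch <- clinical_schema()
#' nrow(sch$labels)       # 11
#' nrow(sch$categories)   # 7
#' @export
clinical_schema <- function() {
  labels <- tibble::tribble(
    ~label,  ~category,            ~e1_type,    ~e2_type,
    "DAP",   "Disease-position",   "disease",   "position",
    "SAP",   "Symptom-position",   "symptom",   "position",
    "SNAP",  "Symptom-position",   "symptom",   "position",
    "TeRD",  "Test-disease",       "test",      "disease",
    "TeAP",  "Test-position",      "test",      "position",
    "TeCP",  "Test-position",      "test",      "position",
    "TeRS",  "Test-symptom",       "test",      "symptom",
    "TeAS",  "Test-symptom",       "test",      "symptom",
    "TrAD",  "Treatment-disease",  "treatment", "disease",
    "TrRD",  "Treatment-disease",  "treatment", "disease",
    "TrAP",  "Treatment-position", "treatment", "position"
  )
  categories <- dplyr::distinct(labels, .data$category, .data$e1_type, .data$e2_type)
  structure(
    list(
      labels = labels,
      categories = categories,
      entity_types = c("treatment", "disease", "symptom", "test", "position"),
      unknown = "unknown"
    ),
    class = "relation_schema"
  )
}

#' @export
print.relation_schema <- function(x, ...) {
  cat("<relation_schema>: ", nrow(x$categories), " pair categories, ",
      nrow(x$labels), " labels + '", x$unknown, "'\n", sep = "")
  print(x$labels)
  invisible(x)
}

#' Relation labels of a schema
#'
#' @param schema A [clinical_schema()] object.
#' @param include_unknown Append the reserved `"unknown"` label at the end?
#' @return Character vector of labels in schema (table) order.
#' @export
schema_labels <- function(schema = clinical_schema(), include_unknown = FALSE) {
  out <- schema$labels$label
  if (include_unknown) out <- c(out, schema$unknown)
  out
}

#' Pair category for two entity types
#'
#' Looks up the (unordered) pair category for two entity types and reports the
#' canonical orientation.
#'
#' @param schema A [clinical_schema()] object.
#' @param type1,type2 Entity type strings.
#' @return `NULL` when the type pair is not a schema category; otherwise a list
#'   with `category`, `e1_type`, `e2_type` (canonical order) and `flipped`
#'   (`TRUE` when `(type1, type2)` had to be swapped to match).
#' @export
pair_category <- function(schema, type1, type2) {
  cats <- schema$categories
  hit <- which(cats$e1_type == type1 & cats$e2_type == type2)
  if (length(hit)) {
    return(list(category = cats$category[hit], e1_type = type1, e2_type = type2,
                flipped = FALSE))
  }
  hit <- which(cats$e1_type == type2 & cats$e2_type == type1)
  if (length(hit)) {
    return(list(category = cats$category[hit], e1_type = type2, e2_type = type1,
                flipped = TRUE))
  }
  NULL
}

#' Admissible relation labels for an entity-type pair
#'
#' @inheritParams pair_category
#' @param include_unknown Include `"unknown"` (admissible for every category)?
#' @return Character vector of labels; empty when the pair is not a category.
#' @export
admissible_labels <- function(schema, type1, type2, include_unknown = TRUE) {
  pc <- pair_category(schema, type1, type2)
  if (is.null(pc)) return(character())
  out <- schema$labels$label[schema$labels$category == pc$category]
  if (include_unknown) out <- c(out, schema$unknown)
  out
}

#' Check that a label may annotate a given entity-type pair
#'
#' @inheritParams pair_category
#' @param label Relation label (may be `"unknown"`).
#' @return Logical scalar.
#' @export
is_admissible <- function(schema, label, type1, type2) {
  label %in% admissible_labels(schema, type1, type2, include_unknown = TRUE)
}
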