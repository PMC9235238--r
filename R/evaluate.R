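#' Per-class and overall precision/recall/F1
#'
#' Computes the confusion counts over all labels, then per-class precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1 (harmonic mean) for each of the
#' schema's relation labels. The `"unknown"` class contributes to the
#' confusion counts (a non-`"unknown"` gold instance predicted `"unknown"` is
#' a false negative) but has no row of its own and is excluded from the
#' overall aggregate, which is micro-averaged over the pooled counts of the
#' remaining classes (macro also reported). Vanishing denominators yield 0
#' with a warning.
#'
#' @param predictions Character vector of predicted labels (or the tibble
#'   returned by [predict.relation_model()], in which case `.pred_label` is
#'   used).
#' @param gold Character vector of gold labels, same length.
#' @param schema A [clinical_schema()] object (fixes the class order).
#' @param labels Optional explicit label order (non-`"unknown"`); defaults to
#'   the schema label order.
#' @return An `eval_report` object: list with `by_class` (tibble: `label`,
#'   `support`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`), `overall`
#'   (one-row tibble with micro `precision`, `recall`, `f1`, plus
#'   `macro_f1` and `n_gold`), and `confusion` (table).
#' @examples
#' rep <- evaluate_relations(c("A", "B", "B"), c("A", "A", "B"),
#'                           labels = c("A", "B"))
#' rep$overall$f1  # 2/3
#' @export
evaluate_relations <- function(predictions, gold, schema = clinical_schema(),
                               labels = NULL) {
  if (is.data.frame(predictions)) predictions <- predictions$.pred_label
  if (length(predictions) != length(gold)) {
    rlang::abort("predictions and gold must have equal length")
  }
  unknown <- if (inherits(schema, "relation_schema")) schema$unknown else "unknown"
  if (is.null(labels)) labels <- schema_labels(schema)
  all_levels <- unique(c(labels, unknown, predictions, gold))
  pf <- factor(predictions, levels = all_levels)
  gf <- factor(gold, levels = all_levels)
  confusion <- table(gold = gf, predicted = pf)
  per <- purrr::map_dfr(labels, function(lab) {
    tp <- sum(predictions == lab & gold == lab)
    fp <- sum(predictions == lab & gold != lab)
    fn <- sum(gold == lab & predictions != lab)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    tibble::tibble(label = lab, support = tp + fn, tp = tp, fp = fp, fn = fn,
                   precision = p, recall = r, f1 = f)
  })
  degenerate <- per$label[per$tp + per$fp == 0L | per$tp + per$fn == 0L]
  if (length(degenerate)) {
    rlang::warn(paste0("vanishing denominator (metric set to 0) for: ",
                       paste(degenerate, collapse = ", ")))
  }
  tp <- sum(per$tp); fp <- sum(per$fp); fn <- sum(per$fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  overall <- tibble::tibble(precision = p, recall = r, f1 = f,
                            macro_f1 = mean(per$f1), n_gold = sum(per$support))
  structure(list(by_class = per, overall = overall, confusion = confusion,
                 unknown = unknown),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> micro P/R/F1 = ",
      paste(formatC(100 * unlist(x$overall[1, c("precision", "recall", "f1")]),
                    format = "f", digits = 2), collapse = " / "),
      " % over ", x$overall$n_gold, " gold relations ('", x$unknown,
      "' excluded)\n", sep = "")
  print(report_by_class(x), n = Inf)
  invisible(x)
}

#' Per-class report table with an overall row
#'
#' One row per relation label in schema order plus a final `overall` row
#' (micro-averaged), suitable for printing or writing to CSV.
#'
#' @param report An `eval_report` from [evaluate_relations()].
#' @param path Optional path; when given the table is also written as CSV.
#' @return Tibble with `label`, `support`, `precision`, `recall`, `f1`.
#' @export
report_by_class <- function(report, path = NULL) {
  out <- dplyr::bind_rows(
    dplyr::select(report$by_class, "label", "support", "precision", "recall", "f1"),
    tibble::tibble(label = "overall", support = report$overall$n_gold,
                   precision = report$overall$precision,
                   recall = report$overall$recall, f1 = report$overall$f1)
  )
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) x$by_class

#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) x$overall

#' Plot per-class F1 of an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot (per-class F1 bars with the micro-average as a line).
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  df <- object$by_class
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$f1)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$overall$f1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "F1",
                  title = "Per-class F1 (dashed: micro average)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
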