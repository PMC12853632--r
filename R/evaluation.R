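#' Micro-averaged top-K ranking metrics
#'
#' Pooled-sum precision, recall and F1 over a test set:
#' `Precision@K = sum_i |R(i) n T(i)| / sum_i |R(i)|`,
#' `Recall@K = sum_i |R(i) n T(i)| / sum_i |T(i)|`, and F1 the harmonic mean
#' of the two pooled rates. Numerators and denominators are summed over all
#' samples before dividing (micro averaging), so predicted lists shorter
#' than `K` simply contribute their actual length to the precision
#' denominator.
#'
#' @param predicted List of predicted herb sets `R(i)`, each of length
#'   `<= K`.
#' @param truth List of true herb sets `T(i)`; an empty truth set is an
#'   error (its recall contribution is undefined).
#' @param k The list-length cutoff the predictions were made at.
#' @return A one-row `topk_report` tibble: `k`, `precision`, `recall`, `f1`,
#'   `n`.
#' @examples
#' topk_metrics(list(c("a", "b"), "c"), list(c("a", "x"), c("c", "d")), k = 2)
#' @export
topk_metrics <- function(predicted, truth, k) {
  if (length(predicted) != length(truth)) {
    abort("topk_metrics: predicted/truth length mismatch")
  }
  n <- length(predicted)
  if (n < 1L) abort("topk_metrics: need at least one sample")
  if (any(lengths(truth) == 0L)) {
    abort("topk_metrics: empty truth set (recall undefined)")
  }
  if (any(lengths(predicted) > k)) {
    abort("topk_metrics: a predicted set exceeds k")
  }
  hits <- sum(mapply(function(r, t) length(intersect(r, t)), predicted, truth))
  precision <- hits / sum(lengths(predicted))
  recall <- hits / sum(lengths(truth))
  out <- tibble(
    k = as.integer(k),
    precision = precision,
    recall = recall,
    f1 = f1_from_pr(precision, recall),
    n = n
  )
  class(out) <- c("topk_report", class(out))
  out
}

#' Harmonic-mean F1 from precision and recall
#'
#' `2 P R / (P + R)`, defined as 0 when `P = R = 0`.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return The F1 score.
#' @examples
#' f1_from_pr(0.60, 0.50)      # 0.5454...
#' f1_from_pr(0.6025, 0.1775)  # 0.2742 to 4 d.p.
#' @export
f1_from_pr <- function(precision, recall) {
  if (any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1)) {
    abort("precision and recall must lie in [0, 1]")
  }
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Relative improvement of a candidate metric over a reference
#'
#' `100 * (candidate - reference) / reference`, in percent.
#'
#' @param candidate,reference Metric values; `reference` must be positive.
#' @return Percent improvement (negative when the candidate is worse).
#' @examples
#' relative_improvement(60.26, 58.49)  # 3.03 to 2 d.p.
#' @export
relative_improvement <- function(candidate, reference) {
  if (any(reference <= 0)) abort("reference must be positive")
  100 * (candidate - reference) / reference
}

#' Write a set of top-K reports as TSV plus a JSON twin
#'
#' @param reports A tibble of stacked `topk_report` rows, optionally with a
#'   `model` column.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return The two paths, invisibly.
#' @export
write_topk_report <- function(reports, prefix) {
  paths <- paste0(prefix, c(".tsv", ".json"))
  readr::write_tsv(as_tibble(reports), paths[1], progress = FALSE)
  jsonlite::write_json(as_tibble(reports), paths[2], digits = NA, dataframe = "rows")
  invisible(paths)
}

#' @export
autoplot.topk_report <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            cols = c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$k), y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "K", y = "micro-averaged value", fill = NULL) +
    ggplot2::theme_minimal()
}
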