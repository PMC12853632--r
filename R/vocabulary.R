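#' Build union vocabularies over both domains
#'
#' Collects the distinct symptom and herb terms across the whole two-domain
#' corpus into ordered vocabularies. A vocabulary is a tibble with one row per
#' term carrying its 0-based `index`, and per-domain presence flags; the union
#' size and per-domain sizes are available through [vocab_sizes()].
#'
#' Ordering is first occurrence in the corpus by default, which is
#' deterministic for a fixed input file; `ordering = "lexicographic"` gives an
#' ordering that is invariant to record permutation.
#'
#' @param records A [clinical_records] tibble.
#' @param ordering `"first_occurrence"` (default) or `"lexicographic"`.
#' @return A list with elements `symptoms` and `herbs`, each a `vocabulary`
#'   tibble with columns `term`, `index` (0-based), `in_source`, `in_target`.
#' @examples
#' recs <- toy_corpus()
#' vocabs <- build_vocabularies(recs)
#' vocab_sizes(vocabs$herbs)
#' @export
build_vocabularies <- function(records,
                               ordering = c("first_occurrence", "lexicographic")) {
  records <- clinical_records(records)
  ordering <- match.arg(ordering)
  build_one <- function(col) {
    terms <- unique(unlist(records[[col]], use.names = FALSE))
    if (is.null(terms)) terms <- character(0)
    if (ordering == "lexicographic") terms <- sort(terms, method = "radix")
    src <- unique(unlist(records[[col]][records$domain == "source"], use.names = FALSE))
    tgt <- unique(unlist(records[[col]][records$domain == "target"], use.names = FALSE))
    out <- tibble(
      term = terms,
      index = seq_along(terms) - 1L,
      in_source = terms %in% src,
      in_target = terms %in% tgt
    )
    class(out) <- c("vocabulary", class(out))
    out
  }
  list(symptoms = build_one("symptoms"), herbs = build_one("herbs"))
}

#' Vocabulary sizes
#'
#' @param vocab A `vocabulary` tibble.
#' @return A named list: `union` (number of distinct terms over both domains),
#'   `source`, `target` (per-domain counts) and `overlap` (terms seen in both).
#' @export
vocab_sizes <- function(vocab) {
  list(
    union = nrow(vocab),
    source = sum(vocab$in_source),
    target = sum(vocab$in_target),
    overlap = sum(vocab$in_source & vocab$in_target)
  )
}

# term -> 1-based position in vocab; errors on unknown terms, naming them.
vocab_index <- function(vocab, terms) {
  idx <- match(terms, vocab$term)
  if (anyNA(idx)) {
    abort(paste0("term(s) absent from vocabulary: ",
                 paste(unique(terms[is.na(idx)]), collapse = ", ")))
  }
  idx
}
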