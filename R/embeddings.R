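#' Assemble union-vocabulary embedding tables
#'
#' Combines the per-domain refined feature vectors into one embedding row per
#' union-vocabulary term. A term present in a single domain keeps its vector
#' verbatim; a term present in both domains gets the elementwise mean of its
#' two vectors by default (`overlap = "concat"` concatenates them instead,
#' doubling the dimension). A term with no feature in either domain is an
#' error.
#'
#' @param symptom_features,herb_features Named lists with elements `source`
#'   and `target`: matrices of refined features whose row names are terms.
#' @param vocabs Vocabularies from [build_vocabularies()].
#' @param overlap `"mean"` (default) or `"concat"`.
#' @return An `embedding_table`: list with `E_s` (union symptoms x d), `E_h`
#'   (union herbs x d), `d`, and `provenance` (tibble of per-term domain
#'   availability).
#' @export
assemble_embeddings <- function(symptom_features, herb_features, vocabs,
                                overlap = c("mean", "concat")) {
  overlap <- match.arg(overlap)
  build <- function(feats, vocab, kind) {
    fs <- as.matrix(feats$source); ft <- as.matrix(feats$target)
    d0 <- if (nrow(fs)) ncol(fs) else ncol(ft)
    d <- if (overlap == "concat") 2L * d0 else d0
    terms <- vocab$term
    missing <- terms[!(terms %in% rownames(fs)) & !(terms %in% rownames(ft))]
    if (length(missing)) {
      abort(paste0("no feature in either domain for ", kind, " term(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    E <- matrix(0, length(terms), d, dimnames = list(terms, NULL))
    for (i in seq_along(terms)) {
      tm <- terms[i]
      u <- if (tm %in% rownames(fs)) fs[tm, ] else NULL
      v <- if (tm %in% rownames(ft)) ft[tm, ] else NULL
      E[i, ] <- if (is.null(v)) {
        if (overlap == "concat") c(u, u) else u
      } else if (is.null(u)) {
        if (overlap == "concat") c(v, v) else v
      } else {
        if (overlap == "concat") c(u, v) else (u + v) / 2
      }
    }
    E
  }
  E_s <- build(symptom_features, vocabs$symptoms, "symptom")
  E_h <- build(herb_features, vocabs$herbs, "herb")
  provenance <- dplyr::bind_rows(
    dplyr::mutate(vocabs$symptoms, kind = "symptom"),
    dplyr::mutate(vocabs$herbs, kind = "herb")
  )
  structure(list(E_s = E_s, E_h = E_h, d = ncol(E_s),
                 provenance = as_tibble(provenance)),
            class = "embedding_table")
}

#' @exportS3Method
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d symptoms, %d herbs, d=%d\n",
              nrow(x$E_s), nrow(x$E_h), x$d))
  invisible(x)
}

#' Read and write embedding matrices as TSV
#'
#' One row per term: the term, then `d` tab-separated reals printed with 17
#' significant digits, so a write/read round trip reproduces the matrix
#' exactly in double precision.
#'
#' @param E Numeric matrix with term row names.
#' @param path File path.
#' @return `write_embeddings()` returns the path invisibly;
#'   `read_embeddings()` returns the matrix.
#' @export
write_embeddings <- function(E, path) {
  stopifnot(!is.null(rownames(E)))
  lines <- vapply(seq_len(nrow(E)), function(i) {
    paste(c(rownames(E)[i], sprintf("%.17g", E[i, ])), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- vapply(parts, `[[`, character(1), 1L)
  vals <- lapply(parts, function(p) as.numeric(p[-1L]))
  E <- do.call(rbind, vals)
  rownames(E) <- terms
  E
}
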