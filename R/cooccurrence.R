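#' Herb-by-symptom co-occurrence matrices
#'
#' Counts, for every (herb, symptom) pair, the number of patient records in
#' which the two terms appear together. Each record contributes at most one
#' count per pair (per-patient binary co-occurrence), so every cell lies in
#' `[0, n_records]`. The rows of this matrix — one co-occurrence profile per
#' herb over the domain's symptom axis — are the partially observed
#' correlation vectors fed to the cross-domain autoencoders; symptom profiles
#' are its columns.
#'
#' @param records A [clinical_records] tibble.
#' @param vocabs Vocabularies from [build_vocabularies()] covering all terms
#'   in the filtered records.
#' @param domain_filter Which records to count: `"source"`, `"target"`, or
#'   `"union"` (all records). For a single domain the matrix is restricted to
#'   the terms occurring in that domain.
#' @param row_kind `"herb"` (default: herbs x symptoms) or `"symptom"`
#'   (the transpose).
#' @return A `cooccurrence` object: list with `counts` (sparse integer
#'   Matrix), `row_kind`, `col_kind`, `domain`, `row_terms`, `col_terms`,
#'   `n_records`.
#' @examples
#' recs <- toy_corpus()
#' vocabs <- build_vocabularies(recs)
#' cooc <- build_cooccurrence(recs, vocabs, "source")
#' @export
build_cooccurrence <- function(records, vocabs,
                               domain_filter = c("union", "source", "target"),
                               row_kind = c("herb", "symptom")) {
  records <- clinical_records(records)
  domain_filter <- match.arg(domain_filter)
  row_kind <- match.arg(row_kind)
  if (domain_filter != "union") {
    records <- records[records$domain == domain_filter, , drop = FALSE]
  }
  herb_terms <- domain_terms(vocabs$herbs, domain_filter)
  sym_terms <- domain_terms(vocabs$symptoms, domain_filter)

  if (nrow(records)) {
    hi <- lapply(records$herbs, function(h) {
      m <- match(h, herb_terms)
      if (anyNA(m)) abort(paste0("term(s) absent from vocabulary: ",
                                 paste(h[is.na(m)], collapse = ", ")))
      m
    })
    si <- lapply(records$symptoms, function(s) {
      m <- match(s, sym_terms)
      if (anyNA(m)) abort(paste0("term(s) absent from vocabulary: ",
                                 paste(s[is.na(m)], collapse = ", ")))
      m
    })
    i <- unlist(mapply(function(h, s) rep(h, each = length(s)), hi, si,
                       SIMPLIFY = FALSE), use.names = FALSE)
    j <- unlist(mapply(function(h, s) rep(s, times = length(h)), hi, si,
                       SIMPLIFY = FALSE), use.names = FALSE)
    counts <- Matrix::sparseMatrix(
      i = i, j = j, x = 1,
      dims = c(length(herb_terms), length(sym_terms)),
      dimnames = list(herb_terms, sym_terms)
    )
  } else {
    counts <- Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(length(herb_terms), length(sym_terms)),
      dimnames = list(herb_terms, sym_terms)
    )
  }
  out <- structure(
    list(counts = counts, row_kind = "herb", col_kind = "symptom",
         domain = domain_filter, row_terms = herb_terms, col_terms = sym_terms,
         n_records = nrow(records)),
    class = "cooccurrence"
  )
  if (row_kind == "symptom") out <- transpose_cooccurrence(out)
  out
}

# Terms of a vocabulary present in the given domain, in vocabulary order.
domain_terms <- function(vocab, domain) {
  switch(domain,
    union = vocab$term,
    source = vocab$term[vocab$in_source],
    target = vocab$term[vocab$in_target]
  )
}

#' @rdname build_cooccurrence
#' @param cooc A `cooccurrence` object.
#' @export
transpose_cooccurrence <- function(cooc) {
  structure(
    list(counts = Matrix::t(cooc$counts), row_kind = cooc$col_kind,
         col_kind = cooc$row_kind, domain = cooc$domain,
         row_terms = cooc$col_terms, col_terms = cooc$row_terms,
         n_records = cooc$n_records),
    class = "cooccurrence"
  )
}

#' @exportS3Method
print.cooccurrence <- function(x, ...) {
  cat(sprintf("<cooccurrence> %s x %s, domain=%s: %d x %d, %d records, %d nonzero cells\n",
              x$row_kind, x$col_kind, x$domain, nrow(x$counts), ncol(x$counts),
              x$n_records, Matrix::nnzero(x$counts)))
  invisible(x)
}

#' Export a co-occurrence matrix as MatrixMarket plus term lists
#'
#' Writes `<prefix>.mtx` (MatrixMarket coordinate format), and
#' `<prefix>.rows.tsv` / `<prefix>.cols.tsv` (term per line, vocabulary
#' order).
#'
#' @param cooc A `cooccurrence` object.
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_cooccurrence <- function(cooc, prefix) {
  paths <- paste0(prefix, c(".mtx", ".rows.tsv", ".cols.tsv"))
  Matrix::writeMM(methods::as(cooc$counts, "CsparseMatrix"), paths[1])
  writeLines(cooc$row_terms, paths[2], useBytes = TRUE)
  writeLines(cooc$col_terms, paths[3], useBytes = TRUE)
  invisible(paths)
}

#' Padded co-occurrence profiles for cross-domain learning
#'
#' Stacks the per-entity co-occurrence profiles of the two domains into one
#' input matrix for an autoencoder. Herb profiles are the rows of each
#' domain's herb x symptom matrix, zero-padded on the symptom axis to
#' `max(m1, m2)` so source and target vectors share an input dimension;
#' symptom profiles are the columns, padded on the herb axis to `max(n1, n2)`.
#'
#' @param cooc_source,cooc_target `cooccurrence` objects for the two domains
#'   (herb rows).
#' @param kind `"herb"` or `"symptom"`: which entity's profiles to extract.
#' @return A list: `x` (profiles matrix, one row per entity), `term`
#'   (character), `domain` (character), `input_dim`.
#' @export
padded_profiles <- function(cooc_source, cooc_target, kind = c("herb", "symptom")) {
  kind <- match.arg(kind)
  get_rows <- function(cooc) {
    m <- if (cooc$row_kind == kind) cooc$counts else Matrix::t(cooc$counts)
    as.matrix(m)
  }
  xs <- get_rows(cooc_source)
  xt <- get_rows(cooc_target)
  dim_max <- max(ncol(xs), ncol(xt))
  pad <- function(m) {
    if (ncol(m) < dim_max) {
      m <- cbind(m, matrix(0, nrow(m), dim_max - ncol(m)))
    }
    m
  }
  xs <- pad(xs); xt <- pad(xt)
  list(
    x = rbind(xs, xt),
    term = c(rownames(xs), rownames(xt)),
    domain = rep(c("source", "target"), c(nrow(xs), nrow(xt))),
    input_dim = dim_max
  )
}
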