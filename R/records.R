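#' Clinical record tables
#'
#' A clinical corpus is a tibble with one row per patient visit and four
#' columns: `record_id` (character, unique), `domain` (`"source"` or
#' `"target"` — the two disease-specific corpora), and the list-columns
#' `symptoms` and `herbs`, each holding a character vector of terms with set
#' semantics (duplicates are collapsed, order is irrelevant).
#'
#' `clinical_records()` validates and canonicalises a tibble into this shape;
#' `read_records()` / `write_records()` round-trip the two on-disk dialects:
#' JSON lines (`{"id": ..., "domain": ..., "symptoms": [...], "herbs": [...]}`,
#' one object per line) and TSV (columns `id`, `domain`, pipe-joined
#' `symptoms`, pipe-joined `herbs`). Both are UTF-8; terms may be CJK.
#'
#' @param records A data frame with columns `record_id`, `domain`, `symptoms`,
#'   `herbs`. The term columns may be list-columns or pipe-joined strings.
#' @return A validated tibble of class `clinical_records`.
#' @examples
#' recs <- clinical_records(tibble::tibble(
#'   record_id = c("r1", "r2"),
#'   domain    = c("source", "target"),
#'   symptoms  = list(c("cough", "fever"), "cough"),
#'   herbs     = list("licorice", c("licorice", "mint"))
#' ))
#' @export
clinical_records <- function(records) {
  records <- as_tibble(records)
  needed <- c("record_id", "domain", "symptoms", "herbs")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("records are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  records$record_id <- as.character(records$record_id)
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup)) {
    abort(paste0("duplicate record_id: ", paste(unique(dup), collapse = ", ")))
  }
  bad_dom <- setdiff(unique(records$domain), c("source", "target"))
  if (length(bad_dom)) {
    abort(paste0("domain must be 'source' or 'target', got: ",
                 paste(bad_dom, collapse = ", ")))
  }
  as_term_sets <- function(col, what) {
    if (!is.list(col)) col <- strsplit(as.character(col), "|", fixed = TRUE)
    col <- lapply(col, function(x) unique(as.character(x[!is.na(x) & nzchar(x)])))
    n <- lengths(col)
    if (any(n == 0L)) {
      abort(paste0("record(s) with empty ", what, " set: ",
                   paste(records$record_id[n == 0L], collapse = ", ")))
    }
    col
  }
  records$symptoms <- as_term_sets(records$symptoms, "symptom")
  records$herbs <- as_term_sets(records$herbs, "herb")
  out <- records[needed]
  class(out) <- c("clinical_records", class(out))
  out
}

#' @rdname clinical_records
#' @param path File path. Format is inferred from the extension
#'   (`.jsonl`/`.json` vs `.tsv`/`.txt`) unless `format` is given.
#' @param format `"jsonl"` or `"tsv"`.
#' @export
read_records <- function(path, format = c("auto", "jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl?|ndjson)$", path)) "jsonl" else "tsv"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
    recs <- tibble(
      record_id = vapply(rows, function(r) as.character(r$id), character(1)),
      domain    = vapply(rows, function(r) as.character(r$domain), character(1)),
      symptoms  = lapply(rows, function(r) as.character(r$symptoms)),
      herbs     = lapply(rows, function(r) as.character(r$herbs))
    )
  } else {
    tab <- readr::read_tsv(path, col_names = c("id", "domain", "symptoms", "herbs"),
                           col_types = "cccc", progress = FALSE)
    recs <- tibble(record_id = tab$id, domain = tab$domain,
                   symptoms = tab$symptoms, herbs = tab$herbs)
  }
  clinical_records(recs)
}

#' @rdname clinical_records
#' @export
write_records <- function(records, path, format = c("auto", "jsonl", "tsv")) {
  records <- clinical_records(records)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl?|ndjson)$", path)) "jsonl" else "tsv"
  }
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      jsonlite::toJSON(list(
        id = records$record_id[i], domain = records$domain[i],
        symptoms = records$symptoms[[i]], herbs = records$herbs[[i]]
      ), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    tab <- tibble(
      id = records$record_id, domain = records$domain,
      symptoms = vapply(records$symptoms, paste, character(1), collapse = "|"),
      herbs = vapply(records$herbs, paste, character(1), collapse = "|")
    )
    readr::write_tsv(tab, path, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}
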