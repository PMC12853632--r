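#' Sample-level sparsity of a clinical corpus
#'
#' Quantifies how small each record's term sets are relative to the
#' vocabulary: the herb sparsity is `S_h = 1 - mean(herbs per record) /
#' (herb vocabulary size)`, and symptom sparsity analogously. By default the
#' denominator is the vocabulary of the records being summarised (the
#' per-corpus vocabulary); `denominator = "union"` uses the full two-domain
#' union instead.
#'
#' @param records A [clinical_records] tibble (all domains, or pre-filtered).
#' @param vocabs Vocabularies from [build_vocabularies()] (built on the full
#'   corpus; per-domain sizes are taken from the presence flags).
#' @param domain Summarise `"union"` (default), `"source"` or `"target"`
#'   records.
#' @param denominator `"per_domain"` (default) or `"union"` vocabulary size.
#' @return A one-row tibble: `domain`, `n_records`,
#'   `mean_symptoms_per_record`, `mean_herbs_per_record`, `symptom_sparsity`,
#'   `herb_sparsity`, `max_symptom_frequency`, `max_herb_frequency`.
#' @examples
#' recs <- toy_corpus()
#' sparsity_report(recs, build_vocabularies(recs))
#' @export
sparsity_report <- function(records, vocabs,
                            domain = c("union", "source", "target"),
                            denominator = c("per_domain", "union")) {
  records <- clinical_records(records)
  domain <- match.arg(domain)
  denominator <- match.arg(denominator)
  if (domain != "union") records <- records[records$domain == domain, , drop = FALSE]
  if (!nrow(records)) abort("sparsity_report: empty corpus")

  denom_size <- function(vocab) {
    if (denominator == "union") nrow(vocab)
    else length(domain_terms(vocab, domain))
  }
  mean_sym <- mean(lengths(records$symptoms))
  mean_herb <- mean(lengths(records$herbs))
  n_sym <- denom_size(vocabs$symptoms)
  n_herb <- denom_size(vocabs$herbs)
  if (n_sym == 0 || n_herb == 0) abort("sparsity_report: empty vocabulary")

  freq_max <- function(col) {
    tab <- table(unlist(records[[col]], use.names = FALSE))
    if (length(tab)) as.integer(max(tab)) else 0L
  }
  tibble(
    domain = domain,
    n_records = nrow(records),
    mean_symptoms_per_record = mean_sym,
    mean_herbs_per_record = mean_herb,
    symptom_sparsity = 1 - mean_sym / n_sym,
    herb_sparsity = 1 - mean_herb / n_herb,
    max_symptom_frequency = freq_max("symptoms"),
    max_herb_frequency = freq_max("herbs")
  )
}
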