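#' Specification of a synthetic two-domain clinical corpus
#'
#' Describes the statistical profile a generated corpus should exhibit:
#' records per domain, per-domain vocabulary sizes with exact overlap
#' counts, target mean set sizes per record, a Zipf-like term-frequency
#' skew, and a planted symptom-to-herb rule table whose strength controls
#' how predictable prescriptions are from symptoms. The rule table is
#' identical across domains for the shared herbs — the minimal structure
#' under which cross-domain transfer can help — and domain-specific
#' elsewhere.
#'
#' @param n_source,n_target Records per domain.
#' @param n_symptoms_source,n_symptoms_target,symptom_overlap Symptom
#'   vocabulary sizes per domain and the number of shared symptom terms.
#' @param n_herbs_source,n_herbs_target,herb_overlap Herb vocabulary sizes
#'   and shared herb count.
#' @param mean_symptoms_source,mean_symptoms_target Target mean symptoms per
#'   record (defaults 13.58 and 17.39, the profile of the stomach/spleen and
#'   lung corpora).
#' @param mean_herbs_source,mean_herbs_target Target mean herbs per record
#'   (defaults 20.98 and 7.89).
#' @param zipf_exponent Term-frequency skew exponent (default 1.1).
#' @param rule_strength Probability that a paired herb is prescribed given
#'   its trigger symptom (default 0.9).
#' @param noise Probability that a chosen herb is swapped for a uniformly
#'   random one (default 0.05).
#' @param seed Integer seed.
#' @return A validated `corpus_spec` list.
#' @export
corpus_spec <- function(n_source = 200L, n_target = 200L,
                        n_symptoms_source = 120L, n_symptoms_target = 100L,
                        symptom_overlap = 30L,
                        n_herbs_source = 70L, n_herbs_target = 50L,
                        herb_overlap = 25L,
                        mean_symptoms_source = 13.58,
                        mean_symptoms_target = 17.39,
                        mean_herbs_source = 20.98, mean_herbs_target = 7.89,
                        zipf_exponent = 1.1, rule_strength = 0.9,
                        noise = 0.05, seed = 1L) {
  spec <- list(
    n_source = as.integer(n_source), n_target = as.integer(n_target),
    n_symptoms_source = as.integer(n_symptoms_source),
    n_symptoms_target = as.integer(n_symptoms_target),
    symptom_overlap = as.integer(symptom_overlap),
    n_herbs_source = as.integer(n_herbs_source),
    n_herbs_target = as.integer(n_herbs_target),
    herb_overlap = as.integer(herb_overlap),
    mean_symptoms_source = mean_symptoms_source,
    mean_symptoms_target = mean_symptoms_target,
    mean_herbs_source = mean_herbs_source,
    mean_herbs_target = mean_herbs_target,
    zipf_exponent = zipf_exponent, rule_strength = rule_strength,
    noise = noise, seed = seed
  )
  if (spec$symptom_overlap > min(spec$n_symptoms_source, spec$n_symptoms_target) ||
      spec$herb_overlap > min(spec$n_herbs_source, spec$n_herbs_target)) {
    abort("overlap counts cannot exceed the per-domain vocabulary sizes")
  }
  if (min(spec$mean_symptoms_source, spec$mean_symptoms_target,
          spec$mean_herbs_source, spec$mean_herbs_target) < 1) {
    abort("target mean set sizes must be >= 1")
  }
  if (spec$mean_symptoms_source > spec$n_symptoms_source ||
      spec$mean_symptoms_target > spec$n_symptoms_target ||
      spec$mean_herbs_source > spec$n_herbs_source ||
      spec$mean_herbs_target > spec$n_herbs_target) {
    abort("infeasible spec: mean set size exceeds the vocabulary size")
  }
  if (spec$rule_strength < 0 || spec$rule_strength > 1 ||
      spec$noise < 0 || spec$noise > 1) {
    abort("rule_strength and noise must lie in [0, 1]")
  }
  if (spec$n_source < 1L || spec$n_target < 1L) {
    abort("need at least one record per domain")
  }
  structure(spec, class = "corpus_spec")
}

#' Preset corpus parameterisations
#'
#' `corpus_presets()` lists the per-domain profiles emulating the two
#' clinical corpora (record counts, printed mean set sizes, vocabulary
#' sizes consistent with the printed union sizes and overlaps);
#' `tcm_corpus_spec()` assembles them into a two-domain [corpus_spec()],
#' optionally scaled down (record counts and vocabulary sizes shrink;
#' the mean set sizes — the emulation targets — are preserved).
#'
#' @param scale Multiplier on record counts and vocabulary sizes, in
#'   (0, 1]; overlap counts scale along.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [corpus_spec()].
#' @return `corpus_presets()` a named list; `tcm_corpus_spec()` a
#'   `corpus_spec`.
#' @export
corpus_presets <- function() {
  list(
    `tcm-ssd-like` = list(
      n_records = 17593L, mean_symptoms = 13.58, mean_herbs = 20.98,
      n_symptoms = 25000L, n_herbs = 791L
    ),
    `tcm-lung-like` = list(
      n_records = 14948L, mean_symptoms = 17.39, mean_herbs = 7.89,
      n_symptoms = 18303L, n_herbs = 422L
    ),
    overlap = list(symptoms = 328L, herbs = 285L)
  )
}

#' @rdname corpus_presets
#' @export
tcm_corpus_spec <- function(scale = 1, seed = 1L, ...) {
  stopifnot(scale > 0, scale <= 1)
  p <- corpus_presets()
  ssd <- p[["tcm-ssd-like"]]; lung <- p[["tcm-lung-like"]]
  sc <- function(x, lo) max(lo, as.integer(round(x * scale)))
  n_sym_src <- sc(ssd$n_symptoms, 40L)
  n_sym_tgt <- sc(lung$n_symptoms, 40L)
  n_herb_src <- sc(ssd$n_herbs, 30L)
  n_herb_tgt <- sc(lung$n_herbs, 30L)
  corpus_spec(
    n_source = sc(ssd$n_records, 50L), n_target = sc(lung$n_records, 50L),
    n_symptoms_source = n_sym_src, n_symptoms_target = n_sym_tgt,
    symptom_overlap = min(sc(p$overlap$symptoms, 10L), n_sym_src, n_sym_tgt),
    n_herbs_source = n_herb_src, n_herbs_target = n_herb_tgt,
    herb_overlap = min(sc(p$overlap$herbs, 10L), n_herb_src, n_herb_tgt),
    mean_symptoms_source = ssd$mean_symptoms,
    mean_symptoms_target = lung$mean_symptoms,
    mean_herbs_source = ssd$mean_herbs, mean_herbs_target = lung$mean_herbs,
    seed = seed, ...
  )
}

# Poisson truncated to >= 1, capped at `cap`.
rtruncpois <- function(n, lambda, cap) {
  k <- qpois(runif(n, ppois(0, lambda), 1), lambda)
  pmin(pmax(k, 1L), cap)
}

#' Generate a synthetic two-domain clinical corpus
#'
#' Draws per-record set sizes from a truncated Poisson (minimum 1) around
#' the spec's target means, samples terms from a Zipf-skewed frequency
#' distribution over each domain's vocabulary, and prescribes herbs through
#' the planted rule table: every sampled symptom that triggers a herb
#' includes that herb with probability `rule_strength`, the remaining slots
#' are filled by frequency-weighted sampling, and each chosen herb is
#' swapped for a uniformly random one with probability `noise`. Every
#' vocabulary term is guaranteed to appear in at least one record (unused
#' terms are injected into randomly chosen records), so the generated
#' vocabularies and their overlap counts match the spec exactly. Fully
#' seeded: the same spec yields the same corpus.
#'
#' @param spec A [corpus_spec()].
#' @return A [clinical_records] tibble with attribute `rules` (tibble of the
#'   planted herb/trigger-symptom pairs per domain).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed, {
    shared_s <- sprintf("S_sh_%04d", seq_len(spec$symptom_overlap))
    shared_h <- sprintf("H_sh_%04d", seq_len(spec$herb_overlap))
    vocab <- list(
      source = list(
        symptoms = c(shared_s, sprintf("S_src_%04d",
                                       seq_len(spec$n_symptoms_source - spec$symptom_overlap))),
        herbs = c(shared_h, sprintf("H_src_%04d",
                                    seq_len(spec$n_herbs_source - spec$herb_overlap)))
      ),
      target = list(
        symptoms = c(shared_s, sprintf("S_tgt_%04d",
                                       seq_len(spec$n_symptoms_target - spec$symptom_overlap))),
        herbs = c(shared_h, sprintf("H_tgt_%04d",
                                    seq_len(spec$n_herbs_target - spec$herb_overlap)))
      )
    )
    # Zipf-like sampling weights over a random rank permutation per domain,
    # but with a single shared ranking for the shared terms so that the two
    # domains agree on which shared terms are common.
    zipf_weights <- function(terms) {
      w <- (seq_along(terms))^(-spec$zipf_exponent)
      setNames(sample(w), terms)
    }
    weights <- lapply(vocab, function(v) {
      list(symptoms = zipf_weights(v$symptoms), herbs = zipf_weights(v$herbs))
    })

    # Planted rules: shared herbs pair with shared symptoms (one table used
    # by both domains); domain-only herbs pair with domain symptoms.
    n_shared_rules <- min(spec$herb_overlap, spec$symptom_overlap)
    shared_rules <- setNames(sample(shared_s, n_shared_rules), shared_h[seq_len(n_shared_rules)])
    domain_rules <- lapply(c(source = "source", target = "target"), function(dom) {
      own_h <- setdiff(vocab[[dom]]$herbs, names(shared_rules))
      c(shared_rules,
        setNames(sample(vocab[[dom]]$symptoms, length(own_h), replace = TRUE), own_h))
    })

    gen_domain <- function(dom, n, mean_s, mean_h) {
      syms <- vocab[[dom]]$symptoms; herbs <- vocab[[dom]]$herbs
      w_s <- weights[[dom]]$symptoms; w_h <- weights[[dom]]$herbs
      rules <- domain_rules[[dom]]
      trigger_of <- split(names(rules), rules)  # symptom -> herbs it triggers
      k_s <- rtruncpois(n, mean_s, length(syms))
      k_h <- rtruncpois(n, mean_h, length(herbs))
      recs <- lapply(seq_len(n), function(i) {
        s_i <- sample(syms, k_s[i], prob = w_s)
        cand <- unlist(trigger_of[s_i], use.names = FALSE)
        triggered <- cand[runif(length(cand)) < spec$rule_strength]
        triggered <- unique(triggered)
        h_i <- triggered
        if (length(h_i) < k_h[i]) {
          pool <- setdiff(herbs, h_i)
          h_i <- c(h_i, sample(pool, min(k_h[i] - length(h_i), length(pool)),
                               prob = w_h[pool]))
        }
        if (spec$noise > 0) {
          swap <- which(runif(length(h_i)) < spec$noise)
          pool <- setdiff(herbs, h_i)
          if (length(swap) && length(pool)) {
            swap <- swap[seq_len(min(length(swap), length(pool)))]
            h_i[swap] <- sample(pool, length(swap))
          }
        }
        list(symptoms = s_i, herbs = unique(h_i))
      })
      tibble(
        record_id = sprintf("%s_%05d", substr(dom, 1, 3), seq_len(n)),
        domain = dom,
        symptoms = lapply(recs, `[[`, "symptoms"),
        herbs = lapply(recs, `[[`, "herbs")
      )
    }
    recs <- dplyr::bind_rows(
      gen_domain("source", spec$n_source, spec$mean_symptoms_source,
                 spec$mean_herbs_source),
      gen_domain("target", spec$n_target, spec$mean_symptoms_target,
                 spec$mean_herbs_target)
    )
    # Coverage: inject vocabulary terms that were never drawn, so generated
    # vocabularies (and their overlaps) match the spec exactly.
    for (dom in c("source", "target")) {
      idx <- which(recs$domain == dom)
      rules <- domain_rules[[dom]]
      trigger_of <- split(names(rules), rules)
      for (col in c("symptoms", "herbs")) {
        seen <- unique(unlist(recs[[col]][idx], use.names = FALSE))
        unused <- setdiff(vocab[[dom]][[col]], seen)
        if (length(unused)) {
          at <- sample(idx, length(unused), replace = TRUE)
          for (j in seq_along(unused)) {
            recs[[col]][[at[j]]] <- c(recs[[col]][[at[j]]], unused[j])
            if (col == "symptoms") {
              # an injected symptom still fires its planted rules
              cand <- trigger_of[[unused[j]]]
              if (length(cand)) {
                fired <- cand[runif(length(cand)) < spec$rule_strength]
                recs$herbs[[at[j]]] <- unique(c(recs$herbs[[at[j]]], fired))
              }
            }
          }
        }
      }
    }
    out <- clinical_records(recs)
    attr(out, "rules") <- dplyr::bind_rows(lapply(names(domain_rules), function(dom) {
      tibble(domain = dom, herb = names(domain_rules[[dom]]),
             trigger_symptom = unname(domain_rules[[dom]]))
    }))
    out
  })
}

#' Generate a toy PPI graph with planted gene sets
#'
#' An Erdos-Renyi base graph plus two disjoint planted node sets whose
#' inter-set edge probability is `boost * edge_prob` (edges added for
#' `boost > 1`, thinned for `boost < 1`; `boost = 1` leaves the sets
#' statistically indistinguishable from background). Simple, undirected,
#' seeded.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param edge_prob Background edge probability in (0, 1).
#' @param size_a,size_b Planted set sizes (defaults ~10% of nodes).
#' @param boost Inter-set edge-probability multiplier; `boost * edge_prob`
#'   must not exceed 1.
#' @param seed Integer seed.
#' @return A list: `graph` (igraph with named nodes), `set_a`, `set_b`.
#' @export
generate_ppi <- function(n_nodes, edge_prob, size_a = NULL, size_b = NULL,
                         boost = 1, seed = 1L) {
  if (n_nodes < 2L) abort("n_nodes must be >= 2")
  if (edge_prob <= 0 || edge_prob >= 1) abort("edge_prob must lie in (0, 1)")
  if (boost < 0) abort("boost must be nonnegative")
  q <- boost * edge_prob
  if (q > 1) abort("infeasible boost: boost * edge_prob exceeds 1")
  size_a <- size_a %||% max(2L, round(0.1 * n_nodes))
  size_b <- size_b %||% max(2L, round(0.1 * n_nodes))
  if (size_a + size_b > n_nodes) abort("planted sets cannot be disjoint: too large")
  with_seed(seed, {
    g <- igraph::sample_gnp(n_nodes, edge_prob, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name",
                                 value = sprintf("g%04d", seq_len(n_nodes)))
    nodes <- igraph::V(g)$name
    picked <- sample(nodes, size_a + size_b)
    set_a <- picked[seq_len(size_a)]
    set_b <- picked[size_a + seq_len(size_b)]
    if (boost != 1) {
      pairs <- expand.grid(a = set_a, b = set_b, stringsAsFactors = FALSE)
      has_edge <- mapply(function(u, v) {
        igraph::are_adjacent(g, u, v)
      }, pairs$a, pairs$b)
      if (boost > 1) {
        p_add <- (q - edge_prob) / (1 - edge_prob)
        add <- !has_edge & runif(nrow(pairs)) < p_add
        if (any(add)) {
          g <- igraph::add_edges(g, rbind(pairs$a[add], pairs$b[add]))
        }
      } else {
        drop <- has_edge & runif(nrow(pairs)) >= boost
        if (any(drop)) {
          eids <- igraph::get_edge_ids(g, rbind(pairs$a[drop], pairs$b[drop]))
          g <- igraph::delete_edges(g, eids[eids > 0])
        }
      }
      g <- igraph::simplify(g)
    }
    list(graph = g, set_a = set_a, set_b = set_b,
         spec = list(n_nodes = n_nodes, edge_prob = edge_prob, boost = boost,
                     seed = seed))
  })
}

#' Write a graph as a two-column TSV edge list
#'
#' @param graph An igraph with named vertices.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ppi_graph <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  readr::write_tsv(tibble(from = el[, 1], to = el[, 2]), path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}
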