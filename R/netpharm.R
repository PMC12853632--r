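#' Network-pharmacology proximity statistics on a PPI graph
#'
#' Quantifies how close a symptom-associated gene set `A` sits to an
#' herb-target gene set `B` on an undirected protein-protein interaction
#' network. [separation_score()] computes `S_AB = d_AB - (d_AA + d_BB) / 2`
#' with the closest-distance convention: `d_AA` averages, over the nodes of
#' `A`, the shortest-path distance to the nearest *other* node of `A`
#' (0 for a singleton set); `d_AB` averages, over all nodes of `A` and `B`,
#' the distance to the nearest node of the opposite set, so nodes shared by
#' both sets contribute 0. Negative `S_AB` indicates overlapping network
#' neighbourhoods. All distances are unweighted breadth-first shortest
#' paths.
#'
#' @param graph An [igraph::igraph] undirected graph with named vertices
#'   (self-loops and multi-edges are removed).
#' @param a,b Character vectors of node names (nonempty, subsets of the
#'   graph's vertices).
#' @param unreachable `"drop"` (default): node pairs with no connecting path
#'   are dropped from the means with a warning; `"error"`: fail instead.
#' @return `separation_score()` returns a one-row tibble: `s_ab`, `d_aa`,
#'   `d_bb`, `d_ab`, `n_dropped`.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' separation_score(g, "a", "c")  # path graph: d_AB = 2, S_AB = 2
#' @export
separation_score <- function(graph, a, b, unreachable = c("drop", "error")) {
  unreachable <- match.arg(unreachable)
  graph <- check_ppi_graph(graph)
  a <- check_gene_set(graph, a, "A"); b <- check_gene_set(graph, b, "B")
  dropped <- 0L
  finite_mean <- function(x, what) {
    bad <- !is.finite(x)
    if (any(bad)) {
      if (unreachable == "error") {
        abort(paste0("unreachable node pair(s) in ", what))
      }
      dropped <<- dropped + sum(bad)
      x <- x[!bad]
    }
    if (!length(x)) abort(paste0("all node pairs unreachable in ", what))
    mean(x)
  }
  within_min <- function(s) {
    if (length(s) < 2L) return(0)
    D <- bfs_distances(graph, s, s)
    diag(D) <- Inf
    finite_mean(apply(D, 1L, min), "within-set distances")
  }
  D_ab <- bfs_distances(graph, a, b)
  d_ab <- finite_mean(c(apply(D_ab, 1L, min), apply(D_ab, 2L, min)),
                      "cross-set distances")
  d_aa <- within_min(a)
  d_bb <- within_min(b)
  if (dropped > 0L) {
    warn(sprintf("separation_score: dropped %d unreachable pair(s)", dropped))
  }
  tibble(s_ab = d_ab - (d_aa + d_bb) / 2,
         d_aa = d_aa, d_bb = d_bb, d_ab = d_ab, n_dropped = dropped)
}

check_ppi_graph <- function(graph) {
  if (!igraph::is_igraph(graph)) abort("graph must be an igraph object")
  if (igraph::is_directed(graph)) graph <- igraph::as_undirected(graph)
  if (is.null(igraph::V(graph)$name)) {
    graph <- igraph::set_vertex_attr(graph, "name",
                                     value = as.character(seq_len(igraph::vcount(graph))))
  }
  igraph::simplify(graph)
}

check_gene_set <- function(graph, s, label) {
  s <- unique(as.character(s))
  if (!length(s)) abort(paste0("gene set ", label, " is empty"))
  missing <- setdiff(s, igraph::V(graph)$name)
  if (length(missing)) {
    abort(paste0("gene set ", label, " has node(s) absent from the graph: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  s
}

bfs_distances <- function(graph, from, to) {
  igraph::distances(graph, v = from, to = to, weights = NA)
}

# Closest-distance d_AB only; used as the randomization statistic.
d_ab_statistic <- function(graph, a, b) {
  D <- bfs_distances(graph, a, b)
  vals <- c(apply(D, 1L, min), apply(D, 2L, min))
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Randomization z-score of network proximity
#'
#' Compares the observed closest-distance proximity `d_AB` with a null of
#' `n_rand` draws in which two node sets of sizes `|A|` and `|B|` are picked
#' uniformly at random from the graph:
#' `z = (s - mean(s_rand)) / sd(s_rand)`. Negative z means the two sets are
#' closer than random expectation. `degree_binned = TRUE` draws null sets
#' matching the degree distribution of the observed sets (nodes are binned
#' by degree into `n_bins` quantile bins and resampled within bins), the
#' common network-medicine refinement.
#'
#' @inheritParams separation_score
#' @param n_rand Number of random trials (>= 2; 10,000 at full scale).
#' @param seed Integer seed; same seed, same z.
#' @param degree_binned Degree-matched null instead of uniform (default
#'   FALSE).
#' @param n_bins Degree bins when `degree_binned` (default 10).
#' @return A `proximity_zscore` list: `z`, `observed`, `null_mean`,
#'   `null_sd`, `null_sample`, `n_rand`.
#' @export
proximity_zscore <- function(graph, a, b, n_rand = 10000L, seed = 1L,
                             degree_binned = FALSE, n_bins = 10L) {
  graph <- check_ppi_graph(graph)
  a <- check_gene_set(graph, a, "A"); b <- check_gene_set(graph, b, "B")
  if (n_rand < 2L) abort("n_rand must be >= 2")
  nodes <- igraph::V(graph)$name
  observed <- d_ab_statistic(graph, a, b)
  sampler <- if (degree_binned) {
    deg <- igraph::degree(graph)
    breaks <- unique(stats::quantile(deg, probs = seq(0, 1, length.out = n_bins + 1L)))
    bin <- cut(deg, breaks = breaks, include.lowest = TRUE)
    by_bin <- split(nodes, bin)
    function(s) {
      s_bins <- as.character(bin[match(s, nodes)])
      unlist(lapply(split(s, s_bins), function(grp) {
        pool <- by_bin[[as.character(bin[match(grp[1], nodes)])]]
        sample(pool, length(grp), replace = length(pool) < length(grp))
      }), use.names = FALSE)
    }
  } else {
    function(s) sample(nodes, length(s))
  }
  null_sample <- with_seed(seed, vapply(seq_len(n_rand), function(i) {
    d_ab_statistic(graph, sampler(a), sampler(b))
  }, numeric(1)))
  null_sample <- null_sample[is.finite(null_sample)]
  m <- mean(null_sample); s_dev <- sd(null_sample)
  if (!is.finite(s_dev) || s_dev == 0) {
    abort("proximity_zscore: degenerate null (sd = 0)")
  }
  structure(list(z = (observed - m) / s_dev, observed = observed,
                 null_mean = m, null_sd = s_dev, null_sample = null_sample,
                 n_rand = n_rand),
            class = "proximity_zscore")
}

#' @exportS3Method
print.proximity_zscore <- function(x, ...) {
  cat(sprintf("<proximity_zscore> z=%.4f (observed %.4f, null %.4f +/- %.4f, %d trials)\n",
              x$z, x$observed, x$null_mean, x$null_sd, x$n_rand))
  invisible(x)
}

#' Average shortest path length between two node sets
#'
#' `ASPL = sum_{i in A} sum_{j in B} SPL(i, j) / (|A| |B|)`: the plain mean
#' over all cross-set pairs (a shared node pairs with itself at distance 0).
#'
#' @inheritParams separation_score
#' @return The mean shortest-path length, a nonnegative scalar.
#' @export
aspl <- function(graph, a, b, unreachable = c("drop", "error")) {
  unreachable <- match.arg(unreachable)
  graph <- check_ppi_graph(graph)
  a <- check_gene_set(graph, a, "A"); b <- check_gene_set(graph, b, "B")
  D <- bfs_distances(graph, a, b)
  bad <- !is.finite(D)
  if (any(bad)) {
    if (unreachable == "error") abort("aspl: unreachable node pair(s)")
    if (all(bad)) abort("aspl: all node pairs unreachable")
    warn(sprintf("aspl: dropped %d unreachable pair(s)", sum(bad)))
  }
  mean(D[!bad])
}

#' Inter-set edge permutation test with binomial significance
#'
#' Counts the graph edges with one endpoint in `A` and the other in `B`,
#' builds a null by recounting for `n_rounds` uniformly random node-set
#' pairs of the same sizes, and computes an upper-tail binomial p-value:
#' the per-pair connection probability is estimated as
#' `p_hat = mean(null) / (|A| |B|)` and
#' `p = P[Binomial(|A| |B|, p_hat) >= observed]`.
#'
#' @inheritParams separation_score
#' @param n_rounds Number of random rounds (>= 1; 1,000 at full scale).
#' @param seed Integer seed.
#' @return An `edge_permutation` list: `observed`, `null_sample`, `p_value`,
#'   `p_hat`, `n_pairs`, `n_rounds`.
#' @export
edge_permutation_test <- function(graph, a, b, n_rounds = 1000L, seed = 1L) {
  graph <- check_ppi_graph(graph)
  a <- check_gene_set(graph, a, "A"); b <- check_gene_set(graph, b, "B")
  if (n_rounds < 1L) abort("n_rounds must be >= 1")
  el <- igraph::as_edgelist(graph, names = TRUE)
  count_between <- function(sa, sb) {
    sum((el[, 1] %in% sa & el[, 2] %in% sb) |
          (el[, 1] %in% sb & el[, 2] %in% sa))
  }
  observed <- count_between(a, b)
  nodes <- igraph::V(graph)$name
  null_sample <- with_seed(seed, vapply(seq_len(n_rounds), function(i) {
    count_between(sample(nodes, length(a)), sample(nodes, length(b)))
  }, numeric(1)))
  n_pairs <- length(a) * length(b)
  p_hat <- min(mean(null_sample) / n_pairs, 1)
  p_value <- pbinom(observed - 1L, size = n_pairs, prob = p_hat,
                    lower.tail = FALSE)
  structure(list(observed = observed, null_sample = null_sample,
                 p_value = p_value, p_hat = p_hat, n_pairs = n_pairs,
                 n_rounds = n_rounds),
            class = "edge_permutation")
}

#' @exportS3Method
print.edge_permutation <- function(x, ...) {
  cat(sprintf("<edge_permutation> observed=%d, null mean=%.2f, p=%.4g (%d rounds)\n",
              x$observed, mean(x$null_sample), x$p_value, x$n_rounds))
  invisible(x)
}

#' @export
autoplot.edge_permutation <- function(object, ...) {
  df <- tibble(edges = object$null_sample)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$edges)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "inter-set edges under the null",
                  y = "rounds",
                  title = sprintf("observed = %d, p = %.3g",
                                  object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Full proximity analysis of two gene sets
#'
#' Runs [separation_score()], [proximity_zscore()], [aspl()] and
#' [edge_permutation_test()] and collects everything in one result.
#'
#' @inheritParams proximity_zscore
#' @param n_rounds Rounds for the edge permutation test.
#' @return A `proximity_result` with all components; `tidy()` gives a
#'   one-row tibble.
#' @export
network_proximity <- function(graph, a, b, n_rand = 1000L, n_rounds = 1000L,
                              seed = 1L, degree_binned = FALSE) {
  sep <- separation_score(graph, a, b)
  zs <- proximity_zscore(graph, a, b, n_rand = n_rand, seed = seed,
                         degree_binned = degree_binned)
  sp <- aspl(graph, a, b)
  ep <- edge_permutation_test(graph, a, b, n_rounds = n_rounds, seed = seed)
  structure(list(separation = sep, zscore = zs, aspl = sp, edge_test = ep,
                 set_sizes = c(a = length(unique(a)), b = length(unique(b)))),
            class = "proximity_result")
}

#' @exportS3Method
print.proximity_result <- function(x, ...) {
  cat(sprintf(
    "<proximity_result> S_AB=%.4f, z=%.4f, ASPL=%.4f, edges=%d (p=%.4g)\n",
    x$separation$s_ab, x$zscore$z, x$aspl, x$edge_test$observed,
    x$edge_test$p_value))
  invisible(x)
}

#' @export
tidy.proximity_result <- function(x, ...) {
  tibble(
    s_ab = x$separation$s_ab, d_aa = x$separation$d_aa,
    d_bb = x$separation$d_bb, d_ab = x$separation$d_ab,
    z = x$zscore$z, null_mean = x$zscore$null_mean,
    null_sd = x$zscore$null_sd, aspl = x$aspl,
    observed_edges = x$edge_test$observed,
    edge_p_value = x$edge_test$p_value,
    n_a = x$set_sizes[["a"]], n_b = x$set_sizes[["b"]]
  )
}

#' @export
glance.proximity_result <- function(x, ...) tidy(x)

#' Read a PPI edge list and gene-set files
#'
#' The graph is a two-column TSV of node ids (one undirected edge per line;
#' self-loops and duplicate edges are dropped). A gene set is one id per
#' line.
#'
#' @param path File path.
#' @return `read_ppi_graph()` an igraph; `read_gene_set()` a character
#'   vector.
#' @export
read_ppi_graph <- function(path) {
  el <- readr::read_tsv(path, col_names = c("from", "to"), col_types = "cc",
                        progress = FALSE)
  check_ppi_graph(igraph::graph_from_edgelist(as.matrix(el), directed = FALSE))
}

#' @rdname read_ppi_graph
#' @export
read_gene_set <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  unique(x[nzchar(trimws(x))])
}

#' Write a proximity result as JSON
#'
#' All components plus null-distribution summaries.
#'
#' @param result A `proximity_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_proximity_result <- function(result, path) {
  payload <- c(
    as.list(tidy(result)),
    list(null_edge_sample = result$edge_test$null_sample,
         null_dab_summary = unclass(summary(result$zscore$null_sample)))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
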