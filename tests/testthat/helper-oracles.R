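# Independent oracles and fixture builders. Everything here deliberately
# avoids the package's own computational paths: distances are a hand-written
# BFS, networks are evaluated with explicit loops, co-occurrence is a double
# loop over records and pairs.

# A random small corpus as a plain tibble (validated by the package later).
random_corpus <- function(n = 8, n_sym = 6, n_herb = 5, seed = 1) {
  withr::with_seed(seed, {
    syms <- paste0("s", seq_len(n_sym))
    herbs <- paste0("h", seq_len(n_herb))
    tibble::tibble(
      record_id = paste0("r", seq_len(n)),
      domain = sample(c("source", "target"), n, replace = TRUE),
      symptoms = lapply(seq_len(n), function(i) sample(syms, sample(1:3, 1))),
      herbs = lapply(seq_len(n), function(i) sample(herbs, sample(1:3, 1)))
    )
  })
}

# Brute-force co-occurrence: loop over records x herb x symptom.
oracle_cooccurrence <- function(records, herb_terms, sym_terms) {
  C <- matrix(0L, length(herb_terms), length(sym_terms),
              dimnames = list(herb_terms, sym_terms))
  for (i in seq_len(nrow(records))) {
    for (h in records$herbs[[i]]) {
      for (s in records$symptoms[[i]]) {
        C[h, s] <- C[h, s] + 1L
      }
    }
  }
  C
}

# Hand-rolled two-layer ReLU autoencoder forward pass (row-vector layout).
oracle_autoencode <- function(y, W1, b1, W2, b2) {
  h <- pmax(as.numeric(y %*% W1) + b1, 0)
  pmax(as.numeric(h %*% W2) + b2, 0)
}

# Plain BFS shortest-path lengths from one node, over an edge-list graph
# given as a two-column character matrix. Returns a named vector (Inf for
# unreachable nodes).
oracle_bfs <- function(edges, nodes, from) {
  adj <- lapply(setNames(nodes, nodes), function(v) {
    c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
  })
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

oracle_dist_matrix <- function(graph, from, to) {
  edges <- igraph::as_edgelist(graph, names = TRUE)
  nodes <- igraph::V(graph)$name
  D <- matrix(Inf, length(from), length(to), dimnames = list(from, to))
  for (a in from) D[a, ] <- oracle_bfs(edges, nodes, a)[to]
  D
}

# Separation-score components evaluated with explicit loops over the BFS
# oracle distances (closest-distance convention, singleton within-set = 0).
oracle_separation <- function(graph, A, B) {
  within <- function(S) {
    if (length(S) < 2) return(0)
    mean(vapply(S, function(v) {
      min(oracle_dist_matrix(graph, v, setdiff(S, v)))
    }, numeric(1)))
  }
  d_ab_each <- c(
    vapply(A, function(v) min(oracle_dist_matrix(graph, v, B)), numeric(1)),
    vapply(B, function(v) min(oracle_dist_matrix(graph, v, A)), numeric(1))
  )
  d_ab <- mean(d_ab_each[is.finite(d_ab_each)])
  d_aa <- within(A); d_bb <- within(B)
  list(s_ab = d_ab - (d_aa + d_bb) / 2, d_aa = d_aa, d_bb = d_bb, d_ab = d_ab)
}

oracle_aspl <- function(graph, A, B) {
  D <- oracle_dist_matrix(graph, A, B)
  mean(D[is.finite(D)])
}

# Micro top-K metrics by explicit per-sample counting.
oracle_topk <- function(predicted, truth) {
  hits <- 0; np <- 0; nt <- 0
  for (i in seq_along(predicted)) {
    hits <- hits + sum(predicted[[i]] %in% truth[[i]])
    np <- np + length(predicted[[i]])
    nt <- nt + length(truth[[i]])
  }
  p <- hits / np; r <- hits / nt
  list(precision = p, recall = r,
       f1 = if (p + r == 0) 0 else 2 * p * r / (p + r))
}

random_named_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    igraph::set_vertex_attr(g, "name", value = paste0("v", seq_len(n)))
  })
}

# Explicit layer-by-layer forward evaluation of a stored network, written
# out in the test suite rather than delegating to the package's engine.
nn_forward_oracle <- function(net, x) {
  a <- as.matrix(x)
  for (l in seq_along(net$layers)) {
    z <- sweep(a %*% net$layers[[l]]$W, 2, net$layers[[l]]$b, "+")
    a <- switch(net$activations[l],
                relu = pmax(z, 0),
                linear = z,
                sigmoid = 1 / (1 + exp(-z)))
  }
  a
}

sq_norm_oracle <- function(net) {
  sum(vapply(net$layers, function(ly) sum(ly$W^2) + sum(ly$b^2), numeric(1)))
}
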