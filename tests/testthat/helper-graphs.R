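# Enumeration of all connected graphs with up to a given number of edges
# (one labelled representative per isomorphism class), for exhaustive
# link-community oracle checks.

enumerate_connected_graphs <- function(max_edges = 6) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  add_graph <- function(edge_mat, n) {
    g <- igraph::graph_from_edgelist(edge_mat, directed = FALSE)
    if (igraph::vcount(g) < n) {
      g <- igraph::add_vertices(g, n - igraph::vcount(g))
    }
    if (!igraph::is_connected(g)) return()
    cp <- igraph::canonical_permutation(g)$labeling
    cg <- igraph::permute(g, cp)
    key <- paste(as.vector(t(igraph::as_edgelist(cg))), collapse = ",")
    key <- paste0(n, ":", key)
    if (exists(key, envir = seen)) return()
    assign(key, TRUE, envir = seen)
    el <- igraph::as_edgelist(cg)
    out[[length(out) + 1]] <<- tibble::tibble(
      gene_i = paste0("v", pmin(el[, 1], el[, 2])),
      gene_j = paste0("v", pmax(el[, 1], el[, 2]))
    )
  }
  for (n in 2:(max_edges + 1)) {
    all_pairs <- t(utils::combn(n, 2))
    n_pairs <- nrow(all_pairs)
    for (m in (n - 1):min(max_edges, n_pairs)) {
      subsets <- utils::combn(n_pairs, m)
      for (col in seq_len(ncol(subsets))) {
        em <- all_pairs[subsets[, col], , drop = FALSE]
        if (length(unique(as.vector(em))) != n) next # must span all n nodes
        add_graph(em, n)
      }
    }
  }
  out
}

# independent partition-density oracle (direct formula, no package code)
oracle_partition_density <- function(pairs, membership) {
  total <- 0
  for (cm in unique(membership)) {
    sel <- membership == cm
    m_c <- sum(sel)
    n_c <- length(unique(c(pairs$gene_i[sel], pairs$gene_j[sel])))
    d_c <- if (n_c > 2) {
      (m_c - (n_c - 1)) / (n_c * (n_c - 1) / 2 - (n_c - 1))
    } else 0
    total <- total + m_c * d_c
  }
  total / nrow(pairs)
}
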