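# Link community detection: edges of the network are clustered (not nodes),
# so genes can belong to several modules. Edge pairs sharing a node get a
# Jaccard similarity of their outer endpoints' inclusive neighborhoods;
# single-linkage agglomeration over these similarities is cut at the
# partition-density maximum; modules with >= 3 genes are kept.

NEVER_MERGE <- 2 # distance for edge pairs with no defined similarity

# inclusive neighborhoods {v} + neighbors(v) from a pairs tibble
inclusive_neighborhoods <- function(pairs) {
  nodes <- unique(c(pairs$gene_i, pairs$gene_j))
  nb <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) nb[[v]] <- v
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$gene_i[k]
    b <- pairs$gene_j[k]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  lapply(nb, unique)
}

#' Jaccard similarity of two network edges
#'
#' Defined only for edge pairs sharing exactly one node `k`: for
#' `e1 = (k, i)` and `e2 = (k, j)`,
#' `S = |n+(i) & n+(j)| / |n+(i) | n+(j)|` with `n+(v)` the inclusive
#' neighborhood `{v} + neighbors(v)`. Returns `NA` for pairs sharing zero
#' (or both) nodes — such pairs are never merged.
#'
#' @param pairs Tibble of the network's gene pairs (`gene_i`, `gene_j`).
#' @param e1,e2 Length-2 character vectors naming the two edges' endpoints.
#' @return Similarity in `[0, 1]`, or `NA` if undefined.
#' @export
edge_similarity <- function(pairs, e1, e2) {
  shared <- intersect(e1, e2)
  if (length(shared) != 1) return(NA_real_)
  nb <- inclusive_neighborhoods(tibble::as_tibble(pairs))
  i <- setdiff(e1, shared)
  j <- setdiff(e2, shared)
  ni <- nb[[i]]
  nj <- nb[[j]]
  length(intersect(ni, nj)) / length(union(ni, nj))
}

# m x m distance matrix over edges: 1 - S where defined, NEVER_MERGE else
edge_distance_matrix <- function(pairs) {
  m <- nrow(pairs)
  nb <- inclusive_neighborhoods(pairs)
  d <- matrix(NEVER_MERGE, m, m)
  diag(d) <- 0
  # incidence: edges touching each node
  incident <- split(rep(seq_len(m), 2), c(pairs$gene_i, pairs$gene_j))
  for (edges_at_node in incident) {
    if (length(edges_at_node) < 2) next
    for (a in seq_len(length(edges_at_node) - 1)) {
      ea <- edges_at_node[a]
      for (b in (a + 1):length(edges_at_node)) {
        eb <- edges_at_node[b]
        if (d[ea, eb] < NEVER_MERGE) next
        outer_a <- setdiff(c(pairs$gene_i[ea], pairs$gene_j[ea]),
                           c(pairs$gene_i[eb], pairs$gene_j[eb]))
        outer_b <- setdiff(c(pairs$gene_i[eb], pairs$gene_j[eb]),
                           c(pairs$gene_i[ea], pairs$gene_j[ea]))
        if (length(outer_a) != 1 || length(outer_b) != 1) next
        ni <- nb[[outer_a]]
        nj <- nb[[outer_b]]
        s <- length(intersect(ni, nj)) / length(union(ni, nj))
        d[ea, eb] <- d[eb, ea] <- 1 - s
      }
    }
  }
  d
}

#' Single-linkage dendrogram over network edges
#'
#' Agglomerates the network's edges by single linkage on
#' `1 - edge_similarity`; edge pairs without a defined similarity (sharing
#' no node) are never merged (they sit at a sentinel distance above every
#' defined height). Edges are ordered by `(gene_i, gene_j)` for
#' determinism.
#'
#' @param network A `nodnet_network` (or a pairs tibble) with >= 2 edges.
#' @return A `nodnet_link_dendro` list: `hclust`, `pairs` (edge order =
#'   dendrogram leaf order).
#' @export
cluster_links <- function(network) {
  pairs <- if (inherits(network, "nodnet_network")) network$pairs
           else tibble::as_tibble(network)
  pairs <- dplyr::arrange(pairs, .data$gene_i, .data$gene_j)
  if (nrow(pairs) == 0) stop("edgeless network")
  if (nrow(pairs) == 1) {
    return(structure(list(hclust = NULL, pairs = pairs),
                     class = "nodnet_link_dendro"))
  }
  d <- edge_distance_matrix(pairs)
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  structure(list(hclust = hc, pairs = pairs),
            class = "nodnet_link_dendro")
}

#' Partition density of an edge partition
#'
#' For a community `c` with `m_c` edges over `n_c` nodes,
#' `D_c = (m_c - (n_c - 1)) / (n_c (n_c - 1) / 2 - (n_c - 1))` for
#' `n_c > 2` and 0 otherwise: 0 for a tree, 1 for a clique. The global
#' density is the edge-weighted mean `D = (1/M) * sum_c m_c * D_c`.
#'
#' @param pairs Tibble of network edges (`gene_i`, `gene_j`).
#' @param membership Integer community label per edge (rows of `pairs`).
#' @return List: `density` (global D), `per_community` tibble
#'   (`community`, `n_edges`, `n_genes`, `D_c`).
#' @export
partition_density <- function(pairs, membership) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(length(membership) == nrow(pairs))
  per <- purrr::map_dfr(unique(membership), function(cm) {
    sel <- membership == cm
    m_c <- sum(sel)
    n_c <- length(unique(c(pairs$gene_i[sel], pairs$gene_j[sel])))
    d_c <- if (n_c > 2) {
      (m_c - (n_c - 1)) / (n_c * (n_c - 1) / 2 - (n_c - 1))
    } else 0
    tibble::tibble(community = cm, n_edges = m_c, n_genes = n_c, D_c = d_c)
  })
  list(
    density = sum(per$n_edges * per$D_c) / nrow(pairs),
    per_community = dplyr::arrange(per, .data$community)
  )
}

#' Cut the link dendrogram at maximum partition density
#'
#' Evaluates the partition density at every distinct merge height (plus the
#' all-singletons cut) and returns the edge partition maximizing it. Merges
#' at the never-merge sentinel are not cuts: components without defined
#' similarities stay separate. Equal-density ties resolve toward more
#' communities (the lower cut).
#'
#' @param dendro A [cluster_links()] result.
#' @return A `nodnet_link_partition` list: `pairs`, `membership`,
#'   `density`, `per_community`, `cut_height`.
#' @export
cut_at_max_density <- function(dendro) {
  stopifnot(inherits(dendro, "nodnet_link_dendro"))
  pairs <- dendro$pairs
  if (is.null(dendro$hclust)) {
    membership <- rep(1L, nrow(pairs))
    pd <- partition_density(pairs, membership)
    return(structure(
      list(pairs = pairs, membership = membership, density = pd$density,
           per_community = pd$per_community, cut_height = 0),
      class = "nodnet_link_partition"
    ))
  }
  hc <- dendro$hclust
  heights <- sort(unique(hc$height[hc$height < NEVER_MERGE - 0.5]))
  candidates <- c(-1, heights) # -1 = all singletons
  best <- NULL
  for (h in candidates) {
    membership <- stats::cutree(hc, h = h + 1e-9)
    pd <- partition_density(pairs, membership)
    # strict improvement required: ties keep the earlier (lower) cut,
    # i.e. more communities
    if (is.null(best) || pd$density > best$density + 1e-12) {
      best <- list(membership = membership, density = pd$density,
                   per_community = pd$per_community, cut_height = h)
    }
  }
  structure(
    list(pairs = pairs, membership = unname(best$membership),
         density = best$density, per_community = best$per_community,
         cut_height = best$cut_height),
    class = "nodnet_link_partition"
  )
}

#' Filter link communities to modules with enough genes
#'
#' Keeps communities whose induced gene set has at least `min_genes`
#' members and assigns module ids `M0001, M0002, ...` in deterministic
#' order: descending edge count, then lexicographically smallest gene.
#'
#' @param partition A [cut_at_max_density()] result.
#' @param min_genes Minimum induced gene-set size (default 3).
#' @return A `nodnet_modules` list: `membership` (tibble `module`, `gene`),
#'   `edges` (tibble `module`, `gene_i`, `gene_j`), `summary` (tibble
#'   `module`, `n_genes`, `n_edges`, `D_c`), `density` (global, pre-filter).
#' @export
filter_modules <- function(partition, min_genes = 3) {
  stopifnot(inherits(partition, "nodnet_link_partition"))
  pairs <- partition$pairs
  mem <- partition$membership
  comm <- purrr::map(unique(mem), function(cm) {
    sel <- mem == cm
    genes <- sort(unique(c(pairs$gene_i[sel], pairs$gene_j[sel])))
    list(community = cm, genes = genes, n_edges = sum(sel),
         edges = pairs[sel, ])
  })
  comm <- purrr::keep(comm, ~ length(.x$genes) >= min_genes)
  if (length(comm) == 0) {
    return(structure(
      list(
        membership = tibble::tibble(module = character(), gene = character()),
        edges = tibble::tibble(module = character(), gene_i = character(),
                               gene_j = character()),
        summary = tibble::tibble(module = character(), n_genes = integer(),
                                 n_edges = integer(), D_c = numeric()),
        density = partition$density
      ),
      class = "nodnet_modules"
    ))
  }
  ord <- order(-purrr::map_int(comm, "n_edges"),
               purrr::map_chr(comm, ~ .x$genes[1]))
  comm <- comm[ord]
  ids <- sprintf("M%04d", seq_along(comm))
  pd <- partition_density(pairs, mem)
  membership <- purrr::map2_dfr(comm, ids, function(c, id) {
    tibble::tibble(module = id, gene = c$genes)
  })
  edges <- purrr::map2_dfr(comm, ids, function(c, id) {
    dplyr::mutate(c$edges, module = id, .before = 1)
  })
  summary <- purrr::map2_dfr(comm, ids, function(c, id) {
    tibble::tibble(
      module = id, n_genes = length(c$genes), n_edges = c$n_edges,
      D_c = pd$per_community$D_c[pd$per_community$community == c$community]
    )
  })
  structure(
    list(membership = membership, edges = edges, summary = summary,
         density = partition$density),
    class = "nodnet_modules"
  )
}

#' Detect link community modules in a network
#'
#' Convenience wrapper: [cluster_links()] then [cut_at_max_density()] then
#' [filter_modules()].
#'
#' @param network A `nodnet_network`.
#' @param min_genes Minimum module gene-set size (default 3).
#' @return A `nodnet_modules` object (see [filter_modules()]) with the
#'   pre-filter partition attached as attribute `"partition"`.
#' @export
link_communities <- function(network, min_genes = 3) {
  dendro <- cluster_links(network)
  partition <- cut_at_max_density(dendro)
  out <- filter_modules(partition, min_genes = min_genes)
  attr(out, "partition") <- partition
  out
}

#' @export
print.nodnet_modules <- function(x, ...) {
  cat(sprintf(
    "<nodnet_modules> %d modules (>= 3 genes), partition density %.3f\n",
    nrow(x$summary), x$density
  ))
  invisible(x)
}
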