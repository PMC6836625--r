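tri <- tibble::tibble(gene_i = c("a", "a", "b"), gene_j = c("b", "c", "c"))

test_that("edge similarity matches hand-computed Jaccard values", {
  # triangle: edges (a,b) and (a,c) share a; n+(b) = n+(c) = {a,b,c}
  expect_equal(edge_similarity(tri, c("a", "b"), c("a", "c")), 1)
  # triangle plus pendant d at a: n+(b) = {a,b,c}, n+(d) = {a,d}
  tp <- dplyr::bind_rows(tri, tibble::tibble(gene_i = "a", gene_j = "d"))
  expect_equal(edge_similarity(tp, c("a", "b"), c("a", "d")), 1 / 4)
  # no shared node, or identical edge: undefined
  expect_true(is.na(edge_similarity(tp, c("a", "b"), c("a", "b"))))
  disj <- tibble::tibble(gene_i = c("a", "c"), gene_j = c("b", "d"))
  expect_true(is.na(edge_similarity(disj, c("a", "b"), c("c", "d"))))
})

test_that("a triangle merges at height zero into one community", {
  dendro <- cluster_links(tri)
  expect_true(all(dendro$hclust$height[1:2] < 1e-12))
  part <- cut_at_max_density(dendro)
  expect_equal(length(unique(part$membership)), 1)
  expect_equal(part$density, 1) # m=3, n=3 community
})

test_that("disconnected components are never merged", {
  two <- tibble::tibble(gene_i = c("a", "a", "b", "x", "x", "y"),
                        gene_j = c("b", "c", "c", "y", "z", "z"))
  dendro <- cluster_links(two)
  part <- cut_at_max_density(dendro)
  memb_ab <- part$membership[dendro$pairs$gene_i %in% c("a", "b")]
  memb_xy <- part$membership[dendro$pairs$gene_i %in% c("x", "y")]
  expect_length(intersect(memb_ab, memb_xy), 0)
  expect_error(cluster_links(two[0, ]), "edgeless")
})

test_that("partition density is 1 for cliques and 0 for trees", {
  k4 <- tibble::tibble(gene_i = c("a", "a", "a", "b", "b", "c"),
                       gene_j = c("b", "c", "d", "c", "d", "d"))
  pd <- partition_density(k4, rep(1L, 6))
  expect_equal(pd$per_community$D_c, 1)
  expect_equal(pd$density, 1)
  path <- tibble::tibble(gene_i = c("a", "b", "c"), gene_j = c("b", "c", "d"))
  expect_equal(partition_density(path, rep(1L, 3))$density, 0)
  # two disjoint triangles as two communities: D = 1
  two_tri <- tibble::tibble(gene_i = c("a", "a", "b", "x", "x", "y"),
                            gene_j = c("b", "c", "c", "y", "z", "z"))
  expect_equal(partition_density(two_tri, c(1, 1, 1, 2, 2, 2))$density, 1)
})

test_that("the bowtie splits into its two triangles with node overlap", {
  bow <- tibble::tibble(gene_i = c("a", "a", "b", "a", "a", "d"),
                        gene_j = c("b", "c", "c", "d", "e", "e"))
  lc <- link_communities(pairs_as_network(bow))
  expect_equal(nrow(lc$summary), 2)
  g1 <- lc$membership$gene[lc$membership$module == "M0001"]
  g2 <- lc$membership$gene[lc$membership$module == "M0002"]
  expect_true(setequal(g1, c("a", "b", "c")) || setequal(g1, c("a", "d", "e")))
  expect_true(setequal(union(g1, g2), c("a", "b", "c", "d", "e")))
  # the shared gene belongs to both communities
  expect_equal(sum(lc$membership$gene == "a"), 2)
  # every edge appears in exactly one pre-filter community
  part <- attr(lc, "partition")
  expect_length(part$membership, 6)
})

test_that("module filtering enforces the 3-gene minimum and deterministic ids", {
  # triangle (kept) + isolated edge (2 genes, dropped)
  mix <- tibble::tibble(gene_i = c("a", "a", "b", "x"),
                        gene_j = c("b", "c", "c", "y"))
  lc <- link_communities(pairs_as_network(mix), min_genes = 3)
  expect_equal(nrow(lc$summary), 1)
  expect_equal(lc$summary$module, "M0001")
  expect_setequal(lc$membership$gene, c("a", "b", "c"))
  lc2 <- link_communities(pairs_as_network(mix), min_genes = 3)
  expect_identical(lc$membership, lc2$membership)
})

test_that("relabeling nodes yields an isomorphic module structure", {
  bow <- tibble::tibble(gene_i = c("a", "a", "b", "a", "a", "d"),
                        gene_j = c("b", "c", "c", "d", "e", "e"))
  relab <- c(a = "t", b = "w", c = "v", d = "u", e = "s")
  bow2 <- tibble::tibble(gene_i = pmin(relab[bow$gene_i], relab[bow$gene_j]),
                         gene_j = pmax(relab[bow$gene_i], relab[bow$gene_j]))
  lc1 <- link_communities(pairs_as_network(bow))
  lc2 <- link_communities(pairs_as_network(bow2))
  sizes1 <- sort(table(lc1$membership$module))
  sizes2 <- sort(table(lc2$membership$module))
  expect_equal(as.vector(sizes1), as.vector(sizes2))
  expect_equal(lc1$density, lc2$density)
})

test_that("the max-density cut equals exhaustive search over dendrogram cuts", {
  # spot-check on a handful of structured graphs; the exhaustive sweep over
  # every connected graph with <= 6 edges runs in the acceptance suite
  graphs <- list(
    tri,
    tibble::tibble(gene_i = c("a", "a", "b", "a", "a", "d"),
                   gene_j = c("b", "c", "c", "d", "e", "e")),
    tibble::tibble(gene_i = c("a", "b", "c", "d", "e"),
                   gene_j = c("b", "c", "d", "e", "f")),
    tibble::tibble(gene_i = c("a", "a", "a", "b", "b", "c"),
                   gene_j = c("b", "c", "d", "c", "d", "d"))
  )
  for (g in graphs) {
    dendro <- cluster_links(g)
    part <- cut_at_max_density(dendro)
    expect_equal(part$density,
                 oracle_partition_density(dendro$pairs, part$membership))
    heights <- c(-1, sort(unique(dendro$hclust$height)))
    best <- max(vapply(heights, function(h) {
      oracle_partition_density(dendro$pairs,
                               stats::cutree(dendro$hclust, h = h + 1e-9))
    }, numeric(1)))
    expect_equal(part$density, best)
  }
})
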