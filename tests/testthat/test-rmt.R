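test_that("equally spaced eigenvalues unfold to unit spacings", {
  s <- unfold_spacings(seq(0, 1, length.out = 120))
  expect_equal(mean(s), 1, tolerance = 0.05)
  expect_true(all(abs(s - 1) < 0.05))
  expect_error(unfold_spacings(1:49), "fewer than 50")
  # duplicates are collapsed before unfolding
  expect_error(unfold_spacings(rep(1:25, 4)), "fewer than 50")
})

test_that("chi-square against the exponential law behaves as a goodness of fit", {
  expect_error(chi2_vs_poisson(numeric(0)), "empty")
  expect_warning(chi2_vs_poisson(rexp(50)), "noisy")
  # degenerate histogram: all spacings in the first bin; closed form
  n <- 200
  s <- rep(0.01, n)
  nb <- 10
  breaks <- seq(0, 3, length.out = nb + 1)
  expd <- n * (exp(-breaks[-(nb + 1)]) - exp(-breaks[-1]))
  closed <- (n - expd[1])^2 / expd[1] + sum(expd[-1])
  expect_equal(suppressWarnings(chi2_vs_poisson(s, n_bins = nb)), closed)
  # large exponential samples sit below the critical value
  set.seed(10)
  chi <- chi2_vs_poisson(rexp(5000), n_bins = 60)
  expect_lt(chi, qchisq(0.999, 59))
})

test_that("seeded exponential spacing samples pass the Poisson test reliably", {
  set.seed(33)
  crit <- qchisq(0.999, 59)
  ok <- replicate(100, chi2_vs_poisson(rexp(1000), n_bins = 60) < crit)
  expect_gte(mean(ok), 0.95)
})

test_that("extract_network applies the absolute-correlation rule", {
  e <- fake_edges(c("a", "b", "c"), c("b", "c", "d"), r = c(0.95, -0.95, 0.90))
  net <- extract_network(e, 0.946)
  expect_equal(nrow(net$pairs), 2)
  expect_setequal(net$nodes, c("a", "b", "c"))
  strict <- extract_network(e, 1.0)
  expect_equal(nrow(strict$pairs), 0)
  empty <- extract_network(e[0, ], 0.9)
  expect_length(empty$nodes, 0)
})

test_that("edge count is non-increasing in the threshold", {
  set.seed(6)
  e <- fake_edges(sprintf("a%d", 1:200), sprintf("b%d", 1:200),
                  r = runif(200, -1, 1))
  sizes <- sapply(seq(0.1, 0.9, by = 0.1),
                  function(t) nrow(extract_network(e, t)$pairs))
  expect_true(all(diff(sizes) <= 0))
})

test_that("similarity matrix takes the max |r| over clusters and prunes", {
  e <- tibble::tibble(
    gene_i = c("a", "a", "b"), gene_j = c("b", "b", "c"),
    cluster = c(1L, 2L, 1L), n = 25L,
    r = c(0.5, -0.9, 0.2), sample_mask = strrep("1", 30)
  )
  m <- similarity_matrix(e, 0.8)
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["a", "b"], 0.9) # max |r| over the two clusters
  expect_equal(diag(m), c(a = 1, b = 1))
})

test_that("an exact power-law degree histogram fits with R squared 1", {
  # frequencies 64, 16, 4, 1 at degrees 1, 2, 4, 8: exactly log-log linear
  set.seed(12)
  deg_seq <- rep(c(1L, 2L, 4L, 8L), c(64, 16, 4, 1))
  g <- igraph::sample_degseq(deg_seq, method = "configuration")
  el <- igraph::as_edgelist(g)
  pairs <- tibble::tibble(gene_i = paste0("g", el[, 1]),
                          gene_j = paste0("g", el[, 2]))
  net <- pairs_as_network(pairs)
  # multigraph artifacts collapse duplicate pairs; recompute histogram check
  r2 <- scale_free_fit(net)
  deg <- igraph::degree(igraph::graph_from_data_frame(net$pairs,
                                                      directed = FALSE))
  tab <- table(deg[deg > 0])
  oracle <- summary(stats::lm(log10(as.numeric(tab)) ~
                                log10(as.numeric(names(tab)))))$r.squared
  expect_equal(as.numeric(r2), oracle, tolerance = 1e-12)
})

test_that("preferential-attachment networks score as scale-free", {
  set.seed(13)
  g <- igraph::sample_pa(2000, m = 2, directed = FALSE)
  el <- igraph::as_edgelist(g)
  pairs <- dplyr::distinct(tibble::tibble(
    gene_i = paste0("g", pmin(el[, 1], el[, 2])),
    gene_j = paste0("g", pmax(el[, 1], el[, 2]))
  ))
  net <- pairs_as_network(pairs)
  expect_gte(as.numeric(scale_free_fit(net)), 0.8)
})

test_that("degenerate degree distributions are flagged", {
  # a perfect cycle: every node has degree 2
  pairs <- tibble::tibble(gene_i = paste0("g", 1:12),
                          gene_j = paste0("g", c(2:12, 1)))
  net <- pairs_as_network(pairs)
  expect_warning(r2 <- scale_free_fit(net), "all degrees equal")
  expect_true(is.na(r2))
  # a star has two distinct degrees: R squared 1 but underpowered
  star <- tibble::tibble(gene_i = "hub", gene_j = paste0("leaf", 1:15))
  expect_warning(r2s <- scale_free_fit(pairs_as_network(star)),
                 "underpowered")
  expect_equal(as.numeric(r2s), 1)
})

test_that("threshold search finds a cutoff separating cliques from background", {
  # planted structure: 30 disjoint near-cliques of 5 genes with |r| ~ 0.99
  # over a diffuse 0.3 background (enough eigenvalues that the spacing
  # test has power to recognise the background bulk)
  set.seed(14)
  genes <- sprintf("g%03d", 1:150)
  rec <- list()
  for (b in 0:29) {
    ids <- genes[b * 5 + 1:5]
    cmb <- utils::combn(ids, 2)
    rec[[length(rec) + 1]] <- fake_edges(cmb[1, ], cmb[2, ],
                                         r = runif(ncol(cmb), 0.985, 0.995))
  }
  cmb_all <- utils::combn(genes, 2)
  cross <- ceiling(match(cmb_all[1, ], genes) / 5) !=
    ceiling(match(cmb_all[2, ], genes) / 5)
  rec[[length(rec) + 1]] <- fake_edges(
    cmb_all[1, cross], cmb_all[2, cross],
    r = runif(sum(cross), 0.25, 0.35)
  )
  e <- dplyr::bind_rows(rec)
  th <- find_threshold(e, start = 0.99, step = 0.005, floor = 0.2,
                       min_size = 50)
  expect_gt(th$threshold, 0.3)
  expect_lt(th$threshold, 0.99)
  expect_true(all(c("cutoff", "n_genes", "chi2", "decision") %in%
                    names(th$trace)))
})

test_that("a background-only candidate stream yields the density error", {
  e <- fake_edges(sprintf("a%d", 1:100), sprintf("b%d", 1:100),
                  r = runif(100, 0, 0.4))
  expect_error(find_threshold(e, start = 0.99, step = 0.01, floor = 0.5),
               "insufficient network density")
})

test_that("the threshold sweep is deterministic", {
  set.seed(15)
  e <- fake_edges(sprintf("a%d", 1:300),
                  sample(sprintf("b%d", 1:50), 300, replace = TRUE),
                  r = runif(300, 0.5, 1))
  t1 <- try(find_threshold(e, floor = 0.5, min_size = 30), silent = TRUE)
  t2 <- try(find_threshold(e, floor = 0.5, min_size = 30), silent = TRUE)
  if (inherits(t1, "try-error")) {
    expect_identical(class(t2), class(t1))
  } else {
    expect_identical(t1$threshold, t2$threshold)
    expect_identical(t1$trace, t2$trace)
  }
})
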