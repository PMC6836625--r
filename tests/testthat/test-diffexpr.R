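test_that("low-count filter applies the row-sum >= 50 rule", {
  m <- rbind(a = c(25, 24), b = c(25, 25), c = c(0, 0))
  colnames(m) <- c("s1", "s2")
  out <- low_count_filter(m)
  expect_identical(rownames(out), "b") # 49 removed, 50 retained
  zero <- matrix(0, 3, 2, dimnames = list(letters[1:3], c("s1", "s2")))
  expect_equal(nrow(low_count_filter(zero)), 0)
  expect_error(low_count_filter(m - 30), "non-negative")
})

test_that("size factors match the median-of-ratios hand computation", {
  cts <- rbind(g1 = c(10, 20), g2 = c(100, 200), g3 = c(30, 60))
  colnames(cts) <- c("s1", "s2")
  sf <- size_factors(cts)
  expect_equal(unname(round(sf, 4)), c(0.7071, 1.4142))
  # identical columns give unit factors
  same <- cbind(s1 = c(5, 50, 500), s2 = c(5, 50, 500))
  expect_equal(unname(size_factors(same)), c(1, 1))
  # permuting samples permutes factors identically
  sf_perm <- size_factors(cts[, c(2, 1)])
  expect_equal(unname(sf_perm), unname(sf[c(2, 1)]))
  # scaling one sample's column scales its factor
  cts2 <- cts
  cts2[, 2] <- cts2[, 2] * 5
  expect_equal(unname(size_factors(cts2)[2] / size_factors(cts)[2]),
               5 * unname(size_factors(cts2)[1] / size_factors(cts)[1]))
  expect_error(size_factors(rbind(c(0, 1), c(1, 0))), "positive")
})

test_that("BH adjustment matches a hand implementation and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # independent step-up oracle
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- rep(NA_real_, m)
    running <- 1
    for (i in m:1) {
      running <- min(running, m / i * p[o[i]])
      adj[o[i]] <- running
    }
    adj
  }
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^2
    expect_equal(bh_adjust(p), bh_oracle(p))
    ranks <- order(p)
    expect_true(all(diff(bh_adjust(p)[ranks]) >= -1e-15))
  }
})

test_that("identical groups give zero fold change and no significance", {
  set.seed(8)
  ctrl <- matrix(rnbinom(60, mu = 100, size = 10), 20, 3)
  cts <- cbind(ctrl, ctrl)
  rownames(cts) <- sprintf("g%d", 1:20)
  colnames(cts) <- toy_meta()$sample
  res <- nb_wald_test(cts, toy_meta(), time_h = 24)
  expect_true(all(abs(res$log2fc) < 1e-8))
  expect_false(any(res$significant))
})

test_that("swapping condition labels negates fold changes and keeps p-values", {
  sim <- small_sim()
  res <- nb_wald_test(sim$counts, sim$sample_meta, time_h = 24)
  meta_sw <- sim$sample_meta
  meta_sw$condition <- ifelse(meta_sw$condition == "control",
                              "inoculated", "control")
  res_sw <- nb_wald_test(sim$counts, meta_sw, time_h = 24)
  expect_equal(res_sw$log2fc, -res$log2fc, tolerance = 1e-6)
  expect_equal(res_sw$pvalue, res$pvalue, tolerance = 1e-6)
})

test_that("planted |log2fc| = 2 at mean 500 is detected with power >= 0.9", {
  # 900 null genes at mean 500; 50 up (x4) and 50 down (/4) in the
  # inoculated group; dispersion 0.05, 3 vs 3
  set.seed(22)
  n_gene <- 1000
  mu <- matrix(500, n_gene, 6)
  mu[1:50, 4:6] <- 2000
  mu[51:100, 4:6] <- 125
  cts <- matrix(rnbinom(n_gene * 6, mu = as.vector(mu), size = 1 / 0.05),
                n_gene, 6,
                dimnames = list(sprintf("g%04d", 1:n_gene),
                                toy_meta()$sample))
  res <- nb_wald_test(cts, toy_meta(), time_h = 24)
  alt <- res[res$gene %in% sprintf("g%04d", 1:100), ]
  expect_gte(mean(alt$significant), 0.9)
  # direction of the estimate matches the planted sign
  up <- sprintf("g%04d", 1:50)
  dn <- sprintf("g%04d", 51:100)
  expect_true(all(alt$log2fc[alt$gene %in% up & alt$significant] > 0))
  expect_true(all(alt$log2fc[alt$gene %in% dn & alt$significant] < 0))
  # false discoveries among the 900 null genes stay near the nominal FDR
  null <- res[!res$gene %in% sprintf("g%04d", 1:100), ]
  expect_lt(mean(null$significant), 0.05)
})

test_that("nb_wald_test validates its inputs", {
  sim <- small_sim()
  expect_error(nb_wald_test(sim$counts, sim$sample_meta, time_h = 999),
               "no samples")
  meta1 <- sim$sample_meta[sim$sample_meta$condition == "control", ]
  expect_error(nb_wald_test(sim$counts[, meta1$sample], meta1, time_h = 24),
               "both conditions")
  meta2 <- sim$sample_meta[sim$sample_meta$time_h == 24, ][c(1, 4), ]
  expect_error(nb_wald_test(sim$counts[, meta2$sample], meta2, time_h = 24),
               "2 replicates")
})

test_that("deg_sets computes exact unique and intersection counts", {
  de <- tibble::tibble(
    gene = c("a", "b", "b", "c"),
    time_h = c(12, 12, 24, 24),
    log2fc = c(1, -1, -1, 2),
    significant = TRUE
  )
  out <- deg_sets(de)
  expect_equal(out$unique_counts$n_unique, c(1, 1))
  expect_equal(out$unique_counts$n_total, c(2, 2))
  both <- out$intersections[out$intersections$pattern == "12+24", ]
  expect_equal(both$n, 1L)
  expect_equal(out$sets$direction[out$sets$gene == "b"], c("down", "down"))
  # empty results give zero counts
  empty <- deg_sets(dplyr::mutate(de, significant = FALSE))
  expect_true(all(empty$unique_counts$n_unique == 0))
  expect_equal(nrow(empty$intersections), 0)
})

test_that("run_de recovers planted time-point-specific DEGs end to end", {
  sim <- small_sim()
  de <- run_de(sim$counts, sim$sample_meta)
  truth <- sim$truth$de
  called <- de[de$significant & de$time_h == 24, ]
  expect_true(all(truth$gene %in% called$gene))
  expect_true(all(called$log2fc[called$gene %in% truth$gene] < 0))
})
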