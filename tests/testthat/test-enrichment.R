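write_ann <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("annotation loading collapses duplicates and skips malformed lines", {
  path <- write_ann(c(
    "g1\tGO\tGO:0001\tsomething",
    "g1\tGO\tGO:0001\tsomething",
    "g2\tPfam\tPF01190",
    "broken line without tabs"
  ))
  expect_warning(ann <- load_annotations(path), "malformed")
  expect_equal(nrow(ann), 2)
  expect_equal(attr(ann, "n_skipped"), 1L)
  expect_equal(sort(unique(ann$vocabulary)), c("GO", "Pfam"))
  empty <- write_ann(character(0))
  expect_warning(out <- load_annotations(empty), "empty")
  expect_equal(nrow(out), 0)
  expect_error(load_annotations("/nonexistent/file.tsv"), "not found")
})

test_that("enrichment p-value matches the closed-form hypergeometric tail", {
  # 100-gene annotated background, 10 genes carry the term, all 5 module
  # genes carry it: p = C(10,5) / C(100,5)
  background <- sprintf("g%03d", 1:100)
  module <- background[1:5]
  ann <- dplyr::bind_rows(
    tibble::tibble(gene = background[1:10], vocabulary = "Pfam",
                   term = "PF0001", name = "test domain"),
    tibble::tibble(gene = background, vocabulary = "Pfam",
                   term = "PF_base", name = NA_character_)
  )
  out <- fisher_enrich(module, background, ann)
  row <- out[out$term == "PF0001", ]
  expect_equal(row$pvalue, 252 / 75287520, tolerance = 1e-12)
  expect_equal(row$k, 5L)
  expect_equal(row$K, 10L)
  expect_equal(row$N, 100L)
})

test_that("ubiquitous terms and module == background give p = 1", {
  background <- sprintf("g%02d", 1:20)
  ann <- tibble::tibble(gene = background, vocabulary = "GO",
                        term = "GO:everything", name = NA_character_)
  out <- fisher_enrich(background[1:4], background, ann)
  expect_equal(out$pvalue, 1)
  out2 <- fisher_enrich(background, background, ann)
  expect_true(all(out2$pvalue == 1))
  expect_error(fisher_enrich(character(0), background, ann), "empty")
  expect_error(fisher_enrich("not_in_bg", background, ann), "subset")
})

test_that("p-values agree with an independent factorial-ratio oracle on small tables", {
  # oracle: sum of hypergeometric point masses computed from factorials
  tail_oracle <- function(k, K, N, n) {
    lch <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)
    xs <- k:min(n, K)
    sum(exp(lch(K, xs) + lch(N - K, n - xs) - lch(N, n)))
  }
  set.seed(30)
  for (i in 1:25) {
    N <- sample(10:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    background <- sprintf("g%03d", 1:N)
    with_term <- sample(background, K)
    module <- sample(background, n)
    k <- length(intersect(module, with_term))
    if (k == 0) next
    ann <- dplyr::bind_rows(
      tibble::tibble(gene = with_term, vocabulary = "GO",
                     term = "T", name = NA_character_),
      tibble::tibble(gene = background, vocabulary = "GO",
                     term = "GO_base", name = NA_character_)
    )
    out <- fisher_enrich(module, background, ann)
    out <- out[out$term == "T", ]
    expect_equal(out$pvalue, tail_oracle(k, K, N, n), tolerance = 1e-10)
    # and with fisher.test as a second, independent route
    ft <- stats::fisher.test(matrix(c(k, n - k, K - k, N - K - (n - k)), 2),
                             alternative = "greater")
    expect_equal(out$pvalue, unname(ft$p.value), tolerance = 1e-8)
  }
})

test_that("a term planted in every module gene ranks first", {
  set.seed(31)
  background <- sprintf("g%03d", 1:200)
  module <- background[1:8]
  planted <- tibble::tibble(gene = module, vocabulary = "Pfam",
                            term = "PF_planted", name = "planted")
  noise <- tibble::tibble(
    gene = sample(background, 300, replace = TRUE),
    vocabulary = "Pfam",
    term = sample(sprintf("PF%03d", 1:30), 300, replace = TRUE),
    name = NA_character_
  )
  ann <- dplyr::distinct(dplyr::bind_rows(planted, noise),
                         gene, vocabulary, term, .keep_all = TRUE)
  out <- fisher_enrich(module, background, ann)
  expect_equal(out$term[1], "PF_planted")
})

test_that("unannotated background genes do not change enrichment", {
  background <- sprintf("g%03d", 1:50)
  ann <- tibble::tibble(gene = background[1:30], vocabulary = "GO",
                        term = rep(c("A", "B"), 15), name = NA_character_)
  module <- background[1:6]
  out1 <- fisher_enrich(module, background, ann)
  out2 <- fisher_enrich(module, c(background, sprintf("x%02d", 1:40)), ann)
  expect_equal(out1$pvalue, out2$pvalue)
})

test_that("enrich_modules runs per module and respects vocabularies", {
  membership <- tibble::tibble(module = rep(c("M0001", "M0002"), each = 3),
                               gene = c("g1", "g2", "g3", "g4", "g5", "g6"))
  background <- sprintf("g%d", 1:20)
  ann <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g4", "g5", "g6", "g7"),
    vocabulary = c(rep("GO", 3), rep("KEGG", 4)),
    term = c(rep("GO:1", 3), rep("K1", 4)),
    name = NA_character_
  )
  out <- enrich_modules(membership, background, ann)
  expect_setequal(unique(out$module), c("M0001", "M0002"))
  expect_equal(out$vocabulary[out$module == "M0001"], "GO")
  expect_equal(out$vocabulary[out$module == "M0002"], "KEGG")
  # BH within vocabulary never drops below the raw p
  expect_true(all(out$padj >= out$pvalue - 1e-15))
})
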