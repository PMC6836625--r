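# Shared fixtures built in code. Expensive objects are computed lazily and
# cached for the duration of one test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small two-condition experiment with one planted 24 h-down module
small_sim <- function() {
  cached("small_sim", {
    # clearly detectable planted structure: large effect, low dispersion
    d <- design_spec(n_genes = 40, seed = 3)
    m <- planted_module(d$genes[1:6], loading = 1.2, de_timepoint = 24,
                        de_direction = "down", de_log2fc = 3,
                        base_shift = 1)
    simulate_counts(d, list(m), dispersion = 0.02)
  })
}

small_gem <- function() {
  cached("small_gem", {
    sim <- small_sim()
    counts_to_fpkm(sim$counts, sim$gene_length_bp) |>
      expression_matrix(sim$sample_meta, state = "fpkm") |>
      log2_transform() |>
      quantile_normalize()
  })
}

# metadata for hand-built count matrices: one time point, two conditions
toy_meta <- function(n_per_group = 3, time_h = 24) {
  tibble::tibble(
    sample = c(sprintf("c%d", seq_len(n_per_group)),
               sprintf("i%d", seq_len(n_per_group))),
    condition = rep(c("control", "inoculated"), each = n_per_group),
    time_h = time_h,
    replicate = rep(seq_len(n_per_group), 2)
  )
}

# gem constructor for hand-built matrices
toy_gem <- function(values, state = "log2") {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%d", seq_len(n))
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  meta <- tibble::tibble(sample = colnames(values),
                         condition = rep_len(c("control", "inoculated"), n),
                         time_h = 0, replicate = seq_len(n))
  expression_matrix(values, meta, state = state)
}

# fabricate an edge-record tibble from a pairs data frame (plumbing tests)
fake_edges <- function(gene_i, gene_j, r, n = 30L, n_samples = 30L) {
  tibble::tibble(
    gene_i = gene_i, gene_j = gene_j, cluster = 1L,
    n = as.integer(n), r = r,
    sample_mask = strrep("1", n_samples)
  )
}

# wrap a pairs tibble as a nodnet_network (unit-weight edges)
pairs_as_network <- function(pairs) {
  extract_network(fake_edges(pairs$gene_i, pairs$gene_j, r = 1), threshold = 0.5)
}
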