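# The package's canonical synthetic experiment: the nodulation study design
# (2 conditions x 5 time points x 3 replicates) with a landscape of planted
# co-expression modules of varying coherence and one tightly co-regulated
# biomarker module down-regulated at 24 h post-inoculation.

#' Canonical synthetic nodulation time-course experiment
#'
#' Generates the experiment used throughout the package's examples and
#' acceptance checks: 200 genes, 30 samples (control vs inoculated at 0,
#' 12, 24, 48 and 72 h, 3 replicates each), 18 planted co-expression
#' modules of 8 genes. Module 1 is the planted biomarker: tightly
#' co-regulated: a designed, gradually rising unit-variance time profile
#' shared by its members (per-gene loadings 1.3-1.5), small private
#' dynamics, a detectably expressed baseline (lift of 1.5 natural-log
#' units), and down-regulation of 4 log2 units in inoculated samples at
#' 24 h. The remaining 17 modules carry no
#' condition effect and span a range of coherence (loadings 0.8-2.2), so
#' the network contains both recoverable and borderline modules, as real
#' co-expression data does. The remaining 56 genes are unstructured
#' background.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_genes,n_modules,module_size Experiment dimensions (defaults
#'   200, 18, 8).
#' @param de_log2fc Planted condition effect of the biomarker module
#'   (default 4, within the fold-change range of published nodulation
#'   DEG tables).
#' @param dispersion Negative-binomial dispersion (default 0.05).
#' @return A list: `sim` ([simulate_counts()] output), `design`, `modules`
#'   and `biomarker` (gene ids of the planted 24 h-down module).
#' @export
#' @examples
#' exp <- demo_experiment(seed = 1)
#' dim(exp$sim$counts)
demo_experiment <- function(seed = 1, n_genes = 200, n_modules = 18,
                            module_size = 8, de_log2fc = 4,
                            dispersion = 0.05) {
  stopifnot(n_modules * module_size <= n_genes)
  design <- design_spec(n_genes = n_genes, seed = seed)
  loadings <- with_local_seed(seed_stream(seed, "scenario-loadings"), {
    lapply(seq_len(n_modules), function(m) {
      if (m == 1) {
        stats::runif(module_size, 1.3, 1.5)
      } else {
        stats::runif(module_size, 0.8, 2.2)
      }
    })
  })
  modules <- lapply(seq_len(n_modules), function(m) {
    genes <- design$genes[((m - 1) * module_size + 1):(m * module_size)]
    if (m == 1) {
      # the biomarker module emulates a recoverable exemplar: a smooth,
      # gradually rising shared time profile (an elongated continuum in
      # any pair's expression plane, so sample clusters keep >= min_obs
      # members), tight co-regulation (small private dynamics), and a
      # detectably expressed baseline
      planted_module(genes, loading = loadings[[m]], de_timepoint = 24,
                     de_direction = "down", de_log2fc = de_log2fc,
                     base_shift = 1.5,
                     profile = c(-2, -1, 0, 1, 2),
                     dynamics_scale = 0.2)
    } else {
      planted_module(genes, loading = loadings[[m]])
    }
  })
  sim <- simulate_counts(design, modules, dispersion = dispersion)
  list(
    sim = sim,
    design = design,
    modules = modules,
    biomarker = modules[[1]]$genes
  )
}
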