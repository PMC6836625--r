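# Synthetic RNA-seq time courses with planted co-expression modules and
# planted per-time-point differential expression. The generator mirrors the
# nodulation study design: 2 conditions x 5 time points x 3 replicates.

#' Describe a simulated experiment design
#'
#' Captures the dimensions of a two-condition time-course RNA-seq experiment:
#' control vs. inoculated samples at each time point, with biological
#' replicates. Defaults reproduce the nodulation study layout (30 samples =
#' 2 conditions x 5 time points x 3 replicates).
#'
#' @param n_genes Number of genes in the simulated transcriptome.
#' @param n_reps Biological replicates per condition per time point.
#' @param timepoints Sampling times in hours post-inoculation.
#' @param gene_length_bp Per-gene length in base pairs (recycled if scalar).
#'   If `NULL`, lengths are drawn log-normally around 2 kb from the design
#'   seed.
#' @param library_size Expected total fragments per sample (recycled across
#'   samples). Realized depths are log-normally jittered (sigma = 0.1) to
#'   exercise normalization.
#' @param seed Integer seed; a single seed drives a hierarchical stream so
#'   each generation stage is independently reproducible.
#' @return A `nodnet_design` list with gene ids, sample ids and metadata.
#' @export
#' @examples
#' d <- design_spec(n_genes = 50, seed = 1)
#' nrow(d$sample_meta)  # 30
design_spec <- function(n_genes,
                        n_reps = 3,
                        timepoints = c(0, 12, 24, 48, 72),
                        gene_length_bp = NULL,
                        library_size = 1e6,
                        seed = 1L) {
  stopifnot(n_genes >= 1, n_reps >= 1, length(timepoints) >= 1)
  genes <- sprintf("G%05d", seq_len(n_genes))
  meta <- tidyr::expand_grid(
    condition = c("control", "inoculated"),
    time_h = timepoints,
    replicate = seq_len(n_reps)
  )
  meta <- dplyr::mutate(
    meta,
    sample = sprintf(
      "%s_%03dh_r%d",
      ifelse(.data$condition == "control", "ctrl", "inoc"),
      .data$time_h, .data$replicate
    ),
    .before = 1
  )
  if (is.null(gene_length_bp)) {
    gene_length_bp <- with_local_seed(seed_stream(seed, "lengths"), {
      pmax(200L, as.integer(round(2000 * exp(stats::rnorm(n_genes, 0, 0.35)))))
    })
  }
  gene_length_bp <- rep_len(gene_length_bp, n_genes)
  library_size <- rep_len(library_size, nrow(meta))
  if (any(gene_length_bp <= 0)) stop("gene lengths must be positive")
  if (any(library_size <= 0)) stop("library sizes must be positive")
  structure(
    list(
      genes = genes,
      gene_length_bp = stats::setNames(gene_length_bp, genes),
      sample_meta = meta,
      library_size = stats::setNames(library_size, meta$sample),
      timepoints = timepoints,
      n_reps = n_reps,
      seed = as.integer(seed)
    ),
    class = "nodnet_design"
  )
}

#' Specify a planted co-expression module
#'
#' A planted module is a gene set sharing a latent time-course expression
#' profile (producing co-expression across all 30 samples) and, optionally,
#' a condition effect at one time point (producing time-point-specific
#' differential expression in inoculated samples).
#'
#' @param genes Character vector of member gene ids (>= 3).
#' @param loading Per-gene coefficient on the module's latent profile
#'   (recycled). Larger loadings give tighter within-module correlation.
#' @param de_timepoint Hour at which the condition effect applies, or `NULL`
#'   for a module with no planted differential expression.
#' @param de_direction `"up"`, `"down"` or `"none"`.
#' @param de_log2fc Magnitude (> 0) of the planted log2 fold change
#'   (inoculated vs control) at `de_timepoint`.
#' @param base_shift Additive shift (natural-log scale) applied to member
#'   genes' baseline abundance; use a positive value for modules of
#'   detectably expressed genes regardless of the baseline draw.
#' @param profile Optional per-time-point latent profile (numeric vector,
#'   one value per design time point; standardized internally). When
#'   `NULL`, a smooth random-walk profile is drawn from the simulation
#'   seed.
#' @param dynamics_scale Multiplier on member genes' private time
#'   dynamics (default 1). Tightly co-regulated modules have their
#'   temporal variation dominated by the shared program; values < 1
#'   express that.
#' @return A `nodnet_planted_module` list.
#' @export
planted_module <- function(genes, loading = 1,
                           de_timepoint = NULL,
                           de_direction = c("none", "up", "down"),
                           de_log2fc = 0, base_shift = 0,
                           profile = NULL, dynamics_scale = 1) {
  de_direction <- match.arg(de_direction)
  if (length(genes) < 3) stop("a planted module needs at least 3 member genes")
  if (anyDuplicated(genes)) stop("duplicate genes in module")
  if (de_direction != "none") {
    if (is.null(de_timepoint)) stop("de_timepoint required when de_direction != 'none'")
    if (de_log2fc <= 0) stop("de_log2fc must be > 0 when de_direction != 'none'")
  }
  structure(
    list(
      genes = as.character(genes),
      loading = rep_len(loading, length(genes)),
      de_timepoint = de_timepoint,
      de_direction = de_direction,
      de_log2fc = de_log2fc,
      base_shift = base_shift,
      profile = profile,
      dynamics_scale = dynamics_scale
    ),
    class = "nodnet_planted_module"
  )
}

#' Simulate a count matrix with planted structure
#'
#' Counts are negative-binomially distributed with mean
#' `mu_gs = s_s * (L_g / 1000) * exp(base_g + loading_g * latent_m(s) + beta)`
#' where `s_s` is the sample depth factor (`library_size / 1e6` times a
#' log-normal jitter), `L_g` the gene length in bp, `base_g` a per-gene
#' baseline calibrated so the expected total per sample matches the design
#' library size, `latent_m(s)` a smooth per-module time profile with
#' replicate noise, and `beta = +/- de_log2fc * ln 2` only for member genes
#' in inoculated samples at the module's DE time point. Variance is
#' `mu + dispersion * mu^2`.
#'
#' In addition to module structure, every gene carries a private smooth
#' time profile (`gene_dynamics_sd`), shared between conditions: most
#' transcripts change over a developmental time course whether or not they
#' respond to inoculation. This term cancels in condition contrasts but
#' shapes the correlation background of the co-expression network.
#'
#' @param design A [design_spec()] object.
#' @param modules List of [planted_module()] specifications; member sets may
#'   overlap.
#' @param dispersion Negative-binomial dispersion alpha (> 0), scalar or
#'   per-gene.
#' @param gene_dynamics_sd Temporal standard deviation (log scale) of each
#'   gene's private smooth time profile (default 0.5, 0 to disable).
#' @return A `nodnet_sim` list: `counts` (genes x samples integer matrix),
#'   `sample_meta`, `truth` (module membership and per-gene per-time-point DE
#'   status), `mu` (expected counts), `fpkm` helper inputs.
#' @export
#' @examples
#' d <- design_spec(n_genes = 30, seed = 7)
#' m <- planted_module(d$genes[1:5], de_timepoint = 24,
#'                     de_direction = "down", de_log2fc = 2)
#' sim <- simulate_counts(d, list(m))
#' dim(sim$counts)
simulate_counts <- function(design, modules = list(), dispersion = 0.05,
                            gene_dynamics_sd = 0.5) {
  stopifnot(inherits(design, "nodnet_design"))
  if (inherits(modules, "nodnet_planted_module")) modules <- list(modules)
  genes <- design$genes
  meta <- design$sample_meta
  n_g <- length(genes)
  n_s <- nrow(meta)
  for (m in modules) {
    bad <- setdiff(m$genes, genes)
    if (length(bad) > 0) {
      stop("module contains genes outside the design universe: ",
           paste(utils::head(bad, 3), collapse = ", "))
    }
  }
  dispersion <- rep_len(dispersion, n_g)
  if (any(!is.finite(dispersion)) || any(dispersion <= 0)) {
    stop("dispersion must be positive")
  }

  # baseline abundances, calibrated so E[column total] ~= library_size
  base <- with_local_seed(seed_stream(design$seed, "baseline"), {
    stats::rnorm(n_g, mean = 0, sd = 1.5)
  })
  len_kb <- design$gene_length_bp / 1000
  scale_const <- 1e6 / sum(len_kb * exp(base))
  base <- base + log(scale_const)

  # sample depth factors: design library size with log-normal jitter
  depth <- with_local_seed(seed_stream(design$seed, "depth"), {
    (design$library_size / 1e6) * exp(stats::rnorm(n_s, 0, 0.1))
  })

  # latent module profiles: smooth in time, replicate noise per sample
  latent <- matrix(0, length(modules), n_s)
  if (length(modules) > 0) {
    latent <- with_local_seed(seed_stream(design$seed, "latent"), {
      t(vapply(seq_along(modules), function(i) {
        prof <- modules[[i]]$profile
        if (is.null(prof)) {
          prof <- cumsum(stats::rnorm(length(design$timepoints), 0, 1))
        }
        if (length(prof) != length(design$timepoints)) {
          stop("module profile must have one value per time point")
        }
        # unit-variance time profile: a module's loading is its log-scale
        # effect size; replicate noise enters at a fixed relative scale
        z <- prof[match(meta$time_h, design$timepoints)]
        z <- z - mean(z)
        s <- stats::sd(z)
        if (is.finite(s) && s > 1e-12) z <- z / s else z <- z * 0
        z + stats::rnorm(n_s, 0, 0.35)
      }, numeric(n_s)))
    })
  }

  # per-gene, per-sample log-scale effect from modules (+ DE shift)
  eta <- matrix(rep(base, n_s), n_g, n_s,
                dimnames = list(genes, meta$sample))
  if (gene_dynamics_sd > 0) {
    # private smooth time profile per gene, identical in both conditions
    tp_idx <- match(meta$time_h, design$timepoints)
    dyn <- with_local_seed(seed_stream(design$seed, "dynamics"), {
      t(vapply(seq_len(n_g), function(g) {
        prof <- cumsum(stats::rnorm(length(design$timepoints), 0, 1))
        prof <- prof - mean(prof)
        # fixed temporal amplitude per gene keeps the per-time-point
        # expression distribution stationary across the course; a
        # single-time-point design has no dynamics
        s <- stats::sd(prof)
        prof <- if (is.finite(s) && s > 1e-12) prof / s * gene_dynamics_sd
                else prof * 0
        prof[tp_idx]
      }, numeric(n_s)))
    })
    dyn_scale <- rep(1, n_g)
    for (m in modules) {
      if (m$dynamics_scale != 1) {
        idx <- match(m$genes, genes)
        dyn_scale[idx] <- pmin(dyn_scale[idx], m$dynamics_scale)
      }
    }
    eta <- eta + dyn * dyn_scale
  }
  inoc <- meta$condition == "inoculated"
  for (i in seq_along(modules)) {
    m <- modules[[i]]
    idx <- match(m$genes, genes)
    eta[idx, ] <- eta[idx, ] + m$base_shift + outer(m$loading, latent[i, ])
    if (m$de_direction != "none") {
      sgn <- if (m$de_direction == "up") 1 else -1
      hit <- inoc & meta$time_h == m$de_timepoint
      eta[idx, hit] <- eta[idx, hit] + sgn * m$de_log2fc * log(2)
    }
  }
  mu <- sweep(exp(eta) * len_kb, 2, depth, `*`)

  counts <- with_local_seed(seed_stream(design$seed, "counts"), {
    matrix(
      stats::rnbinom(n_g * n_s, mu = as.vector(mu),
                     size = rep(1 / dispersion, n_s)),
      n_g, n_s, dimnames = dimnames(mu)
    )
  })

  truth_modules <- purrr::imap_dfr(modules, function(m, i) {
    tibble::tibble(module = sprintf("P%02d", i), gene = m$genes)
  })
  truth_de <- purrr::imap_dfr(modules, function(m, i) {
    if (m$de_direction == "none") return(tibble::tibble())
    tibble::tibble(
      gene = m$genes, time_h = m$de_timepoint,
      direction = m$de_direction,
      log2fc = ifelse(m$de_direction == "up", 1, -1) * m$de_log2fc
    )
  })

  structure(
    list(
      counts = counts,
      sample_meta = meta,
      mu = mu,
      gene_length_bp = design$gene_length_bp,
      truth = list(modules = truth_modules, de = truth_de, latent = latent),
      seed = design$seed
    ),
    class = "nodnet_sim"
  )
}

#' Convert counts to FPKM
#'
#' `fpkm = counts * 1e9 / (gene_length_bp * total_fragments)`, i.e. fragments
#' per kilobase of gene per million read pairs.
#'
#' @param counts Genes x samples non-negative matrix.
#' @param gene_length_bp Per-gene lengths in bp (> 0).
#' @param total_fragments Per-sample total fragment counts (> 0); defaults to
#'   the column sums of `counts`.
#' @return Matrix of FPKM values with the same dimnames as `counts`.
#' @export
counts_to_fpkm <- function(counts, gene_length_bp,
                           total_fragments = colSums(counts)) {
  counts <- as.matrix(counts)
  gene_length_bp <- rep_len(gene_length_bp, nrow(counts))
  total_fragments <- rep_len(total_fragments, ncol(counts))
  if (any(gene_length_bp <= 0)) stop("gene lengths must be positive")
  if (any(total_fragments <= 0)) stop("total fragments must be positive")
  sweep(counts / gene_length_bp, 2, total_fragments, `/`) * 1e9
}

#' @export
print.nodnet_sim <- function(x, ...) {
  cat(sprintf(
    "<nodnet_sim> %d genes x %d samples; %d planted module(s); seed %d\n",
    nrow(x$counts), ncol(x$counts),
    length(unique(x$truth$modules$module)), x$seed
  ))
  invisible(x)
}

# hierarchical seed stream: one global seed, one independent substream per
# stage, all below 2^31
seed_stream <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 2654435761) %% 1e9
  as.integer((as.numeric(seed) * 48271 + h) %% .Machine$integer.max)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
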