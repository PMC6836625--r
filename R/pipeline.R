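# Pipeline orchestration: counts -> FPKM -> preprocessing -> differential
# expression -> condition-aware similarity -> RMT threshold -> network ->
# link communities -> DEG overlay -> enrichment, with one config object, a
# run directory of stage artifacts and a manifest of parameters and
# checksums.

#' Pipeline configuration
#'
#' All stage parameters with their defaults (matching the executed network
#' run: `min_obs` 20, `max_modes` 5, Pearson correlation, threshold sweep
#' step 0.001, minimum module size 3 genes, `alpha` 0.05, count filter 50,
#' KS D threshold 0.15). Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A `nodnet_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    min_total = 50,       # per-comparison count filter
    alpha = 0.05,         # DEG significance on BH-adjusted p
    ks_dval = 0.15,       # outlier flagging threshold on mean pairwise KS D
    drop_outliers = FALSE,
    min_obs = 20,         # minimum samples per correlation cluster
    max_modes = 5,        # GMM components tried per gene pair
    method = "pearson",
    th_start = 0.990, th_step = 0.001, th_floor = 0.500,
    rmt_min_size = 50,    # minimum matrix size in the threshold sweep
    n_bins = 60, s_max = 3.0,
    min_module_genes = 3,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "nodnet_config")
}

stage_log <- function(stage, what, ...) {
  message(sprintf("[%s] %s", stage, sprintf(what, ...)))
}

#' Run the full pipeline
#'
#' Executes every stage in order on a count matrix, writing each stage's
#' artifact as TSV into `out_dir` plus a `manifest.json` with the parameter
#' echo, stage list and per-file md5 checksums. Re-running with identical
#' inputs and config reproduces identical checksums.
#'
#' @param counts Genes x samples count matrix.
#' @param meta Sample metadata (`sample`, `condition`, `time_h`,
#'   `replicate`).
#' @param gene_length_bp Per-gene lengths for the FPKM conversion; if
#'   `NULL`, a constant 1 kb is used (FPKM then equals CPM).
#' @param annotations Optional annotation tibble ([load_annotations()]) for
#'   the enrichment stage.
#' @param config A [run_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every stage result (`gem`, `outliers`,
#'   `de`, `edges`, `threshold`, `network`, `modules`, `calls`,
#'   `pure_tables`, `census`, `enrichment`, `manifest`).
#' @export
run_all <- function(counts, meta, gene_length_bp = NULL, annotations = NULL,
                    config = run_config(), out_dir) {
  stopifnot(inherits(config, "nodnet_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- as.matrix(counts)
  meta <- tibble::as_tibble(meta)
  stages <- character()
  run_stage <- function(name, expr) {
    stage_log(name, "start")
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    out
  }

  if (is.null(gene_length_bp)) gene_length_bp <- rep(1000, nrow(counts))

  fpkm <- run_stage("fpkm", counts_to_fpkm(counts, gene_length_bp))
  write_gem_tsv(fpkm, file.path(out_dir, "fpkm.tsv"))

  gem <- run_stage("preprocess", {
    g <- expression_matrix(fpkm, meta, state = "fpkm")
    g <- log2_transform(g)
    rep <- ks_outlier_scan(g, dval_threshold = config$ks_dval)
    flagged <- attr(rep, "flagged")
    if (length(flagged) > 0) {
      warning("outlier sample(s) flagged: ", paste(flagged, collapse = ", "))
      if (config$drop_outliers) {
        keep <- setdiff(colnames(g$values), flagged)
        g <- expression_matrix(g$values[, keep, drop = FALSE],
                               meta[meta$sample %in% keep, ], state = "log2")
      }
    }
    readr::write_tsv(tibble::as_tibble(rep),
                     file.path(out_dir, "outlier_report.tsv"))
    g <- quantile_normalize(g)
    write_gem_tsv(g, file.path(out_dir, "gem_normalized.tsv"))
    stage_log("preprocess", "%d genes x %d samples, %d flagged",
              nrow(g$values), ncol(g$values), length(flagged))
    g
  })

  de <- run_stage("diffexpr", {
    d <- run_de(counts, meta, alpha = config$alpha,
                min_total = config$min_total)
    readr::write_tsv(d, file.path(out_dir, "de_results.tsv"))
    sets <- deg_sets(d)
    readr::write_tsv(sets$unique_counts,
                     file.path(out_dir, "deg_unique_counts.tsv"))
    stage_log("diffexpr", "%d DEGs over %d time points",
              dplyr::n_distinct(d$gene[d$significant]),
              dplyr::n_distinct(d$time_h))
    d
  })

  edges <- run_stage("similarity", {
    e <- all_pairs_similarity(gem, max_modes = config$max_modes,
                              min_obs = config$min_obs,
                              method = config$method)
    write_edges_tsv(e, file.path(out_dir, "edge_candidates.tsv"))
    stage_log("similarity", "%d edge records (%d pairs skipped)",
              nrow(e), attr(e, "n_skipped"))
    e
  })

  th <- run_stage("threshold", {
    t <- find_threshold(edges, start = config$th_start,
                        step = config$th_step, floor = config$th_floor,
                        n_bins = config$n_bins, s_max = config$s_max,
                        min_size = config$rmt_min_size)
    readr::write_tsv(t$trace, file.path(out_dir, "threshold_trace.tsv"))
    stage_log("threshold", "selected %.6f", t$threshold)
    t
  })

  network <- run_stage("extract", {
    n <- extract_network(edges, th$threshold)
    readr::write_tsv(n$edges, file.path(out_dir, "network_edges.tsv"))
    stage_log("extract", "%d nodes, %d edges",
              length(n$nodes), nrow(n$pairs))
    n
  })

  modules <- run_stage("modules", {
    m <- link_communities(network, min_genes = config$min_module_genes)
    readr::write_tsv(m$membership, file.path(out_dir, "module_membership.tsv"))
    readr::write_tsv(m$summary, file.path(out_dir, "module_summary.tsv"))
    stage_log("modules", "%d modules, partition density %.3f",
              nrow(m$summary), m$density)
    m
  })

  ov <- run_stage("overlay", {
    calls <- classify_modules(modules, de)
    tabs <- pure_module_tables(calls, modules, de)
    census <- deg_in_module_census(modules, de)
    readr::write_tsv(calls, file.path(out_dir, "module_calls.tsv"))
    readr::write_tsv(tabs$tables, file.path(out_dir, "pure_module_tables.tsv"))
    jsonlite::write_json(
      list(per_group = tabs$summary, n_pure_modules = tabs$n_pure_modules,
           degs_in_modules = census),
      file.path(out_dir, "overlay_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
    stage_log("overlay", "%d pure modules, %d DEGs in modules",
              tabs$n_pure_modules, census)
    list(calls = calls, pure_tables = tabs, census = census)
  })

  enr <- run_stage("enrichment", {
    if (is.null(annotations) || nrow(modules$membership) == 0) {
      stage_log("enrichment", "skipped (no annotations or no modules)")
      NULL
    } else {
      e <- enrich_modules(modules, rownames(gem$values), annotations)
      readr::write_tsv(e, file.path(out_dir, "enrichment.tsv"))
      e
    }
  })

  files <- list.files(out_dir, full.names = TRUE, pattern = "\\.(tsv|json)$")
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("nodnet")),
    stages = stages,
    config = unclass(config),
    checksums = as.list(tools::md5sum(sort(files)))
  )
  names(manifest$checksums) <- basename(sort(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    gem = gem, de = de, edges = edges, threshold = th, network = network,
    modules = modules, calls = ov$calls, pure_tables = ov$pure_tables,
    census = ov$census, enrichment = enr, manifest = manifest
  ))
}
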