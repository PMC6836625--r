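# Condition-aware pairwise similarity: for each gene pair, cluster the
# samples in the 2-D expression plane with bivariate Gaussian mixture models
# (model selected by ICL), then compute the correlation within each
# sufficiently large sample cluster. Edges therefore carry a sample
# composition mask and can be specific to a subset of samples (a condition,
# a time window) rather than the whole experiment.

#' Cluster the samples of one gene pair with Gaussian mixtures
#'
#' Fits full-covariance bivariate Gaussian mixtures with `K = 1..max_modes`
#' components to the complete observations of the pair and selects `K` by
#' the integrated completed likelihood
#' `ICL = -2 loglik + df * log(n) + 2 * H`, where `H` is the total MAP
#' assignment entropy; the lowest ICL wins. Samples missing either gene are
#' labeled missing. Fitting uses mclust (model `"VVV"`), whose model-based
#' hierarchical initialization is deterministic.
#'
#' @param x,y Expression vectors of the two genes (same length; `NA` =
#'   missing).
#' @param max_modes Largest number of mixture components tried (default 5).
#' @param min_obs Minimum number of complete pairs; below it the pair is
#'   skipped (recorded, not an error). Default 20.
#' @return A `nodnet_pair_clustering` list: `labels` (per-sample integer or
#'   `NA`), `K`, `icl` (tibble of candidate K and ICL), `skipped`, and the
#'   input vectors.
#' @export
pair_gmm <- function(x, y, max_modes = 5, min_obs = 20) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (any(is.infinite(x)) || any(is.nan(x)) ||
      any(is.infinite(y)) || any(is.nan(y))) {
    stop("non-finite (Inf/NaN) expression values")
  }
  complete <- !is.na(x) & !is.na(y)
  labels <- rep(NA_integer_, length(x))
  base <- structure(
    list(labels = labels, K = NA_integer_,
         icl = tibble::tibble(K = integer(), icl = numeric()),
         skipped = TRUE, x = x, y = y, n_complete = sum(complete)),
    class = "nodnet_pair_clustering"
  )
  if (sum(complete) < min_obs) return(base)

  dat <- cbind(x[complete], y[complete])
  n <- nrow(dat)
  fits <- purrr::map(seq_len(max_modes), function(k) {
    # conjugate prior regularizes covariances: without it, spiky
    # components over 2-3 points win spurious extra modes at n ~ 30
    f <- tryCatch(
      suppressWarnings(mclust::Mclust(dat, G = k, modelNames = "VVV",
                                      verbose = FALSE,
                                      prior = mclust::priorControl())),
      error = function(e) NULL
    )
    if (is.null(f) || !is.finite(f$loglik)) return(NULL)
    entropy <- if (k == 1) 0 else {
      z <- pmax(f$z, 1e-300)
      -sum(f$z * log(z))
    }
    list(K = k, fit = f,
         icl = -2 * f$loglik + f$df * log(n) + 2 * entropy)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) {
    # degenerate geometry (e.g. exactly collinear data): one cluster
    base$labels[complete] <- 1L
    base$K <- 1L
    base$skipped <- FALSE
    return(base)
  }
  icl_tab <- tibble::tibble(
    K = purrr::map_int(fits, "K"),
    icl = purrr::map_dbl(fits, "icl")
  )
  best <- fits[[which.min(icl_tab$icl)]]
  labels[complete] <- as.integer(mclust::map(best$fit$z))
  structure(
    list(labels = labels, K = best$K, icl = icl_tab, skipped = FALSE,
         x = x, y = y, n_complete = n),
    class = "nodnet_pair_clustering"
  )
}

#' Per-cluster correlations for a clustered gene pair
#'
#' One edge record is emitted per sample cluster with at least `min_obs`
#' members: the correlation of the pair within the cluster plus a sample
#' composition mask (`'1'` in-cluster, `'0'` out-of-cluster, `'9'` missing,
#' one character per input sample). Zero-variance clusters are dropped with
#' a warning.
#'
#' @param pc A [pair_gmm()] result.
#' @param gene_i,gene_j Gene ids for the output records.
#' @param min_obs Minimum cluster size (default 20).
#' @param method `"pearson"` (default, matching the executed network run) or
#'   `"spearman"`.
#' @return Tibble: `gene_i`, `gene_j`, `cluster`, `n`, `r`, `sample_mask`.
#' @export
cluster_correlations <- function(pc, gene_i = "g1", gene_j = "g2",
                                 min_obs = 20,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(pc, "nodnet_pair_clustering"))
  empty <- tibble::tibble(
    gene_i = character(), gene_j = character(), cluster = integer(),
    n = integer(), r = numeric(), sample_mask = character()
  )
  if (pc$skipped || is.na(pc$K)) return(empty)
  missing <- is.na(pc$labels)
  out <- purrr::map_dfr(sort(unique(pc$labels[!missing])), function(k) {
    ink <- !missing & pc$labels == k
    if (sum(ink) < min_obs) return(empty)
    xi <- pc$x[ink]
    yi <- pc$y[ink]
    if (stats::sd(xi) == 0 || stats::sd(yi) == 0) {
      warning(sprintf("zero-variance cluster %d for pair (%s, %s) dropped",
                      k, gene_i, gene_j))
      return(empty)
    }
    mask <- rep("0", length(pc$labels))
    mask[missing] <- "9"
    mask[ink] <- "1"
    tibble::tibble(
      gene_i = gene_i, gene_j = gene_j, cluster = as.integer(k),
      n = sum(ink), r = stats::cor(xi, yi, method = method),
      sample_mask = paste(mask, collapse = "")
    )
  })
  if (nrow(out) == 0) empty else out
}

#' Condition-aware similarity over all gene pairs
#'
#' Enumerates gene pairs `i < j` (row order of the matrix), clusters each
#' pair's samples with [pair_gmm()] and emits per-cluster correlation edge
#' records via [cluster_correlations()]. Pairs with fewer than `min_obs`
#' complete observations are skipped and counted.
#'
#' @param gem A `nodnet_gem` in state `"quantile_normalized"` (or `"log2"`).
#' @param max_modes,min_obs,method See [pair_gmm()] and
#'   [cluster_correlations()].
#' @return A tibble of edge records (class `nodnet_edges`) sorted by
#'   `(gene_i, gene_j, cluster)`, with attributes `samples` and
#'   `n_skipped`.
#' @export
all_pairs_similarity <- function(gem, max_modes = 5, min_obs = 20,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_state(gem, c("log2", "quantile_normalized"))
  v <- gem$values
  genes <- rownames(v)
  n_g <- length(genes)
  skipped <- 0L
  chunks <- vector("list", n_g * (n_g - 1) / 2)
  idx <- 0L
  for (i in seq_len(max(n_g - 1, 0))) {
    xi <- v[i, ]
    for (j in (i + 1):n_g) {
      idx <- idx + 1L
      pc <- pair_gmm(xi, v[j, ], max_modes = max_modes, min_obs = min_obs)
      if (pc$skipped) {
        skipped <- skipped + 1L
        next
      }
      rec <- cluster_correlations(pc, genes[i], genes[j],
                                  min_obs = min_obs, method = method)
      if (nrow(rec) > 0) chunks[[idx]] <- rec
    }
  }
  out <- dplyr::bind_rows(purrr::compact(chunks))
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      gene_i = character(), gene_j = character(), cluster = integer(),
      n = integer(), r = numeric(), sample_mask = character()
    )
  }
  out <- dplyr::arrange(out, .data$gene_i, .data$gene_j, .data$cluster)
  attr(out, "samples") <- colnames(v)
  attr(out, "n_skipped") <- skipped
  class(out) <- c("nodnet_edges", class(out))
  out
}

#' Write / read an edge-candidate table as TSV
#'
#' @param edges Edge tibble from [all_pairs_similarity()].
#' @param path File path.
#' @return The path (write) or the edge tibble (read).
#' @export
write_edges_tsv <- function(edges, path) {
  readr::write_tsv(edges, path)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_i = readr::col_character(),
                           gene_j = readr::col_character(),
                           cluster = readr::col_integer(),
                           n = readr::col_integer(),
                           r = readr::col_double(),
                           sample_mask = readr::col_character()
                         ))
  class(out) <- c("nodnet_edges", class(out))
  out
}
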