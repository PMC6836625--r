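# Random-matrix-theory threshold selection. The significance cutoff for
# co-expression edges is the highest correlation at which the thresholded
# similarity matrix's eigenvalue nearest-neighbor spacing distribution
# (NNSD) still follows Poisson statistics (modular signal); below it the
# NNSD transitions to the Wigner-Dyson law of the Gaussian orthogonal
# ensemble (noise).

#' Pairwise similarity matrix at a cutoff
#'
#' Builds the symmetric matrix whose (i, j) entry is the maximum `|r|` over
#' that pair's cluster-specific edge records when it reaches `threshold`,
#' zero otherwise; diagonal 1. Genes without any retained pair are pruned.
#'
#' @param edges Edge-record tibble (`gene_i`, `gene_j`, `cluster`, `r`).
#' @param threshold Correlation cutoff in `(0, 1]`.
#' @return Symmetric numeric matrix over the retained genes.
#' @export
similarity_matrix <- function(edges, threshold) {
  best <- pair_best(edges)
  best_matrix(best, threshold)
}

# one row per gene pair with its maximum |r| over clusters
pair_best <- function(edges) {
  tibble::as_tibble(edges) |>
    dplyr::group_by(.data$gene_i, .data$gene_j) |>
    dplyr::summarise(r = max(abs(.data$r)), .groups = "drop")
}

best_matrix <- function(best, threshold) {
  best <- best[best$r >= threshold, ]
  genes <- sort(unique(c(best$gene_i, best$gene_j)))
  m <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  if (nrow(best) > 0) {
    ii <- match(best$gene_i, genes)
    jj <- match(best$gene_j, genes)
    m[cbind(ii, jj)] <- best$r
    m[cbind(jj, ii)] <- best$r
  }
  diag(m) <- 1
  m
}

#' Unfold an eigenvalue spectrum and compute nearest-neighbor spacings
#'
#' Near-duplicate eigenvalues (within `dedup_tol`) are collapsed, a cubic
#' smoothing spline of modest flexibility (`df` effective degrees of
#' freedom; enough to follow the global spectral density but not the local
#' level fluctuations that are the signal under test) is fitted to the
#' cumulative spectral function (eigenvalue rank vs value), and the
#' unfolded spacings are the successive differences of the fitted
#' cumulative counts. By construction the mean unfolded spacing is ~1.
#'
#' @param eigenvalues Numeric vector (>= 50 after deduplication).
#' @param dedup_tol Collapse tolerance for duplicate eigenvalues.
#' @param df Effective degrees of freedom of the unfolding spline
#'   (default 10).
#' @return Non-negative spacings vector (length `n - 1`).
#' @export
unfold_spacings <- function(eigenvalues, dedup_tol = 1e-6, df = 10) {
  ev <- sort(eigenvalues[is.finite(eigenvalues)])
  if (length(ev) > 1) {
    keep <- c(TRUE, diff(ev) > dedup_tol)
    ev <- ev[keep]
  }
  n <- length(ev)
  if (n < 50) {
    stop("fewer than 50 distinct eigenvalues after deduplication")
  }
  fit <- stats::smooth.spline(ev, seq_len(n), df = min(df, n - 1))
  cum <- stats::predict(fit, ev)$y
  s <- pmax(diff(cum), 0)
  s
}

#' Chi-square statistic of spacings against the Poisson (exponential) law
#'
#' Bins the spacings on `[0, s_max]` into `n_bins` equal-width bins and
#' compares observed counts with those expected under the unit-mean
#' exponential density `exp(-s)` (the NNSD of uncorrelated eigenvalues).
#'
#' @param spacings Unfolded spacing vector.
#' @param n_bins Number of histogram bins (default 60).
#' @param s_max Upper edge of the binned range (default 3).
#' @return The chi-square statistic (df is `n_bins - 1`).
#' @export
chi2_vs_poisson <- function(spacings, n_bins = 60, s_max = 3.0) {
  spacings <- spacings[is.finite(spacings)]
  if (length(spacings) == 0) stop("empty spacings vector")
  if (length(spacings) < 100) {
    warning("fewer than 100 spacings; chi-square statistic is noisy")
  }
  breaks <- seq(0, s_max, length.out = n_bins + 1)
  obs <- as.vector(table(cut(spacings, breaks, include.lowest = TRUE)))
  expd <- length(spacings) * (exp(-breaks[-length(breaks)]) - exp(-breaks[-1]))
  sum((obs - expd)^2 / expd)
}

#' Find the RMT significance threshold
#'
#' Sweeps correlation cutoffs downward from `start` by `step` to `floor`.
#' At each cutoff the thresholded similarity matrix is built, its
#' eigenvalue NNSD computed ([unfold_spacings()]) and tested against the
#' exponential law ([chi2_vs_poisson()]). The selected threshold is the
#' bottom edge of the Poisson-like regime: the lowest Poisson-like cutoff
#' such that at least `poisson_frac` of the `window` evaluated cutoffs at
#' and above it are Poisson-like. The binary chi-square decision flickers
#' near the transition (in both directions), so a windowed-majority edge
#' is used rather than stopping at the first excursion above the critical
#' value. Cutoffs whose pruned matrix has fewer than `min_size` genes are
#' recorded and passed over.
#'
#' The number of histogram bins adapts to the spacing count (about five
#' expected counts per bin, capped at `n_bins`) so the chi-square
#' approximation stays valid on small spectra; the critical value is the
#' chi-square quantile at `alpha = 0.001` with the matching degrees of
#' freedom.
#'
#' @param edges Edge-record tibble.
#' @param start,step,floor Sweep bounds (defaults 0.990, 0.001, 0.500).
#' @param n_bins,s_max Histogram cap and range for [chi2_vs_poisson()].
#' @param chi2_critical Decision boundary; overrides the adaptive
#'   per-cutoff quantile when supplied.
#' @param min_size Minimum matrix size to evaluate a cutoff (default 50).
#' @param poisson_frac Minimum fraction of Poisson-like decisions in the
#'   trailing window for a cutoff to count as inside the regime
#'   (default 0.9).
#' @param window Number of evaluated cutoffs (at and above the candidate)
#'   over which the fraction is taken (default 10).
#' @return A `nodnet_threshold` object: `threshold` (selected cutoff) and
#'   `trace` (tibble of every cutoff tried: `cutoff`, `n_genes`, `chi2`,
#'   `decision`).
#' @export
find_threshold <- function(edges, start = 0.990, step = 0.001, floor = 0.500,
                           n_bins = 60, s_max = 3.0, chi2_critical = NULL,
                           min_size = 50, poisson_frac = 0.9, window = 10) {
  cutoffs <- seq(start, floor, by = -step)
  best <- pair_best(edges)
  trace <- vector("list", length(cutoffs))
  for (k in seq_along(cutoffs)) {
    cutoff <- cutoffs[k]
    m <- best_matrix(best, cutoff)
    n_genes <- nrow(m)
    if (n_genes < min_size) {
      trace[[k]] <- tibble::tibble(cutoff = cutoff, n_genes = n_genes,
                                   chi2 = NA_real_, decision = "too-small")
      next
    }
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    res <- tryCatch({
      s <- unfold_spacings(ev)
      nb <- max(8, min(n_bins, floor(length(s) / 5)))
      list(chi2 = suppressWarnings(
             chi2_vs_poisson(s, n_bins = nb, s_max = s_max)),
           crit = chi2_critical %||% stats::qchisq(1 - 0.001, df = nb - 1))
    }, error = function(e) NULL)
    if (is.null(res)) {
      trace[[k]] <- tibble::tibble(cutoff = cutoff, n_genes = n_genes,
                                   chi2 = NA_real_, decision = "too-small")
      next
    }
    decision <- if (res$chi2 < res$crit) "poisson-like" else "goe-like"
    trace[[k]] <- tibble::tibble(cutoff = cutoff, n_genes = n_genes,
                                 chi2 = res$chi2, decision = decision)
  }
  trace <- dplyr::bind_rows(purrr::compact(trace))
  evaluated <- trace[trace$decision != "too-small", ]
  if (nrow(evaluated) == 0) {
    stop("insufficient network density: similarity matrix never reached ",
         min_size, " genes in the sweep")
  }
  # bottom edge of the Poisson regime: lowest poisson-like cutoff whose
  # trailing window (evaluated cutoffs at and above it) is mostly poisson
  is_p <- evaluated$decision == "poisson-like"
  frac <- vapply(seq_along(is_p), function(i) {
    mean(is_p[max(1, i - window + 1):i])
  }, numeric(1))
  ok <- which(is_p & frac >= poisson_frac)
  if (length(ok) == 0) {
    stop("no Poisson-like regime found in the threshold sweep")
  }
  threshold <- evaluated$cutoff[max(ok)]
  structure(
    list(threshold = threshold, trace = trace,
         chi2_critical = chi2_critical %||%
           stats::qchisq(1 - 0.001, df = n_bins - 1),
         params = list(start = start, step = step, floor = floor,
                       n_bins = n_bins, s_max = s_max, min_size = min_size,
                       poisson_frac = poisson_frac, window = window)),
    class = "nodnet_threshold"
  )
}

#' @export
print.nodnet_threshold <- function(x, ...) {
  cat(sprintf(
    "<nodnet_threshold> selected %.6f (%d cutoffs tried, chi2 critical %.1f)\n",
    x$threshold, nrow(x$trace), x$chi2_critical
  ))
  invisible(x)
}

#' Extract the co-expression network at a threshold
#'
#' Retains every cluster-specific edge record with `|r| >= threshold`; the
#' node set is the genes incident to a retained record.
#'
#' @param edges Edge-record tibble.
#' @param threshold Correlation cutoff in `(0, 1]`.
#' @return A `nodnet_network` list: `nodes` (character), `edges` (the
#'   retained records), `pairs` (deduplicated gene pairs).
#' @export
extract_network <- function(edges, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  edges <- tibble::as_tibble(edges)
  keep <- edges[abs(edges$r) >= threshold & edges$gene_i != edges$gene_j, ]
  pairs <- dplyr::distinct(keep, .data$gene_i, .data$gene_j)
  structure(
    list(
      nodes = sort(unique(c(keep$gene_i, keep$gene_j))),
      edges = keep,
      pairs = pairs,
      threshold = threshold
    ),
    class = "nodnet_network"
  )
}

#' @export
print.nodnet_network <- function(x, ...) {
  cat(sprintf("<nodnet_network> %d nodes, %d edges (threshold %.4f)\n",
              length(x$nodes), nrow(x$pairs), x$threshold))
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$pairs, directed = FALSE,
                                vertices = network$nodes)
}

#' Scale-free topology fit of the degree distribution
#'
#' Bins node degrees by value and fits `log10(frequency) ~ log10(degree)`
#' by least squares; a high R-squared indicates power-law (scale-free)
#' degree structure.
#'
#' @param network A `nodnet_network` (>= 10 nodes).
#' @return R-squared of the log-log fit (`NA` with a warning when all
#'   degrees are equal); attribute `n_distinct_degrees` flags underpowered
#'   fits (< 3 distinct degrees).
#' @export
scale_free_fit <- function(network) {
  g <- as_igraph(network)
  deg <- igraph::degree(g)
  deg <- deg[deg > 0]
  if (length(igraph::V(g)) < 10) stop("need at least 10 nodes")
  tab <- table(deg)
  if (length(tab) < 2) {
    warning("all degrees equal; scale-free fit undefined")
    return(NA_real_)
  }
  k <- as.numeric(names(tab))
  f <- as.numeric(tab)
  fit <- stats::lm(log10(f) ~ log10(k))
  r2 <- summary(fit)$r.squared
  attr(r2, "n_distinct_degrees") <- length(tab)
  if (length(tab) < 3) {
    warning("fewer than 3 distinct degrees; fit is underpowered")
  }
  r2
}
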