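# Gene expression matrix (GEM) assembly and preprocessing: log2 transform,
# pairwise Kolmogorov-Smirnov outlier screen, quantile normalization.

GEM_STATES <- c("counts", "fpkm", "log2", "quantile_normalized")

#' Construct a gene expression matrix object
#'
#' Wraps a genes x samples numeric matrix with its processing state and
#' per-sample metadata. States move forward only:
#' `counts`/`fpkm -> log2 -> quantile_normalized`.
#'
#' @param values Numeric matrix (genes in rows, samples in columns) with
#'   unique dimnames; `NA` marks missing values.
#' @param sample_meta Data frame with columns `sample`, `condition`,
#'   `time_h`, `replicate`; rows are matched to the matrix columns by
#'   `sample`.
#' @param state One of `"counts"`, `"fpkm"`, `"log2"`,
#'   `"quantile_normalized"`.
#' @return A `nodnet_gem` object.
#' @export
expression_matrix <- function(values, sample_meta, state = "fpkm") {
  state <- match.arg(state, GEM_STATES)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  sample_meta <- tibble::as_tibble(sample_meta)
  need <- c("sample", "condition", "time_h", "replicate")
  if (!all(need %in% names(sample_meta))) {
    stop("sample_meta needs columns: ", paste(need, collapse = ", "))
  }
  if (!setequal(sample_meta$sample, colnames(values))) {
    stop("sample_meta$sample must match the matrix columns")
  }
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), ]
  structure(
    list(values = values, state = state, sample_meta = sample_meta),
    class = "nodnet_gem"
  )
}

#' @export
print.nodnet_gem <- function(x, ...) {
  cat(sprintf("<nodnet_gem> %d genes x %d samples [%s]; %d missing values\n",
              nrow(x$values), ncol(x$values), x$state, sum(is.na(x$values))))
  invisible(x)
}

assert_state <- function(gem, state) {
  stopifnot(inherits(gem, "nodnet_gem"))
  if (!gem$state %in% state) {
    stop(sprintf("expected GEM in state %s, got '%s'",
                 paste(sQuote(state), collapse = "/"), gem$state))
  }
}

#' Log2-transform an FPKM matrix
#'
#' Positive values become `log2(x)`; zeros become missing (`NA`) rather than
#' `-Inf` or a pseudo-counted value, so the missingness mask propagates to
#' the mixture-model clustering downstream.
#'
#' @param gem A `nodnet_gem` in state `"fpkm"`.
#' @return A `nodnet_gem` in state `"log2"`.
#' @export
log2_transform <- function(gem) {
  assert_state(gem, "fpkm")
  v <- gem$values
  if (any(v < 0, na.rm = TRUE)) stop("negative values cannot be log2 transformed")
  v[!is.na(v) & v == 0] <- NA
  v[!is.na(v)] <- log2(v[!is.na(v)])
  gem$values <- v
  gem$state <- "log2"
  gem
}

#' Screen samples for outliers with pairwise KS statistics
#'
#' Computes the two-sample Kolmogorov-Smirnov D statistic between every
#' pair of sample columns (on non-missing values) and flags a sample when
#' the mean of its pairwise D values exceeds `dval_threshold`.
#'
#' @param gem A `nodnet_gem` in state `"log2"`.
#' @param dval_threshold Flagging threshold on a sample's mean pairwise D
#'   (default 0.15).
#' @return A tibble (one row per sample: `sample`, `mean_D`, `max_D`,
#'   `flagged`) with attributes `flagged` (sample ids) and `threshold`.
#' @export
ks_outlier_scan <- function(gem, dval_threshold = 0.15) {
  assert_state(gem, c("log2", "quantile_normalized"))
  v <- gem$values
  if (ncol(v) < 2) stop("need at least 2 samples")
  n_ok <- colSums(!is.na(v))
  if (any(n_ok < 10)) {
    stop("samples with fewer than 10 non-missing values: ",
         paste(colnames(v)[n_ok < 10], collapse = ", "))
  }
  n <- ncol(v)
  D <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(n - 1)) {
    xi <- v[, i][!is.na(v[, i])]
    for (j in (i + 1):n) {
      xj <- v[, j][!is.na(v[, j])]
      D[i, j] <- D[j, i] <- ks_statistic(xi, xj)
    }
  }
  mean_D <- rowSums(D) / (n - 1)
  max_D <- apply(D, 1, max)
  report <- tibble::tibble(
    sample = colnames(v),
    mean_D = unname(mean_D),
    max_D = unname(max_D),
    flagged = unname(mean_D > dval_threshold)
  )
  attr(report, "flagged") <- report$sample[report$flagged]
  attr(report, "threshold") <- dval_threshold
  attr(report, "D_matrix") <- D
  class(report) <- c("nodnet_outlier_report", class(report))
  report
}

# two-sample KS D via the empirical CDFs (ties handled exactly)
ks_statistic <- function(x, y) {
  z <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(z)
  Fy <- stats::ecdf(y)(z)
  max(abs(Fx - Fy))
}

#' Quantile-normalize a log2 expression matrix
#'
#' Forces every sample column onto the common reference distribution (the
#' row means of the column-sorted matrix). Ties receive the mean of the
#' reference values at their tied ranks; missing cells stay missing, with
#' each column's non-missing quantiles mapped through interpolation.
#' Delegates to [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param gem A `nodnet_gem` in state `"log2"`.
#' @return A `nodnet_gem` in state `"quantile_normalized"`.
#' @export
quantile_normalize <- function(gem) {
  assert_state(gem, "log2")
  v <- gem$values
  if (any(colSums(!is.na(v)) == 0)) stop("all-missing sample column")
  out <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(out) <- dimnames(v)
  gem$values <- out
  gem$state <- "quantile_normalized"
  gem
}

#' Read / write a GEM as TSV
#'
#' Tab-separated, gene ids in the first column (`gene`), one column per
#' sample.
#'
#' @param path File path.
#' @param gem,values A `nodnet_gem` (written) or matrix.
#' @param sample_meta Sample metadata for [expression_matrix()] on read.
#' @param state Processing state to attach on read.
#' @return `read_gem_tsv()` returns a `nodnet_gem`; `write_gem_tsv()`
#'   returns `path` invisibly.
#' @export
read_gem_tsv <- function(path, sample_meta, state = "fpkm") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  expression_matrix(m, sample_meta, state = state)
}

#' @rdname read_gem_tsv
#' @export
write_gem_tsv <- function(gem, path) {
  v <- if (inherits(gem, "nodnet_gem")) gem$values else as.matrix(gem)
  df <- tibble::as_tibble(v, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname read_gem_tsv
#' @export
read_sample_meta_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample = readr::col_character(),
                    condition = readr::col_character(),
                    time_h = readr::col_double(),
                    replicate = readr::col_integer()
                  ))
}
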