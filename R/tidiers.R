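# broom-style tidiers for fitted pipeline objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy / glance methods for pipeline results
#'
#' `tidy()` returns the per-unit table of a result (per-cutoff trace, per
#' module-gene membership, per edge record); `glance()` a one-row summary.
#'
#' @param x A `nodnet_threshold`, `nodnet_modules`, `nodnet_network` or
#'   `nodnet_de` object.
#' @param ... Unused.
#' @return A tibble.
#' @name nodnet-tidiers
NULL

#' @rdname nodnet-tidiers
#' @exportS3Method generics::tidy
tidy.nodnet_threshold <- function(x, ...) x$trace

#' @rdname nodnet-tidiers
#' @exportS3Method generics::glance
glance.nodnet_threshold <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    n_cutoffs_tried = nrow(x$trace),
    chi2_critical = x$chi2_critical
  )
}

#' @rdname nodnet-tidiers
#' @exportS3Method generics::tidy
tidy.nodnet_modules <- function(x, ...) {
  dplyr::left_join(x$membership, x$summary, by = "module")
}

#' @rdname nodnet-tidiers
#' @exportS3Method generics::glance
glance.nodnet_modules <- function(x, ...) {
  tibble::tibble(
    n_modules = nrow(x$summary),
    n_genes = dplyr::n_distinct(x$membership$gene),
    largest_module = if (nrow(x$summary) > 0) max(x$summary$n_genes) else 0L,
    partition_density = x$density
  )
}

#' @rdname nodnet-tidiers
#' @exportS3Method generics::tidy
tidy.nodnet_network <- function(x, ...) x$edges

#' @rdname nodnet-tidiers
#' @exportS3Method generics::glance
glance.nodnet_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$pairs),
    n_edge_records = nrow(x$edges),
    threshold = x$threshold
  )
}

#' @rdname nodnet-tidiers
#' @exportS3Method generics::glance
glance.nodnet_de <- function(x, ...) {
  df <- tibble::as_tibble(x)
  tibble::tibble(
    n_tests = nrow(df),
    n_genes = dplyr::n_distinct(df$gene),
    n_timepoints = dplyr::n_distinct(df$time_h),
    n_degs = dplyr::n_distinct(df$gene[df$significant]),
    alpha = attr(x, "alpha") %||% 0.05
  )
}
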