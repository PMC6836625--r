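# Overlay of per-time-point DEG sets onto link-community modules. A module
# is "pure" at a time point when every member gene is a significant DEG
# there with a uniform fold-change direction; pure modules are grouped by
# labels like 24U (up at 24 h) / 24D / 48D.

#' Group label helpers
#'
#' `group_label()` builds labels like `"24U"`/`"48D"` from a time point and
#' direction; `parse_group_label()` inverts them.
#'
#' @param time_h Time point in hours.
#' @param direction `"up"` or `"down"`.
#' @param label Label string such as `"24D"`.
#' @return A label string, or a list `(time_h, direction)`.
#' @export
group_label <- function(time_h, direction) {
  paste0(time_h, toupper(substr(direction, 1, 1)))
}

#' @rdname group_label
#' @export
parse_group_label <- function(label) {
  m <- regmatches(label, regexec("^([0-9]+)([UD])$", label))[[1]]
  if (length(m) != 3) stop("unparseable group label: ", label)
  list(time_h = as.numeric(m[2]),
       direction = if (m[3] == "U") "up" else "down")
}

#' Classify modules by DEG purity
#'
#' For every module and time point, a module is pure iff all of its member
#' genes are significant at that time point with the same fold-change sign.
#' Genes absent from the DE results (e.g. removed by the count filter)
#' count as non-significant and make a module impure.
#'
#' @param modules A `nodnet_modules` object (or its `membership` tibble).
#' @param de Differential-expression results ([run_de()] output).
#' @return Tibble: `module`, `time_h`, `direction` (`NA` unless pure),
#'   `pure`, `n_genes`, `label` (`NA` unless pure).
#' @export
classify_modules <- function(modules, de) {
  membership <- if (inherits(modules, "nodnet_modules")) modules$membership
                else tibble::as_tibble(modules)
  de <- tibble::as_tibble(de)
  tps <- sort(unique(de$time_h))
  purrr::map_dfr(unique(membership$module), function(mod) {
    genes <- membership$gene[membership$module == mod]
    purrr::map_dfr(tps, function(tp) {
      sub <- de[de$time_h == tp & de$gene %in% genes, ]
      all_sig <- nrow(sub) == length(genes) && all(sub$significant)
      uniform <- all_sig &&
        (all(sub$log2fc > 0) || all(sub$log2fc < 0))
      dir <- if (uniform) {
        if (all(sub$log2fc > 0)) "up" else "down"
      } else NA_character_
      tibble::tibble(
        module = mod, time_h = tp, direction = dir,
        pure = uniform, n_genes = length(genes),
        label = if (uniform) group_label(tp, dir) else NA_character_
      )
    })
  })
}

#' Per-group tables of pure-module genes
#'
#' For each purity group (e.g. 24U, 24D, 48D) lists the member genes of its
#' pure modules with their fold changes and adjusted p-values, sorted by
#' `|log2fc|` descending; a gene appearing in several modules of the group
#' is listed once with the module list collapsed.
#'
#' @param calls [classify_modules()] output.
#' @param modules A `nodnet_modules` object.
#' @param de Differential-expression results.
#' @return List: `tables` (tibble `group`, `gene`, `modules`, `log2fc`,
#'   `padj`), `summary` (tibble `group`, `n_genes`, `n_modules`), and
#'   `n_pure_modules` (distinct pure modules over all groups).
#' @export
pure_module_tables <- function(calls, modules, de) {
  membership <- if (inherits(modules, "nodnet_modules")) modules$membership
                else tibble::as_tibble(modules)
  de <- tibble::as_tibble(de)
  pure <- dplyr::filter(calls, .data$pure)
  if (nrow(pure) == 0) {
    return(list(
      tables = tibble::tibble(group = character(), gene = character(),
                              modules = character(), log2fc = numeric(),
                              padj = numeric()),
      summary = tibble::tibble(group = character(), n_genes = integer(),
                               n_modules = integer()),
      n_pure_modules = 0L
    ))
  }
  tables <- pure |>
    dplyr::inner_join(membership, by = "module",
                      relationship = "many-to-many") |>
    dplyr::inner_join(de, by = c("gene", "time_h")) |>
    dplyr::group_by(.data$label, .data$gene) |>
    dplyr::summarise(
      modules = paste(sort(unique(.data$module)), collapse = ","),
      log2fc = .data$log2fc[1], padj = .data$padj[1], .groups = "drop"
    ) |>
    dplyr::rename(group = "label") |>
    dplyr::arrange(.data$group, dplyr::desc(abs(.data$log2fc)))
  summary <- pure |>
    dplyr::inner_join(membership, by = "module",
                      relationship = "many-to-many") |>
    dplyr::group_by(group = .data$label) |>
    dplyr::summarise(
      n_genes = dplyr::n_distinct(.data$gene),
      n_modules = dplyr::n_distinct(.data$module), .groups = "drop"
    )
  list(tables = tables, summary = summary,
       n_pure_modules = dplyr::n_distinct(pure$module))
}

#' Census of DEGs appearing in modules
#'
#' The number of distinct genes that are both a member of at least one
#' module and significant at at least one time point.
#'
#' @param modules A `nodnet_modules` object (or membership tibble).
#' @param de Differential-expression results.
#' @return Integer count.
#' @export
deg_in_module_census <- function(modules, de) {
  membership <- if (inherits(modules, "nodnet_modules")) modules$membership
                else tibble::as_tibble(modules)
  de <- tibble::as_tibble(de)
  length(intersect(unique(membership$gene),
                   unique(de$gene[de$significant])))
}

#' Parse a collapsed module list
#'
#' Module lists in published tables abbreviate repeats: `"M0004,6"` means
#' modules M0004 and M0006; `"M0021,55,72"` means M0021, M0055 and M0072.
#' Shorthand tokens replace the trailing digits of the first full id.
#'
#' @param x Character vector of collapsed module lists.
#' @return List of character vectors of full module ids.
#' @export
parse_module_list <- function(x) {
  purrr::map(x, function(s) {
    toks <- trimws(strsplit(s, ",")[[1]])
    toks <- toks[nzchar(toks)]
    full <- toks[1]
    digits <- sub("^M", "", full)
    purrr::map_chr(toks, function(t) {
      if (grepl("^M", t)) return(t)
      d <- digits
      substr(d, nchar(d) - nchar(t) + 1, nchar(d)) <- t
      paste0("M", d)
    })
  })
}

#' Read a pure-module group table
#'
#' Reads the worked-example TSV shipped with the package (columns `group`,
#' `gene`, `description`, `modules`, `log2fc`, `padj`), expanding collapsed
#' module lists via [parse_module_list()].
#'
#' @param path TSV path; defaults to the packaged nodulation example
#'   (pure 24U/24D/48D modules from a Medicago truncatula inoculation time
#'   course).
#' @return Tibble with a `module_ids` list-column of full module ids.
#' @export
read_module_groups <- function(path = system.file(
                                 "extdata", "nodulation_pure_module_groups.tsv",
                                 package = "nodnet")) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  df$module_ids <- parse_module_list(df$modules)
  tibble::as_tibble(df)
}

#' Summarise a pure-module group table
#'
#' Distinct gene and module counts per group, plus the overall distinct
#' module count.
#'
#' @param groups Output of [read_module_groups()].
#' @return List: `per_group` tibble (`group`, `n_genes`, `n_modules`),
#'   `n_modules_total`, `n_genes_total`.
#' @export
module_group_summary <- function(groups) {
  per_group <- groups |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_genes = dplyr::n_distinct(.data$gene),
      n_modules = dplyr::n_distinct(unlist(.data$module_ids)),
      .groups = "drop"
    )
  list(
    per_group = per_group,
    n_modules_total = dplyr::n_distinct(unlist(groups$module_ids)),
    n_genes_total = dplyr::n_distinct(groups$gene)
  )
}
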