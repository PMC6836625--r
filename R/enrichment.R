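# Functional enrichment of module gene sets: one-sided Fisher's exact
# (hypergeometric over-representation) test per term, DAVID-style, across
# multiple annotation vocabularies (GO, KEGG, Pfam, InterPro, ...).

#' Load a gene-to-term annotation table
#'
#' Reads a headerless TSV with columns gene, vocabulary, term and an
#' optional fourth term-name column. Duplicate (gene, vocabulary, term)
#' rows are collapsed; malformed lines (< 3 fields) are skipped with a
#' warning and counted.
#'
#' @param path Annotation TSV path.
#' @return Tibble (`gene`, `vocabulary`, `term`, `name`) with attribute
#'   `n_skipped`.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 3
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warning(sprintf("skipped %d malformed annotation line(s)", n_skipped))
  }
  if (!any(ok)) {
    out <- tibble::tibble(gene = character(), vocabulary = character(),
                          term = character(), name = character())
    if (length(lines) == 0) warning("empty annotation file")
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  recs <- fields[ok]
  out <- tibble::tibble(
    gene = purrr::map_chr(recs, 1),
    vocabulary = purrr::map_chr(recs, 2),
    term = purrr::map_chr(recs, 3),
    name = purrr::map_chr(recs, ~ if (length(.x) >= 4) .x[[4]] else NA_character_)
  )
  out <- dplyr::distinct(out, .data$gene, .data$vocabulary, .data$term,
                         .keep_all = TRUE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Fisher's exact functional enrichment of a gene set
#'
#' For each vocabulary, the background is restricted to genes carrying at
#' least one annotation in that vocabulary (DAVID convention). For each
#' term present in the module, the over-representation p-value is the
#' hypergeometric upper tail
#' `P(X >= k)` with `k` module genes carrying the term, `n` annotated
#' module genes, `K` annotated background genes carrying the term, `N`
#' annotated background genes. Raw p drives the ranking; BH-adjusted p
#' (within vocabulary) is reported alongside.
#'
#' @param module_genes Character vector of module gene ids (non-empty,
#'   subset of `background_genes`).
#' @param background_genes Character vector; the gene universe (e.g. all
#'   genes in the preprocessed expression matrix).
#' @param annotations Annotation tibble from [load_annotations()].
#' @param module_id Optional id copied into the output rows.
#' @return Tibble sorted by `pvalue`: `module`, `vocabulary`, `term`,
#'   `name`, `k`, `n`, `K`, `N`, `pvalue`, `padj`.
#' @export
fisher_enrich <- function(module_genes, background_genes, annotations,
                          module_id = "module") {
  if (length(module_genes) == 0) stop("empty module gene set")
  if (!all(module_genes %in% background_genes)) {
    stop("module genes must be a subset of the background")
  }
  annotations <- tibble::as_tibble(annotations)
  ann <- annotations[annotations$gene %in% background_genes, ]
  if (nrow(ann) == 0) stop("no background gene carries any annotation")
  out <- purrr::map_dfr(unique(ann$vocabulary), function(voc) {
    av <- ann[ann$vocabulary == voc, ]
    bg <- unique(av$gene)                  # annotated background, this vocab
    mod <- intersect(module_genes, bg)     # annotated module genes
    if (length(mod) == 0) return(tibble::tibble())
    in_mod <- av[av$gene %in% mod, ]
    terms <- unique(in_mod$term)
    rows <- purrr::map_dfr(terms, function(tm) {
      k <- dplyr::n_distinct(in_mod$gene[in_mod$term == tm])
      K <- dplyr::n_distinct(av$gene[av$term == tm])
      p <- stats::phyper(k - 1, K, length(bg) - K, length(mod),
                         lower.tail = FALSE)
      nm <- av$name[av$term == tm]
      nm <- nm[!is.na(nm)]
      tibble::tibble(
        module = module_id, vocabulary = voc, term = tm,
        name = if (length(nm) > 0) nm[1] else NA_character_,
        k = k, n = length(mod), K = K, N = length(bg), pvalue = p
      )
    })
    rows$padj <- bh_adjust(rows$pvalue)
    rows
  })
  dplyr::arrange(out, .data$pvalue)
}

#' Enrichment across all modules
#'
#' Runs [fisher_enrich()] for every module in a `nodnet_modules` object.
#'
#' @param modules A `nodnet_modules` object.
#' @param background_genes Gene universe.
#' @param annotations Annotation tibble.
#' @return Tibble of enrichment rows for all modules.
#' @export
enrich_modules <- function(modules, background_genes, annotations) {
  membership <- if (inherits(modules, "nodnet_modules")) modules$membership
                else tibble::as_tibble(modules)
  purrr::map_dfr(unique(membership$module), function(mod) {
    genes <- membership$gene[membership$module == mod]
    genes <- intersect(genes, background_genes)
    if (length(genes) == 0) return(tibble::tibble())
    fisher_enrich(genes, background_genes, annotations, module_id = mod)
  })
}
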