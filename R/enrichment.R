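#' Construct an annotation catalog
#'
#' A named collection of term-to-gene annotations (pathway, tissue or
#' disease shaped) over a background gene universe. The background
#' defaults to the union of all annotated genes, which keeps the test
#' self-contained and conservative.
#'
#' @param term_members named list: term ID -> character vector of gene IDs.
#' @param background character vector of background gene IDs; must
#'   contain every annotated gene.
#' @param catalog_name label for the catalog.
#' @return an `annotation_catalog` object.
#' @export
annotation_catalog <- function(term_members, background = NULL,
                               catalog_name = "catalog") {
  stopifnot(is.list(term_members), !is.null(names(term_members)))
  term_members <- lapply(term_members, function(g) unique(as.character(g)))
  annotated <- unique(unlist(term_members))
  if (is.null(background)) background <- annotated
  background <- unique(as.character(background))
  if (!all(annotated %in% background))
    stop("term members must be a subset of the background")
  structure(list(catalog_name = catalog_name, term_members = term_members,
                 background = background),
            class = "annotation_catalog")
}

#' Read an annotation catalog from a 2-column TSV (`term_id<TAB>gene_id`)
#' @param path file path.
#' @param catalog_name label for the catalog.
#' @return an [annotation_catalog()].
#' @export
read_annotation_catalog <- function(path, catalog_name = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("term_id", "gene_id"),
                          colClasses = "character", quote = "")
  annotation_catalog(split(df$gene_id, df$term_id), catalog_name = catalog_name)
}

#' Hypergeometric upper-tail p-value for term overlap
#'
#' Probability of observing at least `k` annotated genes in a query of
#' size `n` drawn without replacement from a background of `N` genes of
#' which `K` carry the term, i.e. `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. Computed in log space for stability.
#'
#' @param k observed overlap.
#' @param K term size in the background.
#' @param n query size.
#' @param N background size.
#' @return p-value in (0, 1].
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | k > pmin(K, n) | K > N | n > N
  if (any(bad)) stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  ifelse(k == 0, 1,
         exp(stats::phyper(k - 1, K, N - K, n,
                           lower.tail = FALSE, log.p = TRUE)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, order-preserving with the input positions
#' and capped at 1.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values of the same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Term enrichment of a gene set against an annotation catalog
#'
#' Tests every catalog term with a potential overlap for
#' over-representation in the query via the hypergeometric upper tail,
#' controlling FDR across all tested terms with Benjamini-Hochberg.
#' Query genes outside the catalog background are dropped (their count
#' is attached as attribute `n_dropped`).
#'
#' @param query character vector of gene IDs.
#' @param catalog an [annotation_catalog()].
#' @return data frame with columns `term_id`, `k` (overlap), `K` (term
#'   size), `n` (effective query size), `N` (background size), `p_value`,
#'   `fdr`, sorted by p-value then term ID.
#' @export
enrich <- function(query, catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  query <- unique(as.character(query))
  eff <- intersect(query, catalog$background)
  n_dropped <- length(query) - length(eff)
  if (!length(eff)) stop("no query gene lies in the catalog background")
  N <- length(catalog$background)
  n <- length(eff)
  K <- lengths(catalog$term_members)
  k <- vapply(catalog$term_members, function(g) length(intersect(g, eff)),
              integer(1))
  keep <- K > 0L
  res <- data.frame(term_id = names(catalog$term_members)[keep],
                    k = k[keep], K = K[keep], n = n, N = N)
  res$p_value <- hypergeom_pvalue(res$k, res$K, res$n, res$N)
  res$fdr <- bh_adjust(res$p_value)
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- n_dropped
  attr(res, "catalog_name") <- catalog$catalog_name
  res
}

#' Write an enrichment result as TSV
#' @param result data frame from [enrich()].
#' @param path output path.
#' @export
write_enrichment <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
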