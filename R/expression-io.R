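#' Construct an expression matrix object
#'
#' An `expression_matrix` holds one experiment's probe-by-sample value
#' table together with its channel kind. Single-channel arrays carry
#' absolute intensities; dual-channel arrays carry log-ratio
#' (fold-change) values. The two kinds are normalized differently before
#' they enter the correlation pipeline, so the kind is part of the object.
#'
#' @param values numeric matrix, probes in rows (rownames = probe IDs),
#'   samples in columns (colnames = sample IDs). `NA` marks missing cells.
#' @param channel `"single"` or `"dual"`.
#' @param experiment_id,organism_id identifier strings.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, channel = c("single", "dual"),
                              experiment_id, organism_id) {
  channel <- match.arg(channel)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  structure(
    list(experiment_id = as.character(experiment_id),
         organism_id = as.character(organism_id),
         channel = channel,
         values = values),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %s (%s, %s-channel): %d probes x %d samples, %d missing\n",
              x$experiment_id, x$organism_id, x$channel,
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from a tab-separated file
#'
#' The file dialect is deliberately plain: row 1 holds sample IDs
#' (optionally preceded by a corner cell for the probe column), each
#' subsequent row is `probe_id` followed by one numeric or empty cell per
#' sample. Empty cells and `NA` become missing values.
#'
#' @param path file path.
#' @inheritParams expression_matrix
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, channel = c("single", "dual"),
                                   experiment_id = basename(path),
                                   organism_id = "unknown") {
  channel <- match.arg(channel)
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("parse error in ", path, ": need a header line and at least one probe row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  # tolerate an optional corner cell above the probe-ID column
  if (length(header) >= 2L && header[1L] == "") {
    sample_ids <- header[-1L]
  } else {
    sample_ids <- header
  }
  n_samples <- length(sample_ids)
  if (n_samples < 1L || any(sample_ids == ""))
    stop("parse error in ", path, ": line 1: malformed sample header")

  body <- cells[-1L]
  keep <- !vapply(body, function(x) length(x) == 1L && x[1L] == "", logical(1))
  body <- body[keep]
  widths <- lengths(body)
  bad <- which(widths != n_samples + 1L)
  if (length(bad)) {
    # line numbers are 1-based in the file; header is line 1
    stop(sprintf("parse error in %s: line %d has %d cells, expected %d (probe ID + %d samples)",
                 path, bad[1L] + 1L, widths[bad[1L]], n_samples + 1L, n_samples))
  }
  probe_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(probe_ids))
    stop("parse error in ", path, ": duplicate probe ID '",
         probe_ids[duplicated(probe_ids)][1L], "'")
  vals <- vapply(body, function(x) {
    v <- x[-1L]
    v[v == ""] <- NA_character_
    suppressWarnings(as.numeric(v))
  }, numeric(n_samples))
  vals <- matrix(vals, ncol = n_samples, byrow = TRUE,
                 dimnames = list(probe_ids, sample_ids))
  expression_matrix(vals, channel, experiment_id, organism_id)
}

#' Write an expression matrix in the TSV dialect read by [read_expression_matrix()]
#' @param m an [expression_matrix()].
#' @param path output path.
#' @export
write_expression_matrix <- function(m, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("", colnames(m$values)), collapse = "\t"), con)
  body <- apply(m$values, 1L, function(v) {
    v <- ifelse(is.na(v), "", format(v, trim = TRUE, digits = 10))
    paste(v, collapse = "\t")
  })
  writeLines(paste(rownames(m$values), body, sep = "\t"), con)
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' Two tab-separated columns, `probe_id` and `gene_id`. Many probes may
#' map to the same gene; a probe may appear at most once (one gene per
#' probe). Unmapped probes are simply absent from the table.
#'
#' @param path file path.
#' @return named character vector: `names()` are probe IDs, values gene IDs.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("probe_id", "gene_id"),
                          colClasses = "character", quote = "")
  probe_map(df$probe_id, df$gene_id)
}

#' Construct a probe-to-gene map from parallel vectors
#' @param probe_ids,gene_ids character vectors of equal length.
#' @return named character vector (probe -> gene).
#' @export
probe_map <- function(probe_ids, gene_ids) {
  if (length(probe_ids) != length(gene_ids))
    stop("probe_ids and gene_ids must have the same length")
  if (anyDuplicated(probe_ids))
    stop("a probe may map to at most one gene; duplicated: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  stats::setNames(as.character(gene_ids), as.character(probe_ids))
}

#' Group experiments by organism
#'
#' @param experiments list of [expression_matrix()] objects (any organisms).
#' @return named list (organism ID -> list of experiments), the
#'   `experiment_set` collection used by [apply_filters()].
#' @export
experiment_sets <- function(experiments) {
  stopifnot(all(vapply(experiments, inherits, logical(1), "expression_matrix")))
  orgs <- vapply(experiments, `[[`, character(1), "organism_id")
  split(experiments, orgs)
}

#' Inclusion-filter configuration
#'
#' Thresholds controlling which samples, experiments and organisms enter
#' the co-expression analysis. Defaults match the published pipeline:
#' samples with fewer than 100 mappable genes and experiments with fewer
#' than three samples are excluded, and an organism qualifies only with
#' at least 50 surviving experiments.
#'
#' @param min_mappable_genes_per_sample minimum distinct genes with a
#'   non-missing value a sample must cover (after probe mapping).
#' @param min_samples_per_experiment minimum surviving samples per experiment.
#' @param min_experiments_per_organism minimum surviving experiments per organism.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_mappable_genes_per_sample = 100L,
                          min_samples_per_experiment = 3L,
                          min_experiments_per_organism = 50L) {
  cfg <- list(min_mappable_genes_per_sample = as.integer(min_mappable_genes_per_sample),
              min_samples_per_experiment = as.integer(min_samples_per_experiment),
              min_experiments_per_organism = as.integer(min_experiments_per_organism))
  if (any(unlist(cfg) < 1L)) stop("all filter thresholds must be >= 1")
  structure(cfg, class = "filter_config")
}

#' Apply sample / experiment / organism inclusion filters
#'
#' Filters are applied in a fixed order: first samples (too few mappable
#' genes), then experiments (too few surviving samples), then organisms
#' (too few surviving experiments). A "mappable gene" is a distinct gene
#' ID with at least one non-missing probe value in that sample. The
#' operation is idempotent and only ever removes entries.
#'
#' @param sets named list of experiment lists as returned by
#'   [experiment_sets()], or a plain list of [expression_matrix()] objects.
#' @param map probe-to-gene map ([probe_map()]).
#' @param config a [filter_config()].
#' @return filtered sets, with an `exclusions` attribute: a data frame
#'   with columns `level`, `id`, `reason` recording every removal.
#' @export
apply_filters <- function(sets, map, config = filter_config()) {
  if (length(sets) && all(vapply(sets, inherits, logical(1), "expression_matrix")))
    sets <- experiment_sets(unname(sets))
  stopifnot(inherits(config, "filter_config"))
  log <- list()
  note <- function(level, id, reason)
    log[[length(log) + 1L]] <<- data.frame(level = level, id = id,
                                           reason = reason)

  out <- lapply(names(sets), function(org) {
    kept_exps <- list()
    for (m in sets[[org]]) {
      mapped <- intersect(rownames(m$values), names(map))
      keep_sample <- logical(ncol(m$values))
      for (j in seq_len(ncol(m$values))) {
        present <- mapped[!is.na(m$values[mapped, j])]
        n_genes <- length(unique(map[present]))
        keep_sample[j] <- n_genes >= config$min_mappable_genes_per_sample
        if (!keep_sample[j])
          note("sample", paste0(m$experiment_id, ":", colnames(m$values)[j]),
               sprintf("only %d mappable genes (< %d)", n_genes,
                       config$min_mappable_genes_per_sample))
      }
      if (sum(keep_sample) < config$min_samples_per_experiment) {
        note("experiment", m$experiment_id,
             sprintf("only %d samples after sample filtering (< %d)",
                     sum(keep_sample), config$min_samples_per_experiment))
        next
      }
      m$values <- m$values[, keep_sample, drop = FALSE]
      kept_exps[[length(kept_exps) + 1L]] <- m
    }
    kept_exps
  })
  names(out) <- names(sets)

  enough <- vapply(out, length, integer(1)) >= config$min_experiments_per_organism
  for (org in names(out)[!enough])
    note("organism", org,
         sprintf("only %d experiments after experiment filtering (< %d)",
                 length(out[[org]]), config$min_experiments_per_organism))
  out <- out[enough]

  exclusions <- if (length(log)) do.call(rbind, log) else
    data.frame(level = character(), id = character(), reason = character())
  attr(out, "exclusions") <- exclusions
  out
}

#' Write an exclusion log as TSV (`level<TAB>id<TAB>reason`)
#' @param exclusions data frame from `attr(apply_filters(...), "exclusions")`.
#' @param path output path.
#' @export
write_exclusion_log <- function(exclusions, path) {
  utils::write.table(exclusions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
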