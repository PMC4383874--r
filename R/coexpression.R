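# Column z-normalization with the population (1/n) standard deviation so
# that a column like (-1, 0, 1) maps to (-1.2247, 0, 1.2247) and the step
# is exactly idempotent. Constant (or all-missing) columns become zeros
# (resp. stay missing) rather than NaN.
z_normalize_columns <- function(values) {
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    ok <- !is.na(v)
    n <- sum(ok)
    if (n == 0L) next
    mu <- mean(v[ok])
    sd_pop <- sqrt(sum((v[ok] - mu)^2) / n)
    values[ok, j] <- if (sd_pop > 0) (v[ok] - mu) / sd_pop else 0
  }
  values
}

#' Normalize a single-channel (intensity) expression matrix
#'
#' Absolute intensities are made comparable to dual-channel log-ratios:
#' values are log2-transformed (non-positive values treated as missing),
#' each probe's mean across the experiment's samples is subtracted
#' (yielding a fold-change against the probe's average condition), and
#' finally each sample column is z-normalized using the population
#' standard deviation. Constant columns become all zeros.
#'
#' @param m an [expression_matrix()] with `channel == "single"`.
#' @return the normalized [expression_matrix()].
#' @export
normalize_single_channel <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$channel != "single")
    stop("normalize_single_channel() requires a single-channel matrix, got '",
         m$channel, "'")
  v <- m$values
  v[!is.na(v) & v <= 0] <- NA_real_
  v <- log2(v)
  v <- v - rowMeans(v, na.rm = TRUE)
  v[is.nan(v)] <- NA_real_   # rows that were entirely missing
  m$values <- z_normalize_columns(v)
  m
}

#' Normalize a dual-channel (log-ratio) expression matrix
#'
#' Dual-channel values are already fold changes, so only the per-sample
#' z-normalization is applied (population standard deviation; constant
#' columns become zeros, all-missing columns stay missing).
#'
#' @param m an [expression_matrix()] with `channel == "dual"`.
#' @return the normalized [expression_matrix()].
#' @export
normalize_dual_channel <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$channel != "dual")
    stop("normalize_dual_channel() requires a dual-channel matrix, got '",
         m$channel, "'")
  m$values <- z_normalize_columns(m$values)
  m
}

#' Normalize an expression matrix according to its channel kind
#' @param m an [expression_matrix()].
#' @return the normalized [expression_matrix()].
#' @export
normalize_expression <- function(m) {
  if (m$channel == "single") normalize_single_channel(m) else normalize_dual_channel(m)
}

#' Merge probe rows into gene rows
#'
#' Rows are re-keyed by gene ID using the probe map; a gene measured by
#' several probes gets, per sample, the arithmetic mean of its probes'
#' non-missing values. Probes without a mapping are dropped. Should the
#' map not cover any probe, an empty matrix is returned with a warning.
#'
#' @param m a normalized [expression_matrix()].
#' @param map probe-to-gene map ([probe_map()]).
#' @return an [expression_matrix()] whose rows are genes.
#' @export
merge_probes <- function(m, map) {
  stopifnot(inherits(m, "expression_matrix"))
  probes <- intersect(rownames(m$values), names(map))
  if (!length(probes)) {
    warning("probe map does not cover any probe of experiment ",
            m$experiment_id)
    m$values <- matrix(numeric(), nrow = 0L, ncol = ncol(m$values),
                       dimnames = list(character(), colnames(m$values)))
    return(m)
  }
  genes <- map[probes]
  v <- m$values[probes, , drop = FALSE]
  grp <- factor(genes, levels = unique(genes))
  merged <- rowsum(ifelse(is.na(v), 0, v), grp, na.rm = FALSE)
  counts <- rowsum((!is.na(v)) * 1, grp)
  merged <- merged / counts            # 0/0 -> NaN where all probes missing
  merged[counts == 0] <- NA_real_
  rownames(merged) <- levels(grp)
  m$values <- merged
  m
}

#' Pool normalized, gene-level experiments into one gene profile matrix
#'
#' Concatenates the arrays (samples) of all experiments of one organism
#' and channel into a single gene-by-array matrix; this pooled collection
#' is what redundancy pruning operates on. Array IDs are
#' `experiment_id:sample_id`; genes absent from an experiment are missing
#' in its columns.
#'
#' @param experiments list of gene-level [expression_matrix()] objects
#'   sharing organism and channel.
#' @return a `gene_profile_matrix`: list with `organism_id`, `channel`,
#'   `values` (gene x array matrix), and `array_source` (data frame
#'   mapping each array to its experiment and sample).
#' @export
pool_experiments <- function(experiments) {
  stopifnot(length(experiments) >= 1L)
  org <- unique(vapply(experiments, `[[`, character(1), "organism_id"))
  chan <- unique(vapply(experiments, `[[`, character(1), "channel"))
  if (length(org) != 1L) stop("experiments span multiple organisms")
  if (length(chan) != 1L) stop("experiments span multiple channels")
  genes <- sort(unique(unlist(lapply(experiments, function(m) rownames(m$values)))))
  cols <- lapply(experiments, function(m) {
    out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(m$values),
                  dimnames = list(genes,
                                  paste0(m$experiment_id, ":", colnames(m$values))))
    out[rownames(m$values), ] <- m$values
    out
  })
  values <- do.call(cbind, cols)
  if (anyDuplicated(colnames(values))) stop("duplicate array IDs after pooling")
  src <- do.call(rbind, lapply(experiments, function(m)
    data.frame(array_id = paste0(m$experiment_id, ":", colnames(m$values)),
               experiment_id = m$experiment_id, sample_id = colnames(m$values))))
  structure(list(organism_id = org, channel = chan, values = values,
                 array_source = src),
            class = "gene_profile_matrix")
}

#' @export
print.gene_profile_matrix <- function(x, ...) {
  cat(sprintf("<gene_profile_matrix> %s (%s-channel): %d genes x %d arrays\n",
              x$organism_id, x$channel, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Array redundancy-pruning configuration
#'
#' Similarity thresholds above which two arrays count as redundant for
#' Hobohm-2 pruning. Defaults are 0.7 for single-channel and 0.95 for
#' dual-channel collections. `min_overlap` is the minimum number of
#' genes two arrays must share (non-missing in both) for their Spearman
#' similarity to be considered defined.
#'
#' @param threshold_single,threshold_dual redundancy thresholds in (0, 1].
#' @param min_overlap minimum shared non-missing genes.
#' @return a `prune_config` list.
#' @export
prune_config <- function(threshold_single = 0.7, threshold_dual = 0.95,
                         min_overlap = 20L) {
  if (threshold_single <= 0 || threshold_single > 1 ||
      threshold_dual <= 0 || threshold_dual > 1)
    stop("thresholds must lie in (0, 1]")
  structure(list(threshold_single = threshold_single,
                 threshold_dual = threshold_dual,
                 min_overlap = as.integer(min_overlap)),
            class = "prune_config")
}

#' Spearman similarity between arrays
#'
#' Rank correlation between every pair of arrays over the genes
#' non-missing in both. Entries whose pairwise overlap falls below
#' `min_overlap`, or where either array has zero rank variance on the
#' shared genes, are undefined (`NA`) and are treated as *not* redundant
#' by the pruning step.
#'
#' @param profiles a `gene_profile_matrix` from [pool_experiments()], or
#'   a plain gene-by-array matrix.
#' @param min_overlap minimum shared non-missing genes.
#' @return symmetric similarity matrix with unit diagonal (array IDs as
#'   dimnames).
#' @export
array_similarity <- function(profiles, min_overlap = 20L) {
  values <- if (inherits(profiles, "gene_profile_matrix")) profiles$values else profiles
  if (ncol(values) < 2L) stop("need at least two arrays")
  sims <- suppressWarnings(
    stats::cor(values, method = "spearman", use = "pairwise.complete.obs"))
  overlap <- crossprod(!is.na(values))
  sims[overlap < min_overlap] <- NA_real_
  diag(sims) <- ifelse(diag(overlap) > 0, 1, NA_real_)
  sims
}

#' Hobohm-2 redundancy pruning
#'
#' Greedy maximal-degree removal: build a redundancy graph with an edge
#' wherever similarity exceeds the threshold, then repeatedly delete the
#' vertex with the highest current degree until no edges remain. Ties on
#' degree are broken by deleting the lexicographically larger array ID,
#' making the result deterministic. Undefined (`NA`) similarities never
#' create an edge. Similarity is signed: strongly anti-correlated arrays
#' are not redundant.
#'
#' @param sims symmetric similarity matrix (as from [array_similarity()]).
#' @param threshold redundancy threshold in (0, 1]; pairs with
#'   `similarity > threshold` are redundant.
#' @return character vector of retained array IDs (in input order).
#' @export
hobohm2_prune <- function(sims, threshold) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  ids <- colnames(sims)
  adj <- !is.na(sims) & sims > threshold
  diag(adj) <- FALSE
  alive <- rep(TRUE, length(ids))
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (max(deg) == 0) break
    worst <- which(deg == max(deg))
    victim <- worst[ids[worst] == max(ids[worst])][1L]  # drop lexicographically larger ID
    alive[victim] <- FALSE
  }
  ids[alive]
}

#' Gene-by-gene Pearson correlation over retained arrays
#'
#' Computes, for every unordered gene pair, the Pearson correlation of
#' their expression profiles across the retained (non-redundant) arrays,
#' using pairwise-complete observations. Pairs with fewer than
#' `min_overlap` shared arrays, or with zero variance on the shared
#' arrays, are omitted.
#'
#' @param profiles a `gene_profile_matrix` or gene-by-array matrix.
#' @param retained character vector of array IDs to use (defaults to all).
#' @param min_overlap minimum pairwise-complete array count.
#' @return data frame with columns `gene_a`, `gene_b` (with
#'   `gene_a < gene_b`), `r`, `n_arrays`, sorted by the pair key.
#' @export
gene_correlation <- function(profiles, retained = NULL, min_overlap = 20L) {
  values <- if (inherits(profiles, "gene_profile_matrix")) profiles$values else profiles
  if (is.null(retained)) retained <- colnames(values)
  if (!length(retained)) stop("empty retained array set")
  if (!all(retained %in% colnames(values)))
    stop("retained IDs not present in profiles: ",
         paste(setdiff(retained, colnames(values)), collapse = ", "))
  v <- t(values[, retained, drop = FALSE])   # arrays x genes
  r <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(v))
  genes <- colnames(v)
  idx <- which(upper.tri(r), arr.ind = TRUE)
  out <- data.frame(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
                    r = pmin(1, pmax(-1, r[idx])), n_arrays = n[idx])
  swap <- out$gene_a > out$gene_b
  if (any(swap)) {
    tmp <- out$gene_a[swap]
    out$gene_a[swap] <- out$gene_b[swap]
    out$gene_b[swap] <- tmp
  }
  out <- out[!is.na(out$r) & out$n_arrays >= min_overlap, , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene-pair correlations as TSV (`gene_a  gene_b  r  n`)
#' @param pairs data frame from [gene_correlation()].
#' @param path output path.
#' @export
write_correlations <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
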