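#' Construct a pathway co-membership gold standard
#'
#' The benchmark truth used for calibration and ROC evaluation: a gene
#' pair counts as a true functional association when both genes are
#' annotated to at least one common pathway map.
#'
#' @param gene_ids,pathway_ids parallel character vectors (one row per
#'   gene-pathway membership).
#' @return a `gold_standard`: named list mapping gene ID -> character
#'   vector of pathway IDs.
#' @export
gold_standard <- function(gene_ids, pathway_ids) {
  if (length(gene_ids) != length(pathway_ids))
    stop("gene_ids and pathway_ids must have the same length")
  sets <- lapply(split(as.character(pathway_ids), as.character(gene_ids)), unique)
  structure(sets, class = "gold_standard")
}

#' Read a gold standard from a 2-column TSV (`gene_id<TAB>pathway_id`)
#' @param path file path.
#' @return a [gold_standard()].
#' @export
read_gold_standard <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene_id", "pathway_id"),
                          colClasses = "character", quote = "")
  gold_standard(df$gene_id, df$pathway_id)
}

#' Label gene pairs against a gold standard
#'
#' A pair is positive when the two genes share at least one pathway,
#' negative when both are annotated but share none, and unbenchmarkable
#' (excluded from the returned set) when either gene lacks annotation.
#'
#' @param pairs data frame with `gene_a`, `gene_b` and (usually) `r`
#'   columns, e.g. from [gene_correlation()].
#' @param gold a [gold_standard()].
#' @return the benchmarkable subset of `pairs` with an added integer
#'   `label` column (1 positive / 0 negative); the number of excluded
#'   pairs is attached as attribute `n_unbenchmarkable`.
#' @export
label_pairs <- function(pairs, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  a_ann <- pairs$gene_a %in% names(gold)
  b_ann <- pairs$gene_b %in% names(gold)
  bench <- a_ann & b_ann
  out <- pairs[bench, , drop = FALSE]
  share <- mapply(function(a, b) length(intersect(gold[[a]], gold[[b]])) > 0,
                  out$gene_a, out$gene_b, USE.NAMES = FALSE)
  out$label <- as.integer(share)
  rownames(out) <- NULL
  attr(out, "n_unbenchmarkable") <- sum(!bench)
  out
}

#' Calibrate raw correlations against gold-standard labels
#'
#' Estimates the posterior probability that a pair with a given raw
#' correlation is a true association. Benchmarkable pairs are sorted by
#' raw correlation (descending); a sliding window of `window_size` pairs
#' yields a local precision estimate, which is then made monotone
#' non-decreasing in the raw score by isotonic (pool-adjacent-violators)
#' regression. The global positive fraction is recorded as the prior.
#'
#' @param labeled data frame with numeric `r` and 0/1 `label` columns
#'   (from [label_pairs()]).
#' @param window_size sliding-window width (>= 50).
#' @return a `calibration_curve`: list with `knots` (data frame
#'   `raw`, `posterior`, non-decreasing), `window_size` and `prior`.
#' @export
calibrate <- function(labeled, window_size = 500L) {
  window_size <- as.integer(window_size)
  if (window_size < 50L) stop("window_size must be >= 50")
  n <- nrow(labeled)
  if (n < window_size)
    stop(sprintf("need at least window_size benchmarkable pairs (have %d, window %d)",
                 n, window_size))
  ord <- order(labeled$r, decreasing = TRUE)
  r <- labeled$r[ord]
  y <- labeled$label[ord]
  kern <- rep(1 / window_size, window_size)
  prec <- as.numeric(stats::filter(y, kern, sides = 2))
  raw <- as.numeric(stats::filter(r, kern, sides = 2))
  ok <- !is.na(prec) & !is.na(raw)
  raw <- raw[ok]; prec <- prec[ok]
  iso <- stats::isoreg(raw, prec)     # sorts by raw ascending internally
  xr <- iso$x[iso$ord]
  yf <- iso$yf
  knots <- data.frame(raw = xr, posterior = pmin(1, pmax(0, yf)))
  knots <- stats::aggregate(posterior ~ raw, knots, mean)  # collapse tied raw
  knots$posterior <- cummax(knots$posterior)               # guard numeric ties
  structure(list(knots = knots, window_size = window_size,
                 prior = mean(y)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d knots, raw in [%.3f, %.3f], posterior in [%.3f, %.3f], prior %.4f\n",
              nrow(x$knots), min(x$knots$raw), max(x$knots$raw),
              min(x$knots$posterior), max(x$knots$posterior), x$prior))
  invisible(x)
}

#' Map raw correlations through a calibration curve
#'
#' Linear interpolation between curve knots; raw scores below the lowest
#' knot get the lowest posterior, above the highest knot the highest.
#'
#' @param curve a [calibrate()] result.
#' @param r numeric vector of raw correlations.
#' @return numeric vector of posterior association probabilities.
#' @export
calibrated_score <- function(curve, r) {
  stopifnot(inherits(curve, "calibration_curve"))
  k <- curve$knots
  if (nrow(k) == 1L) return(rep(k$posterior, length(r)))
  stats::approx(k$raw, k$posterior, xout = r, rule = 2, ties = "ordered")$y
}

#' Score gene pairs with a calibration curve
#'
#' @param pairs data frame with `gene_a`, `gene_b`, `r`.
#' @param curve a [calibrate()] result.
#' @param channel name of the score column to create (default `"score"`).
#' @return `pairs` with an added posterior score column.
#' @export
score_pairs <- function(pairs, curve, channel = "score") {
  pairs[[channel]] <- calibrated_score(curve, pairs$r)
  pairs
}

#' Combine per-channel scores in a probabilistic (noisy-OR) manner
#'
#' Each channel score is first corrected for the benchmark prior,
#' `s' = (s - prior) / (1 - prior)` (scores below the prior are floored
#' at the prior), the corrected scores are combined as
#' `1 - prod(1 - s')`, and the prior is restored. With a single channel
#' the input score is returned unchanged; the result always lies in
#' `[prior, 1)` for inputs in `[0, 1)`.
#'
#' @param scores numeric vector of channel scores in `[0, 1]`; `NA`
#'   entries (absent channels) are dropped.
#' @param prior baseline probability that a random benchmarkable pair is
#'   positive, in `[0, 1)`.
#' @return combined score (length 1).
#' @export
combine_scores <- function(scores, prior = 0) {
  if (prior >= 1 || prior < 0) stop("prior must lie in [0, 1)")
  scores <- scores[!is.na(scores)]
  if (!length(scores)) return(NA_real_)
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  s <- (pmax(scores, prior) - prior) / (1 - prior)
  comb <- 1 - prod(1 - s)
  comb * (1 - prior) + prior
}

#' Row-wise noisy-OR combination over a matrix of channel scores
#' @param score_matrix numeric matrix, one column per channel, `NA` for
#'   absent channels.
#' @inheritParams combine_scores
#' @return numeric vector of combined scores (one per row).
#' @export
combine_score_matrix <- function(score_matrix, prior = 0) {
  apply(score_matrix, 1L, combine_scores, prior = prior)
}

#' Build a scored network from per-channel pair scores
#'
#' Outer-joins the per-channel score tables on the pair key and combines
#' the channel scores with [combine_scores()].
#'
#' @param channel_pairs named list of data frames, each with `gene_a`,
#'   `gene_b` and a posterior score column named `score`.
#' @param prior prior used for the noisy-OR combination.
#' @return a `scored_network` data frame: `gene_a`, `gene_b`, one
#'   `score_<channel>` column per channel, and `combined`.
#' @export
scored_network <- function(channel_pairs, prior = 0) {
  stopifnot(length(channel_pairs) >= 1L, !is.null(names(channel_pairs)))
  tabs <- lapply(names(channel_pairs), function(ch) {
    df <- channel_pairs[[ch]][, c("gene_a", "gene_b", "score")]
    names(df)[3L] <- paste0("score_", ch)
    df
  })
  out <- Reduce(function(x, y) merge(x, y, by = c("gene_a", "gene_b"),
                                     all = TRUE), tabs)
  score_cols <- grep("^score_", names(out), value = TRUE)
  out$combined <- combine_score_matrix(
    as.matrix(out[, score_cols, drop = FALSE]), prior = prior)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "prior") <- prior
  class(out) <- c("scored_network", "data.frame")
  out
}

#' Write a scored network as TSV
#'
#' Scores are rendered on the 0-1 scale with three decimals, or, with
#' `string_convention = TRUE`, as integers on the conventional 0-999
#' scale (`round(score * 1000)` capped at 999).
#'
#' @param network a [scored_network()] data frame.
#' @param path output path.
#' @param string_convention render scores as 0-999 integers.
#' @export
write_scored_network <- function(network, path, string_convention = FALSE) {
  out <- as.data.frame(network)
  num <- vapply(out, is.numeric, logical(1))
  if (string_convention) {
    out[num] <- lapply(out[num], function(s) pmin(999L, as.integer(round(s * 1000))))
  } else {
    out[num] <- lapply(out[num], function(s) sprintf("%.3f", s))
    out[out == "NA"] <- ""
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' ROC benchmark of a scored network against a gold standard
#'
#' Ranks pairs by combined score, groups tied scores into single ROC
#' steps, and integrates the area under the curve by the trapezoid rule
#' (equivalently, the tie-corrected Mann-Whitney statistic).
#'
#' @param network a [scored_network()] data frame (or any data frame with
#'   `gene_a`, `gene_b` and a score column).
#' @param gold a [gold_standard()].
#' @param score_col name of the score column (default `"combined"`).
#' @return a `roc_result`: list with `points` (data frame `fpr`, `tpr`)
#'   and `auc`.
#' @export
roc_benchmark <- function(network, gold, score_col = "combined") {
  labeled <- label_pairs(as.data.frame(network), gold)
  roc_curve(labeled[[score_col]], labeled$label)
}

#' ROC curve and AUC from scores and binary labels
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length.
#' @return a `roc_result` (see [roc_benchmark()]).
#' @export
roc_curve <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop(sprintf("ROC needs both classes (have %d positives, %d negatives)",
                 n_pos, n_neg))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # one ROC step per distinct score value
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Write a ROC result as TSV of (fpr, tpr) with a one-line AUC footer
#' @param roc a `roc_result`.
#' @param path output path.
#' @export
write_roc <- function(roc, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("fpr\ttpr", con)
  writeLines(sprintf("%.6g\t%.6g", roc$points$fpr, roc$points$tpr), con)
  writeLines(sprintf("# auc\t%.10g", roc$auc), con)
  invisible(path)
}
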