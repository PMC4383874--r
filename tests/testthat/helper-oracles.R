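# Independent oracles and small fixture builders used across the suite.

# Build an expression_matrix from a plain matrix with auto IDs.
make_expr <- function(values, channel = "dual", experiment_id = "E1",
                      organism_id = "orgA") {
  if (is.null(rownames(values))) rownames(values) <- sprintf("p%d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  expression_matrix(values, channel, experiment_id, organism_id)
}

# Identity probe map for a matrix whose probes are genes.
identity_map <- function(m) probe_map(rownames(m$values), rownames(m$values))

# Step-by-step greedy simulation of maximal-degree removal, written as a
# literal per-vertex recount (independent of the packaged implementation).
hobohm_oracle <- function(sims, threshold) {
  ids <- colnames(sims)
  redundant <- function(i, j) {
    s <- sims[i, j]
    !is.na(s) && s > threshold
  }
  alive <- ids
  repeat {
    deg <- vapply(alive, function(i)
      sum(vapply(alive, function(j) i != j && redundant(i, j), logical(1))),
      integer(1))
    if (!length(deg) || max(deg) == 0L) break
    worst <- alive[deg == max(deg)]
    victim <- sort(worst, decreasing = TRUE)[1L]
    alive <- setdiff(alive, victim)
  }
  ids[ids %in% alive]
}

# Random symmetric similarity matrix with unit diagonal.
random_sims <- function(n_arrays) {
  s <- matrix(stats::runif(n_arrays^2, -1, 1), n_arrays)
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  diag(s) <- 1
  dimnames(s) <- list(sprintf("a%02d", seq_len(n_arrays)),
                      sprintf("a%02d", seq_len(n_arrays)))
  s
}

# Tie-corrected Mann-Whitney AUC (rank formula), the trapezoid oracle.
mann_whitney_auc <- function(scores, labels) {
  rk <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Exact hypergeometric upper tail by explicit combinatorial enumeration.
hyper_upper_enum <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Does partition `fine` refine partition `coarse`? Both are named vectors
# protein -> group over (at least) the shared proteins.
partition_refines <- function(fine, coarse) {
  shared <- intersect(names(fine), names(coarse))
  all(vapply(split(coarse[shared], fine[shared]),
             function(g) length(unique(g)) == 1L, logical(1)))
}

# Named vector protein -> group at one clade of an ortholog_groups object.
groups_vec <- function(groups, clade) {
  a <- groups$assignments
  sel <- a$clade_id == clade
  stats::setNames(a$group_id[sel], a$protein_id[sel])
}

# A small fixed clade tree over four species: root -> (AB, CD).
toy_tree <- function() {
  clade_tree(c("root", "AB", "CD"),
             c(NA, "root", "root"),
             list(root = c("spA", "spB", "spC", "spD"),
                  AB = c("spA", "spB"), CD = c("spC", "spD")))
}
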