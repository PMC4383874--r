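test_that("single-channel normalization: log2, probe-mean subtraction, column z", {
  v <- matrix(c(2, 8,
                4, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("pA", "pB"), c("s1", "s2")))
  m <- make_expr(v, channel = "single")
  # after log2 and row-mean subtraction, pA is (-1, +1) and pB is (0, 0);
  # columns then z-normalize to (-1, 1) and (1, -1) -> check via moments
  out <- normalize_single_channel(m)$values
  expect_equal(unname(colMeans(out)), c(0, 0), tolerance = 1e-12)
  expect_error(normalize_single_channel(make_expr(v, channel = "dual")),
               "single-channel")

  # random positive matrix: every column has population mean 0 / sd 1
  set.seed(3)
  big <- make_expr(matrix(2^stats::rnorm(60), 12, 5), channel = "single")
  bv <- normalize_single_channel(big)$values
  for (j in 1:5) {
    expect_equal(mean(bv[, j]), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean((bv[, j] - mean(bv[, j]))^2)), 1, tolerance = 1e-9)
  }
  # non-positive intensities are treated as missing, not -Inf
  v2 <- v; v2[1, 1] <- 0
  expect_true(is.na(normalize_single_channel(make_expr(v2, channel = "single"))$values[1, 1]))
})

test_that("dual-channel z-normalization matches the closed form and is idempotent", {
  v <- matrix(c(-1, 0, 1), 3, dimnames = list(paste0("p", 1:3), "s1"))
  m <- make_expr(v, channel = "dual")
  out <- normalize_dual_channel(m)$values
  expect_equal(unname(out[, 1]), c(-1.2247, 0, 1.2247), tolerance = 1e-3)
  expect_equal(normalize_dual_channel(normalize_dual_channel(m))$values, out,
               tolerance = 1e-9)
  # constant column -> zeros; all-missing column stays missing
  v3 <- cbind(v, s2 = c(5, 5, 5), s3 = NA_real_)
  out3 <- normalize_dual_channel(make_expr(v3, channel = "dual"))$values
  expect_equal(unname(out3[, "s2"]), c(0, 0, 0))
  expect_true(all(is.na(out3[, "s3"])))
  expect_error(normalize_dual_channel(make_expr(v, channel = "single")),
               "dual-channel")
})

test_that("probe merging averages probes per gene, missing-aware", {
  v <- matrix(c(1, 5,
                3, NA,
                7, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  m <- make_expr(v, channel = "dual")
  map <- probe_map(c("p1", "p2", "p3"), c("gX", "gX", "gY"))
  out <- merge_probes(m, map)
  expect_equal(out$values["gX", ], c(s1 = 2, s2 = 5))
  expect_equal(out$values["gY", ], c(s1 = 7, s2 = 2))
  # zero-overlap map: empty result with a warning
  expect_warning(empty <- merge_probes(m, probe_map("q1", "gZ")), "cover")
  expect_identical(nrow(empty$values), 0L)
})

test_that("array similarity is Spearman over shared genes with an overlap guard", {
  v <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
  rownames(v) <- paste0("g", 1:4)
  s <- array_similarity(v, min_overlap = 2)
  expect_equal(s["a", "b"], 0.8)            # hand enumeration of rank distance
  expect_equal(s["a", "c"], -1)
  expect_equal(s["a", "a"], 1)
  expect_equal(s, t(s), tolerance = 1e-12)
  # overlap below the guard is undefined
  v2 <- v; v2[3:4, "b"] <- NA
  expect_true(is.na(array_similarity(v2, min_overlap = 3)["a", "b"]))
  expect_error(array_similarity(v[, 1, drop = FALSE], 2), "two arrays")
})

test_that("Hobohm-2 follows the greedy maximal-degree rule", {
  s <- matrix(c(1, .8, .8,
                .8, 1, .1,
                .8, .1, 1), 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_identical(hobohm2_prune(s, 0.7), c("B", "C"))   # A has degree 2
  expect_identical(hobohm2_prune(s, 0.9), c("A", "B", "C"))
  # oracle equivalence and no-redundant-pair postcondition on random inputs
  set.seed(4)
  for (i in 1:25) {
    sims <- random_sims(sample(3:9, 1))
    thr <- stats::runif(1, 0.2, 0.95)
    kept <- hobohm2_prune(sims, thr)
    expect_identical(kept, hobohm_oracle(sims, thr))
    sub <- sims[kept, kept, drop = FALSE]
    expect_true(all(sub[upper.tri(sub)] <= thr))
  }
})

test_that("adding an exact duplicate array leaves the pruned set unchanged", {
  set.seed(5)
  v <- matrix(stats::rnorm(30 * 4), 30, dimnames = list(sprintf("g%02d", 1:30),
                                                        c("a1", "a2", "a3", "a4")))
  base <- hobohm2_prune(array_similarity(v, 10), 0.7)
  v2 <- cbind(v, a1d = v[, "a1"])
  kept <- hobohm2_prune(array_similarity(v2, 10), 0.7)
  expect_length(kept, length(base))
  expect_true(xor("a1" %in% kept, "a1d" %in% kept) || !"a1" %in% base)
})

test_that("gene correlations match the textbook formula and respect overlap", {
  v <- rbind(gA = c(1, 2, 3, 4), gB = c(2, 4, 5, 9), gC = c(3, 2, 1, 0))
  colnames(v) <- paste0("a", 1:4)
  out <- gene_correlation(v, min_overlap = 3)
  x <- v["gA", ]; y <- v["gB", ]
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r[out$gene_a == "gA" & out$gene_b == "gB"], r_manual,
               tolerance = 1e-9)
  expect_equal(out$r[out$gene_a == "gA" & out$gene_b == "gC"], -1)
  expect_true(all(out$gene_a < out$gene_b))
  expect_true(all(out$n_arrays == 4))
  expect_error(gene_correlation(v, retained = character(0)), "empty")
  # order invariance
  perm <- gene_correlation(v[c(3, 1, 2), c(2, 4, 1, 3)], min_overlap = 3)
  expect_equal(perm[order(perm$gene_a, perm$gene_b), ]$r, out$r)
})

test_that("pooling concatenates experiments with traceable array IDs", {
  m1 <- make_expr(rbind(gA = c(1, 2), gB = c(3, 4)), experiment_id = "E1")
  m2 <- make_expr(rbind(gA = c(5, 6), gC = c(7, 8)), experiment_id = "E2")
  pool <- pool_experiments(list(m1, m2))
  expect_identical(colnames(pool$values), c("E1:s1", "E1:s2", "E2:s1", "E2:s2"))
  expect_true(is.na(pool$values["gC", "E1:s1"]))
  expect_equal(pool$values["gA", "E2:s2"], 6)
  expect_error(pool_experiments(list(m1, make_expr(matrix(1, 1, 1,
    dimnames = list("gA", "s1")), channel = "single"))), "channels")
})
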