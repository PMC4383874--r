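test_that("clade trees validate rootedness, nesting and sibling disjointness", {
  expect_s3_class(toy_tree(), "clade_tree")
  expect_error(clade_tree(c("a", "b"), c(NA, NA),
                          list(a = "s1", b = "s2")), "exactly one root")
  expect_error(clade_tree(c("r", "c"), c(NA, "r"),
                          list(r = "s1", c = c("s1", "s2"))), "outside its parent")
  expect_error(clade_tree(c("r", "c1", "c2"), c(NA, "r", "r"),
                          list(r = c("s1", "s2"), c1 = "s1", c2 = "s1")),
               "share species")
})

toy_groups <- function(df) {
  sp <- c(pA1 = "spA", pA2 = "spA", pB1 = "spB", pB2 = "spB",
          pC1 = "spC", pD1 = "spD")
  ortholog_groups(df, sp, toy_tree())
}

test_that("consistency check flags proteins co-grouped below but split above", {
  # consistent: AB group {pA1, pB1} sits inside root group {pA1, pB1, pC1}
  ok <- toy_groups(data.frame(
    clade_id = c("root", "root", "root", "AB", "AB"),
    group_id = c("r1", "r1", "r1", "x", "x"),
    protein_id = c("pA1", "pB1", "pC1", "pA1", "pB1")))
  expect_true(is_consistent(ok, toy_tree()))

  # violation: pA1, pB1 together at AB but split at root
  bad <- toy_groups(data.frame(
    clade_id = c("root", "root", "AB", "AB"),
    group_id = c("r1", "r2", "x", "x"),
    protein_id = c("pA1", "pB1", "pA1", "pB1")))
  v <- is_consistent(bad, toy_tree())
  expect_false(v)
  viol <- attr(v, "violations")
  expect_identical(viol$clade, "AB")
  expect_setequal(c(viol$witness_a, viol$witness_b), c("pA1", "pB1"))

  # single-clade assignment is vacuously consistent
  solo <- toy_groups(data.frame(clade_id = "AB", group_id = "x",
                                protein_id = c("pA1", "pB1")))
  expect_true(is_consistent(solo, toy_tree()))
})

test_that("both repair strategies resolve the two-protein conflict as specified", {
  bad <- toy_groups(data.frame(
    clade_id = c("root", "root", "AB", "AB"),
    group_id = c("r1", "r2", "x", "x"),
    protein_id = c("pA1", "pB1", "pA1", "pB1")))
  tree <- toy_tree()

  up <- enforce_consistency(bad, tree, "merge_up")
  expect_true(is_consistent(up, tree))
  expect_identical(length(unique(groups_vec(up, "root"))), 1L)   # root merged
  expect_identical(groups_vec(up, "AB"), groups_vec(bad, "AB"))  # child intact

  down <- enforce_consistency(bad, tree, "split_down")
  expect_true(is_consistent(down, tree))
  expect_identical(groups_vec(down, "root"), groups_vec(bad, "root"))
  expect_identical(length(unique(groups_vec(down, "AB"))), 2L)   # child split
})

test_that("already-consistent input is a fixpoint for both strategies", {
  sim <- simulate_orthology(4, 3, 4, corruption_rate = 0, seed = 11)
  expect_true(is_consistent(sim$groups, sim$tree))
  for (strat in c("merge_up", "split_down")) {
    fixed <- enforce_consistency(sim$groups, sim$tree, strat)
    expect_identical(fixed$assignments, sim$groups$assignments)
  }
})

test_that("repair yields consistency with the promised growth direction, idempotently", {
  for (seed in 1:15) {
    sim <- simulate_orthology(4, 3, 4, corruption_rate = 0.3, seed = seed)
    for (strat in c("merge_up", "split_down")) {
      fixed <- enforce_consistency(sim$groups, sim$tree, strat)
      expect_true(is_consistent(fixed, sim$tree))
      for (cl in unique(sim$groups$assignments$clade_id)) {
        before <- groups_vec(sim$groups, cl)
        after <- groups_vec(fixed, cl)
        if (strat == "merge_up") {
          # original groups are never broken apart (they may only fuse)
          expect_true(partition_refines(before, after))
        } else {
          # result groups are fragments of the originals
          expect_true(partition_refines(after, before))
        }
      }
      again <- enforce_consistency(fixed, sim$tree, strat)
      expect_identical(again$assignments, fixed$assignments)
    }
  }
})

test_that("transfer happens at the lowest common clade and skips orphan edges", {
  tree <- toy_tree()
  sp <- c(a1 = "spA", a2 = "spA", b1 = "spB", c1 = "spC", d1 = "spD")
  # groups at both levels: AB resolves spA/spB, root resolves the rest
  grp <- ortholog_groups(data.frame(
    clade_id = c("AB", "AB", "AB", "root", "root", "root", "root", "root"),
    group_id = c("ab1", "ab1", "ab2", "R1", "R1", "R1", "R2", "R2"),
    protein_id = c("a1", "b1", "a2", "a1", "b1", "c1", "a2", "d1")), sp, tree)
  src <- data.frame(gene_a = "a1", gene_b = "a2", combined = 0.8)

  # spA -> spB uses clade AB; a2's group ab2 has no spB member -> skipped
  out <- transfer_interactions(src, "spA", "spB", grp, tree,
                               transfer_config(gamma = 0.5, min_transferred_score = 0))
  expect_identical(attr(out, "clade"), "AB")
  expect_identical(nrow(out), 0L)
  expect_identical(attr(out, "skipped")$reason, "no ortholog in target species")

  # spA -> spC uses the root: a1 -> c1 (R1), a2 -> d1 is not spC -> skipped
  out2 <- transfer_interactions(src, "spA", "spC", grp, tree,
                                transfer_config(0.5, 0))
  expect_identical(attr(out2, "clade"), "root")
  expect_identical(nrow(out2), 0L)
})

test_that("paralog fan-out matches the closed form and merges by noisy-OR", {
  tree <- clade_tree("root", NA, list(root = c("spA", "spB")))
  sp <- c(a1 = "spA", a2 = "spA", b1 = "spB", b2 = "spB", b3 = "spB", b4 = "spB")
  grp <- ortholog_groups(data.frame(
    clade_id = "root",
    group_id = c("G1", "G2", "G1", "G1", "G2", "G2"),
    protein_id = c("a1", "a2", "b1", "b2", "b3", "b4")), sp, tree)
  src <- data.frame(gene_a = "a1", gene_b = "a2", combined = 0.8)
  out <- transfer_interactions(src, "spA", "spB", grp, tree,
                               transfer_config(gamma = 0.5, min_transferred_score = 0))
  expect_identical(nrow(out), 4L)                    # 2 x 2 target pairs
  expect_equal(out$combined, rep(0.8 / sqrt(4), 4))  # S * (n_a n_b)^(-1/2)
  # gamma = 0 conserves the score
  out0 <- transfer_interactions(src, "spA", "spB", grp, tree,
                                transfer_config(gamma = 0, min_transferred_score = 0))
  expect_equal(out0$combined, rep(0.8, 4))
  # the minimum-score floor drops weak transfers
  floor_cfg <- transfer_config(gamma = 0.5, min_transferred_score = 0.5)
  expect_identical(nrow(transfer_interactions(src, "spA", "spB", grp, tree,
                                              floor_cfg)), 0L)
})

test_that("1:1 round-trip transfer reproduces the source network exactly", {
  tree <- clade_tree("root", NA, list(root = c("spA", "spB")))
  sp <- c(a1 = "spA", a2 = "spA", a3 = "spA", b1 = "spB", b2 = "spB", b3 = "spB")
  grp <- ortholog_groups(data.frame(
    clade_id = "root",
    group_id = rep(c("G1", "G2", "G3"), 2),
    protein_id = c("a1", "a2", "a3", "b1", "b2", "b3")), sp, tree)
  src <- data.frame(gene_a = c("a1", "a1", "a2"),
                    gene_b = c("a2", "a3", "a3"),
                    combined = c(0.9, 0.4, 0.6))
  cfg <- transfer_config(gamma = 0.5, min_transferred_score = 0)
  there <- transfer_interactions(src, "spA", "spB", grp, tree, cfg)
  back <- transfer_interactions(there, "spB", "spA", grp, tree, cfg)
  expect_identical(back$gene_a, src$gene_a)
  expect_identical(back$gene_b, src$gene_b)
  expect_equal(back$combined, src$combined, tolerance = 1e-12)
  expect_error(transfer_interactions(src, "spX", "spB", grp, tree, cfg),
               "unknown species")
})
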