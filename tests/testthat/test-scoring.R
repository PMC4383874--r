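test_that("pair labeling follows pathway co-membership", {
  gold <- gold_standard(c("g1", "g2", "g3", "g3"), c("P1", "P1", "P2", "P3"))
  pairs <- data.frame(gene_a = c("g1", "g1", "g1"),
                      gene_b = c("g2", "g3", "g9"),
                      r = c(0.9, 0.5, 0.1))
  lab <- label_pairs(pairs, gold)
  expect_identical(nrow(lab), 2L)                       # g9 unannotated
  expect_identical(lab$label, c(1L, 0L))
  expect_identical(attr(lab, "n_unbenchmarkable"), 1L)
})

test_that("degenerate calibrations behave: all-positive labels, short input", {
  set.seed(6)
  r <- stats::runif(200, -1, 1)
  all_pos <- data.frame(r = r, label = 1L)
  cur <- calibrate(all_pos, 50L)
  expect_true(all(cur$knots$posterior == 1))
  expect_equal(cur$prior, 1)
  expect_error(calibrate(all_pos[1:30, ], 50L), "window")
  expect_error(calibrate(all_pos, 10L), ">= 50")
})

test_that("calibration of label-free noise stays near the prior", {
  set.seed(7)
  n <- 5000; w <- 200
  lab <- data.frame(r = stats::runif(n, -1, 1),
                    label = stats::rbinom(n, 1, 0.3))
  cur <- calibrate(lab, w)
  bound <- 3 * sqrt(0.3 * 0.7 / w)
  expect_true(all(abs(cur$knots$posterior - 0.3) < bound + 0.02))
  expect_false(is.unsorted(cur$knots$posterior))
})

test_that("calibrated scoring interpolates linearly and monotonically", {
  cur <- structure(list(knots = data.frame(raw = c(0, 0.5, 1),
                                           posterior = c(0.2, 0.4, 0.9)),
                        window_size = 50L, prior = 0.3),
                   class = "calibration_curve")
  expect_equal(calibrated_score(cur, 0.5), 0.4)       # knot hit
  expect_equal(calibrated_score(cur, 0.25), 0.3)      # midway interpolation
  expect_equal(calibrated_score(cur, -2), 0.2)        # clamped below
  expect_equal(calibrated_score(cur, 2), 0.9)         # clamped above
  set.seed(8)
  for (i in 1:20) {
    raws <- sort(stats::runif(6, -1, 1))
    post <- cummax(stats::runif(6))
    cv <- structure(list(knots = data.frame(raw = raws, posterior = post),
                         window_size = 50L, prior = 0.2),
                    class = "calibration_curve")
    probes <- sort(stats::runif(50, -1.2, 1.2))
    expect_false(is.unsorted(calibrated_score(cv, probes)))
  }
})

test_that("noisy-OR combination matches hand-evaluated closed forms", {
  expect_equal(combine_scores(0.42, 0.1), 0.42, tolerance = 1e-12)  # single channel
  expect_equal(combine_scores(c(0.5, 0.5), 0), 0.75)
  expect_equal(combine_scores(c(0.6, 0.4), 0.1), 19 / 27 * 0.9 + 0.1,
               tolerance = 1e-12)
  expect_equal(combine_scores(c(0.6, NA), 0.1), 0.6)        # absent channel
  expect_error(combine_scores(0.5, 1), "prior")
  # scores below the prior are floored at the prior
  expect_equal(combine_scores(c(0.05, 0.6), 0.1), 0.6)
})

test_that("combination is commutative, monotone, and dominates its inputs", {
  set.seed(9)
  for (i in 1:200) {
    prior <- stats::runif(1, 0, 0.5)
    s <- stats::runif(sample(2:4, 1), prior, 0.999)
    c1 <- combine_scores(s, prior)
    expect_equal(c1, combine_scores(rev(s), prior), tolerance = 1e-12)
    expect_gte(c1 + 1e-12, max(s))
    bumped <- s; bumped[1] <- min(0.999, s[1] + 0.1)
    expect_gte(combine_scores(bumped, prior) + 1e-12, c1)
    # associativity through the corrected space: combining in two stages
    ab <- combine_scores(s[1:2], prior)
    expect_equal(combine_scores(c(ab, s[-(1:2)]), prior), c1, tolerance = 1e-9)
  }
})

test_that("ROC handles perfect, random and fully-tied rankings", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  tied <- roc_curve(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(tied$auc, 0.5)
  expect_identical(nrow(tied$points), 2L)               # one step
  expect_error(roc_curve(c(0.1, 0.9), c(1, 1)), "both classes")
  set.seed(10)
  sc <- stats::runif(10000); lb <- stats::rbinom(10000, 1, 0.4)
  rnd <- roc_curve(sc, lb)
  expect_equal(rnd$auc, 0.5, tolerance = 0.02)
  # monotone points and trapezoid-consistent AUC
  expect_false(is.unsorted(rnd$points$fpr))
  expect_false(is.unsorted(rnd$points$tpr))
  expect_equal(rnd$auc, mann_whitney_auc(sc, lb), tolerance = 1e-9)
})

test_that("scored networks outer-join channels and render both score scales", {
  single <- data.frame(gene_a = c("a", "a"), gene_b = c("b", "c"),
                       score = c(0.6, 0.3))
  dual <- data.frame(gene_a = "a", gene_b = "b", score = 0.4)
  net <- scored_network(list(single = single, dual = dual), prior = 0.1)
  expect_equal(net$combined[net$gene_b == "b"], combine_scores(c(0.6, 0.4), 0.1))
  expect_equal(net$combined[net$gene_b == "c"], 0.3)     # one channel only
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scored_network(net, path)
  txt <- read.delim(path, colClasses = "character")
  expect_identical(txt$score_single, c("0.600", "0.300"))
  write_scored_network(net, path, string_convention = TRUE)
  txt2 <- read.delim(path)
  expect_identical(txt2$score_single, c(600L, 300L))
})
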