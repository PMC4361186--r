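test_that("UPGMA reproduces hand agglomerations and refuses masked input", {
  labs <- c("A", "B", "C")
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3, dimnames = list(labs, labs))
  tr <- upgma_tree(dm_from_matrix(D))
  cp <- cophenetic(tr)[labs, labs]
  expect_equal(cp, D, tolerance = 1e-12)
  # rooted and ultrametric: ((A:1,B:1):1,C:2)
  expect_true(ape::is.rooted(tr))
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)

  labs2 <- c("A", "B")
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(labs2, labs2))
  tr2 <- upgma_tree(dm_from_matrix(D2))
  expect_equal(sort(tr2$edge.length), c(0.2, 0.2))

  Dm <- dm_from_matrix(D)
  Dm$defined["A", "B"] <- Dm$defined["B", "A"] <- FALSE
  expect_error(upgma_tree(Dm), "masked")
  expect_error(nj_tree(Dm), "masked")
})

test_that("NJ recovers the generating tree from an additive matrix", {
  labs <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(labs, labs))
  D["A", "B"] <- 3; D["A", "C"] <- 8; D["A", "D"] <- 9
  D["B", "C"] <- 9; D["B", "D"] <- 10; D["C", "D"] <- 9
  D <- D + t(D)
  tr <- nj_tree(dm_from_matrix(D))
  expect_equal(cophenetic(tr)[labs, labs], D, tolerance = 1e-9)
  # the AB|CD split must be present with internal length 3
  expect_true(is_monophyletic(tr, c("A", "B"))$monophyletic)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_equal(tr$edge.length[internal], 3, tolerance = 1e-9)
})

test_that("NJ closed form on three taxa and the zero/degenerate cases", {
  labs <- c("A", "B", "C")
  D <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3, dimnames = list(labs, labs))
  tr <- nj_tree(dm_from_matrix(D))
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["A"]), (2 + 3 - 5) / 2, tolerance = 1e-12)
  expect_equal(unname(bl["B"]), (2 + 5 - 3) / 2, tolerance = 1e-12)
  expect_equal(unname(bl["C"]), (3 + 5 - 2) / 2, tolerance = 1e-12)

  Z <- matrix(0, 3, 3, dimnames = list(labs, labs))
  trz <- nj_tree(dm_from_matrix(Z))
  expect_true(all(trz$edge.length == 0))

  # two taxa: single split edge
  D2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- nj_tree(dm_from_matrix(D2))
  expect_equal(sum(tr2$edge.length), 1)
})

test_that("NJ agrees with ape::nj on random matrices", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    tr0 <- ape::rtree(n)
    D <- cophenetic(tr0)
    ord <- sample(rownames(D))
    D <- D[ord, ord]
    mine <- nj_tree(dm_from_matrix(D))
    ref <- ape::nj(as.dist(D))
    expect_equal(cophenetic(mine)[ord, ord], cophenetic(ref)[ord, ord],
                 tolerance = 1e-8)
  }
})

test_that("negative NJ branch estimates are clamped and flagged", {
  labs <- c("A", "B", "C", "D")
  # strongly non-additive matrix known to give a negative pendant estimate
  D <- matrix(c(0, 1, 1, 1,
                1, 0, 1, 1,
                1, 1, 0, 0.1,
                1, 1, 0.1, 0), 4, 4, dimnames = list(labs, labs))
  tr <- nj_tree(dm_from_matrix(D))
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports: no-variance alignments give 100, single rep is 0/100", {
  # 20 informative columns (A/A/G/G) + 60 constant columns: every plausible
  # resample yields the same ((a1,a2),(b1,b2)) topology
  seqs <- c(paste0(strrep("A", 20), strrep("C", 60)),
            paste0(strrep("A", 20), strrep("C", 60)),
            paste0(strrep("G", 20), strrep("C", 60)),
            paste0(strrep("G", 20), strrep("C", 60)))
  aln <- marker_alignment(c("a1", "a2", "b1", "b2"),
                          c("A", "A", "B", "B"), seqs, "m")
  tr <- bootstrap_supports(aln, "upgma", n_reps = 20, seed = 1)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  tr1 <- bootstrap_supports(aln, "nj", n_reps = 1, seed = 9)
  sup1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 100)))
})

test_that("bootstrap is reproducible by seed and stable across seeds", {
  set.seed(31)
  aln <- random_toy_alignment(8, 200, 4)
  t1 <- bootstrap_supports(aln, "nj", n_reps = 50, seed = 123)
  t2 <- bootstrap_supports(aln, "nj", n_reps = 50, seed = 123)
  expect_identical(t1$node.label, t2$node.label)

  # different seeds: supports within binomial sampling error
  t3 <- bootstrap_supports(aln, "nj", n_reps = 400, seed = 124)
  t4 <- bootstrap_supports(aln, "nj", n_reps = 400, seed = 125)
  s3 <- suppressWarnings(as.numeric(t3$node.label)) / 100
  s4 <- suppressWarnings(as.numeric(t4$node.label)) / 100
  keep <- !is.na(s3) & !is.na(s4)
  se <- sqrt(pmax(s3[keep] * (1 - s3[keep]), 0.25 / 400) / 400) +
        sqrt(pmax(s4[keep] * (1 - s4[keep]), 0.25 / 400) / 400)
  expect_true(all(abs(s3[keep] - s4[keep]) <= 4 * se + 0.01))
})
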