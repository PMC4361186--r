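test_that("species tree: shape, depth, radiation compression, determinism", {
  tr <- simulate_species_tree(5, tree_depth = 0.02, radiation_scale = 1,
                              seed = 4)
  expect_equal(length(tr$tip.label), 5L)
  expect_equal(tr$Nnode, 4L)
  depths <- ape::node.depth.edgelength(tr)[1:5]
  expect_true(all(abs(depths - 0.02) < 1e-9))

  # radiation_scale 0: all internal branches collapse
  tr0 <- simulate_species_tree(6, 0.02, radiation_scale = 0, seed = 4)
  n <- length(tr0$tip.label)
  internal <- tr0$edge[, 2] > n
  expect_true(all(tr0$edge.length[internal] < 1e-12))
  # still ultrametric at full depth
  d0 <- ape::node.depth.edgelength(tr0)[1:n]
  expect_true(all(abs(d0 - 0.02) < 1e-9))

  # intermediate scale multiplies internal branches exactly
  trA <- simulate_species_tree(8, 0.02, radiation_scale = 1, seed = 9)
  trB <- simulate_species_tree(8, 0.02, radiation_scale = 0.25, seed = 9)
  iA <- trA$edge[, 2] > 8
  expect_equal(trB$edge.length[iA], 0.25 * trA$edge.length[iA],
               tolerance = 1e-12)

  expect_identical(write_newick(simulate_species_tree(7, 0.01, 0.5, seed = 2)),
                   write_newick(simulate_species_tree(7, 0.01, 0.5, seed = 2)))
  expect_false(identical(
    write_newick(simulate_species_tree(7, 0.01, 0.5, seed = 2)),
    write_newick(simulate_species_tree(7, 0.01, 0.5, seed = 3))))
  expect_error(simulate_species_tree(1, 0.01), "at least 2")
})

test_that("gene trees: leaf counts, concordance at small theta, discordance at large", {
  sp_tree <- simulate_species_tree(5, 0.05, 1, seed = 21)
  samples <- setNames(rep(3L, 5), sp_tree$tip.label)
  gt <- simulate_gene_tree(sp_tree, samples, coalescent_theta = 0.01, seed = 1)
  expect_equal(length(gt$tip.label), 15L)
  spof <- attr(gt, "species_of")
  expect_equal(sort(unique(unname(spof))), sort(sp_tree$tip.label))

  # theta -> 0: every species monophyletic in every gene tree
  mono_frac <- function(theta, seeds) {
    mean(vapply(seeds, function(s) {
      g <- simulate_gene_tree(sp_tree, samples, theta, seed = s)
      so <- attr(g, "species_of")
      all(vapply(unique(so), function(x)
        is_monophyletic(g, names(so)[so == x])$monophyletic, TRUE))
    }, TRUE))
  }
  expect_equal(mono_frac(1e-9, 1:25), 1)
  # large theta: discordance appears
  expect_lt(mono_frac(0.5, 1:25), 1)
  expect_error(simulate_gene_tree(sp_tree, samples, -1), ">= 0")
})

test_that("gene-tree branch lengths are consistent with species divergence times", {
  # two species, theta ~ 0: pairwise cross-species path length ~ 2 * depth
  sp_tree <- simulate_species_tree(2, 0.1, 1, seed = 5)
  samples <- setNames(c(2L, 2L), sp_tree$tip.label)
  gt <- simulate_gene_tree(sp_tree, samples, 1e-12, seed = 8)
  cp <- cophenetic(gt)
  so <- attr(gt, "species_of")
  cross <- cp[so[rownames(cp)] == so[[1]], so[colnames(cp)] != so[[1]]]
  expect_true(all(abs(cross - 0.2) < 1e-6))
})

test_that("introgression: probability gate, non-monophyly, determinism", {
  sp_tree <- simulate_species_tree(4, 0.05, 1, seed = 31)
  samples <- setNames(rep(3L, 4), sp_tree$tip.label)
  gt <- simulate_gene_tree(sp_tree, samples, 1e-6, seed = 2)

  r0 <- apply_introgression(gt, sp_tree, introgression_prob = 0, seed = 3)
  expect_identical(write_newick(r0$tree), write_newick(gt))
  expect_equal(nrow(r0$events), 0L)

  r1 <- apply_introgression(gt, sp_tree, introgression_prob = 1, seed = 3)
  expect_equal(nrow(r1$events), 1L)
  so <- attr(r1$tree, "species_of")
  rec_tips <- names(so)[so == r1$events$recipient]
  expect_false(is_monophyletic(r1$tree, rec_tips)$monophyletic)
  # recipient lineages nest inside the donor clade: recipient + donor tips
  # together form a clade on the unchanged remainder of the tree
  don_tips <- names(so)[so == r1$events$donor]
  expect_true(is_monophyletic(r1$tree, c(rec_tips, don_tips))$monophyletic)

  r2 <- apply_introgression(gt, sp_tree, introgression_prob = 1, seed = 3)
  expect_identical(r2$events, r1$events)
  expect_identical(write_newick(r2$tree), write_newick(r1$tree))
})

test_that("sequence evolution: zero rate copies the root, distances track path lengths", {
  tr <- read_newick(text = "((a:0.02,b:0.02):0.03,(c:0.04,d:0.04):0.01);")
  spof <- setNames(c("A", "A", "B", "B"), letters[1:4])
  aln0 <- evolve_alignment(tr, 200, kappa = 2, rate_multiplier = 0, seed = 1,
                           species_of = spof)
  expect_equal(length(unique(unname(aln0$seq))), 1L)

  # estimator consistency: d(a,b) ~ 0.04 over many sites
  tr2 <- read_newick(text = "(a:0.05,b:0.05);")
  spof2 <- setNames(c("A", "B"), c("a", "b"))
  aln <- evolve_alignment(tr2, 50000, kappa = 2, rate_multiplier = 1,
                          seed = 2, species_of = spof2)
  r <- k2p_distance(aln$seq[["a"]], aln$seq[["b"]])
  se <- sqrt(0.1 / 50000)
  expect_lt(abs(r$d - 0.1), 3 * se + 0.002)

  # extreme kappa: transversions vanish at small t
  alnk <- evolve_alignment(tr2, 20000, kappa = 1e6, rate_multiplier = 1,
                           seed = 3, species_of = spof2)
  rk <- k2p_distance(alnk$seq[["a"]], alnk$seq[["b"]])
  expect_lt(rk$Q, 1e-3)
  expect_gt(rk$P, 0.05)
})

test_that("simulate_dataset: bounds, missingness, determinism", {
  cfg <- simulation_config(n_species = 8, seed = 77, missing_prob = 0)
  sd1 <- simulate_dataset(cfg)
  n_acc <- length(sd1$dataset$species_of)
  expect_gte(n_acc, 8 * 3)
  expect_lte(n_acc, 8 * 6)
  # no missing data: every marker carries every accession
  for (a in sd1$dataset$alignments)
    expect_equal(length(a$accession), n_acc)
  # gene-tree leaves match the accessions sampled per marker
  for (mk in names(sd1$dataset$alignments))
    expect_setequal(sd1$gene_trees[[mk]]$tip.label,
                    sd1$dataset$alignments[[mk]]$accession)

  sd2 <- simulate_dataset(cfg)
  expect_identical(sd1$dataset, sd2$dataset)
  expect_identical(write_newick(sd1$species_tree),
                   write_newick(sd2$species_tree))

  cfgm <- simulation_config(n_species = 8, seed = 77, missing_prob = 0.2)
  sdm <- simulate_dataset(cfgm)
  n_per <- vapply(sdm$dataset$alignments,
                  function(a) length(a$accession), 0L)
  expect_true(any(n_per < length(sdm$dataset$species_of)))
})

test_that("per-marker variability ranks follow the configured rate order", {
  # two markers, 10x rate apart: variable-site counts must rank accordingly
  cfg <- simulation_config(
    n_species = 10, seed = 13, missing_prob = 0,
    markers = data.frame(name = c("slow", "fast"),
                         length = c(800L, 800L),
                         rate_multiplier = c(1, 10)))
  sd1 <- simulate_dataset(cfg)
  v <- vapply(sd1$dataset$alignments,
              function(a) marker_profile(a)$n_variable_sites, 0L)
  expect_lt(v[["slow"]], v[["fast"]])
})
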