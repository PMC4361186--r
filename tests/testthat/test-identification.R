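test_that("nearest-rank percentile threshold", {
  expect_equal(intraspecific_threshold(1:20, 95), 19)
  expect_equal(intraspecific_threshold(0.01, 50), 0.01)
  expect_equal(intraspecific_threshold(c(3, 1, 2), 100), 3)
  expect_error(intraspecific_threshold(numeric()), "unavailable")
})

.toy_dm <- function(d, sp) {
  labs <- names(sp)
  D <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (k in seq_len(nrow(d))) {
    D[d$a[k], d$b[k]] <- D[d$b[k], d$a[k]] <- d$dist[k]
  }
  dm_from_matrix(D)
}

test_that("identify_query reproduces the worked toy cases", {
  sp <- c(A1 = "A", A2 = "A", A3 = "A", B1 = "B")
  d <- data.frame(a = c("A3", "A3", "A3", "A1", "A1", "A2"),
                  b = c("A1", "A2", "B1", "A2", "B1", "B1"),
                  dist = c(0.01, 0.02, 0.20, 0.015, 0.21, 0.22))
  dm <- .toy_dm(d, sp)
  r <- identify_query("A3", dm, sp, "best_match")
  expect_equal(r$outcome, "correct")
  expect_equal(r$matched_species, "A")
  expect_equal(r$best_distance, 0.01)

  # tie across species: ambiguous
  d2 <- d; d2$dist[d2$a == "A3" & d2$b == "B1"] <- 0.01
  r2 <- identify_query("A3", .toy_dm(d2, sp), sp, "best_match")
  expect_equal(r2$outcome, "ambiguous")

  # nearest reference beyond the threshold: no_match
  d3 <- data.frame(a = "A3", b = "B1", dist = 0.30)
  sp3 <- c(A3 = "A", B1 = "B")
  r3 <- identify_query("A3", .toy_dm(d3, sp3), sp3, "best_close_match",
                       threshold = 0.05)
  expect_equal(r3$outcome, "no_match")

  # all species barcodes: S equals the full conspecific set
  r4 <- identify_query("A3", dm, sp, "all_species_barcodes", threshold = 0.05)
  expect_equal(r4$outcome, "correct")
  # with only one conspecific reference sampled: no_conspecific
  sp5 <- c(A3 = "A", A1 = "A", B1 = "B")
  d5 <- data.frame(a = c("A3", "A3", "A1"), b = c("A1", "B1", "B1"),
                   dist = c(0.01, 0.2, 0.21))
  r5 <- identify_query("A3", .toy_dm(d5, sp5), sp5, "all_species_barcodes",
                       threshold = 0.05)
  expect_equal(r5$outcome, "no_conspecific")
})

test_that("undefined distances never match and empty reference sets degrade", {
  sp <- c(A1 = "A", A2 = "A", B1 = "B")
  D <- matrix(0.1, 3, 3, dimnames = list(names(sp), names(sp)))
  diag(D) <- 0
  def <- matrix(TRUE, 3, 3, dimnames = dimnames(D))
  def["A1", ] <- def[, "A1"] <- FALSE
  diag(def) <- TRUE
  dm <- dm_from_matrix(D, def)
  r <- identify_query("A1", dm, sp, "best_match")
  expect_equal(r$outcome, "no_match")
  expect_true(is.na(r$best_distance))
})

test_that("success rates on separable and degenerate datasets", {
  # 2 species x 2 accessions, intra ~ 0.01, inter ~ 0.3
  aln <- marker_alignment(
    c("A1", "A2", "B1", "B2"), c("A", "A", "B", "B"),
    c(strrep("A", 100),
      paste0(strrep("A", 99), "G"),
      strrep("T", 100),
      paste0(strrep("T", 99), "C")), "toy")
  sr <- identification_success_rates(aln)
  bm <- sr$per_criterion[sr$per_criterion$criterion == "best_match", ]
  expect_equal(bm$pct_correct, 100)
  expect_equal(bm$n_queries, 4L)

  # all sequences identical: every best-match query is ambiguous
  aln2 <- marker_alignment(c("A1", "A2", "B1", "B2"), c("A", "A", "B", "B"),
                           rep(strrep("ACGT", 10), 4), "toy")
  sr2 <- identification_success_rates(aln2, criteria = "best_match")
  expect_equal(sr2$per_criterion$n_ambiguous, 4L)
  expect_equal(sr2$per_criterion$pct_correct, 0)
})

test_that("best close match never beats best match", {
  set.seed(23)
  for (rep in 1:20) {
    aln <- random_toy_alignment(sample(4:8, 1), 60, 3)
    # some random labelings have no conspecific pairs: threshold warning ok
    sr <- suppressWarnings(identification_success_rates(
      aln, criteria = c("best_match", "best_close_match")))
    tab <- sr$per_criterion
    expect_lte(tab$n_correct[tab$criterion == "best_close_match"],
               tab$n_correct[tab$criterion == "best_match"])
    expect_true(all(rowSums(tab[, c("n_correct", "n_ambiguous", "n_incorrect",
                                    "n_no_match", "n_no_conspecific")]) ==
                    tab$n_queries))
  }
})

test_that("outcomes are invariant to accession order and joint distance scaling", {
  set.seed(29)
  aln <- random_toy_alignment(6, 80, 2)
  dm <- build_distance_matrix(aln)
  thr <- intraspecific_threshold(
    partition_distances(dm, aln$species)$intra, 95)
  base <- vapply(aln$accession, function(q)
    identify_query(q, dm, aln$species, "best_close_match", thr)$outcome, "")
  # scale all distances and the threshold by the same factor
  dm2 <- dm; dm2$d <- dm$d * 7
  scaled <- vapply(aln$accession, function(q)
    identify_query(q, dm2, aln$species, "best_close_match", 7 * thr)$outcome, "")
  expect_identical(base, scaled)
  # permute accession order
  ord <- sample(length(aln$accession))
  aln3 <- marker_alignment(aln$accession[ord], unname(aln$species[ord]),
                           unname(aln$seq[ord]), aln$marker)
  dm3 <- build_distance_matrix(aln3)
  perm <- vapply(aln$accession, function(q)
    identify_query(q, dm3, aln3$species, "best_close_match", thr)$outcome, "")
  expect_identical(base[sort(names(base))], perm[sort(names(perm))])
})
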