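# Multispecies-coalescent synthetic-data generator.
#
# Emulates a recently radiated clade: a Yule species tree whose internal
# branches can be compressed toward a star phylogeny, per-marker gene trees
# drawn under the multispecies coalescent (so incomplete lineage sorting
# appears when internal branches are short relative to theta), optional
# introgression events that move one species' lineages into a donor's
# branch, and K80 sequence evolution at marker-specific rates. Time is
# expressed directly in expected substitutions/site of the slowest marker.

#' Default marker profile for the generator
#'
#' Five markers emulating a typical plastid + ITS barcoding panel: aligned
#' lengths 1415, 847, 423, 927 and 668 bp and relative substitution rates
#' ordered rbcL < trnL-F < matK < trnH-psbA < ITS.
#'
#' @return A data.frame with columns `name`, `length`, `rate_multiplier`.
#' @export
default_marker_profile <- function() {
  data.frame(
    name = c("rbcL", "matK", "trnH-psbA", "trnL-F", "ITS"),
    length = c(1415L, 847L, 423L, 927L, 668L),
    rate_multiplier = c(1, 2.25, 6.5, 1.9, 9),
    stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' Defaults describe the study conditions the package is designed around:
#' 47 species with 3-6 accessions each, the five-marker profile of
#' [default_marker_profile()], shallow divergence (root-to-tip depth 0.0015
#' substitutions/site at the slowest marker, which reproduces mean
#' interspecific K2P distances of roughly 0.004 at the slowest and 0.04 at
#' the fastest marker), compressed internal branches
#' (`radiation_scale = 0.3`), and enough coalescent noise
#' (`coalescent_theta = 0.001`, on the order of the species pendant
#' branches) to produce incomplete lineage sorting.
#'
#' @param n_species Number of species (>= 2).
#' @param accessions_min,accessions_max Per-species accession count range.
#' @param markers data.frame with `name`, `length`, `rate_multiplier`.
#' @param kappa Transition/transversion rate ratio of the K80 model.
#' @param tree_depth Root-to-tip depth, in expected substitutions/site at
#'   the slowest marker (`rate_multiplier = 1`).
#' @param radiation_scale Factor in `[0, 1]` multiplying internal branch
#'   lengths; 0 approaches a star phylogeny.
#' @param coalescent_theta Coalescent population-size parameter (same time
#'   units); lineages within a species-tree branch coalesce at rate
#'   `choose(k, 2) / theta`. 0 forces concordant gene trees.
#' @param introgression_prob Per-marker probability of one introgression
#'   event.
#' @param missing_prob Per accession-by-marker dropout probability in
#'   `[0, 1)`.
#' @param seed Integer seed; identical configs give identical datasets.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 47L,
                              accessions_min = 3L, accessions_max = 6L,
                              markers = default_marker_profile(),
                              kappa = 2,
                              tree_depth = 0.0015,
                              radiation_scale = 0.3,
                              coalescent_theta = 0.001,
                              introgression_prob = 0,
                              missing_prob = 0.03,
                              seed = 1L) {
  stopifnot(n_species >= 2L, accessions_min >= 1L,
            accessions_max >= accessions_min,
            is.data.frame(markers), nrow(markers) >= 1L,
            all(c("name", "length", "rate_multiplier") %in% names(markers)),
            all(markers$length > 0), all(markers$rate_multiplier > 0),
            kappa > 0, tree_depth > 0,
            radiation_scale >= 0, radiation_scale <= 1,
            coalescent_theta >= 0,
            introgression_prob >= 0, introgression_prob <= 1,
            missing_prob >= 0, missing_prob < 1)
  if (anyDuplicated(markers$name)) stop("marker names must be unique", call. = FALSE)
  structure(list(n_species = as.integer(n_species),
                 accessions_min = as.integer(accessions_min),
                 accessions_max = as.integer(accessions_max),
                 markers = markers, kappa = kappa, tree_depth = tree_depth,
                 radiation_scale = radiation_scale,
                 coalescent_theta = coalescent_theta,
                 introgression_prob = introgression_prob,
                 missing_prob = missing_prob, seed = as.integer(seed)),
            class = "simulation_config")
}

# heights above the tips for every node of an ultrametric rooted tree
.node_heights <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)   # distance from root
  max(depths[seq_along(tree$tip.label)]) - depths
}

#' Simulate a species tree under a compressible Yule model
#'
#' Draws a pure-birth topology, rescales it so the root-to-tip depth equals
#' `tree_depth`, then compresses internal node heights toward the root so
#' every internal branch length is multiplied by `radiation_scale` while the
#' tree stays ultrametric (pendant branches absorb the difference;
#' `radiation_scale = 0` collapses all internal branches, the star-phylogeny
#' regime of a hard radiation).
#'
#' @param n_species Number of species (>= 2).
#' @param tree_depth Root-to-tip depth (substitutions/site, slowest marker).
#' @param radiation_scale Internal-branch multiplier in `[0, 1]`.
#' @param seed Integer seed.
#' @param species Optional tip labels (default `Sim_sp01`, ...).
#' @return A rooted ultrametric [ape::phylo] tree.
#' @export
simulate_species_tree <- function(n_species, tree_depth, radiation_scale = 1,
                                  seed = 1L, species = NULL) {
  if (n_species < 2L) stop("need at least 2 species", call. = FALSE)
  stopifnot(tree_depth > 0, radiation_scale >= 0, radiation_scale <= 1)
  if (is.null(species))
    species <- sprintf("Sim_sp%02d", seq_len(n_species))
  stopifnot(length(species) == n_species)
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  tr$tip.label <- species[as.integer(sub("^t", "", tr$tip.label))]
  h <- .node_heights(tr)
  tr$edge.length <- tr$edge.length * (tree_depth / max(h))
  h <- .node_heights(tr)
  n <- length(tr$tip.label)
  hh <- h
  internal <- seq(n + 1L, n + tr$Nnode)
  hh[internal] <- tree_depth * (1 - radiation_scale) +
    radiation_scale * h[internal]
  tr$edge.length <- hh[tr$edge[, 1L]] - hh[tr$edge[, 2L]]
  tr
}

# draw a coalescent history for `lin` lineages (list of rlist nodes with a
# `height` attribute) inside a branch spanning [t0, t1]
.coalesce_interval <- function(lin, t0, t1, theta) {
  t <- t0
  while (length(lin) >= 2L) {
    k <- length(lin)
    if (theta == 0) {
      tnew <- t
    } else {
      dt <- rexp(1L, rate = k * (k - 1) / 2 / theta)
      tnew <- t + dt
      if (tnew > t1) break
    }
    pick <- sample.int(k, 2L)
    a <- lin[[pick[1L]]]; b <- lin[[pick[2L]]]
    a$node$length <- tnew - a$height
    b$node$length <- tnew - b$height
    merged <- list(node = .rnode(children = list(a$node, b$node)),
                   height = tnew)
    lin <- c(lin[-pick], list(merged))
    t <- tnew
  }
  lin
}

#' Simulate a gene tree under the multispecies coalescent
#'
#' Within each species-tree branch, sampled lineages coalesce at rate
#' `choose(k, 2) / theta` (time in the species tree's substitution units);
#' lineages that fail to coalesce before the branch's top propagate into the
#' parent branch, and everything coalesces above the root. `theta = 0`
#' forces topological concordance with the species tree.
#'
#' @param species_tree Ultrametric rooted [ape::phylo] with species tips.
#' @param samples_per_species Either a named integer vector (species ->
#'   sample count; accessions are auto-named `species.1`, ...) or a named
#'   list of accession-id vectors.
#' @param coalescent_theta Non-negative coalescent parameter.
#' @param seed Integer seed.
#' @return A rooted [ape::phylo] gene tree whose tips are accessions, with
#'   attribute `species_of` (named accession -> species vector).
#' @export
simulate_gene_tree <- function(species_tree, samples_per_species,
                               coalescent_theta, seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"))
  if (coalescent_theta < 0) stop("theta must be >= 0", call. = FALSE)
  if (!is.list(samples_per_species)) {
    stopifnot(all(samples_per_species >= 1L))
    samples_per_species <- lapply(
      setNames(nm = names(samples_per_species)),
      function(s) sprintf("%s.%d", s, seq_len(samples_per_species[[s]])))
  }
  miss <- setdiff(species_tree$tip.label, names(samples_per_species))
  if (length(miss) > 0L)
    stop(sprintf("no samples given for species '%s'", miss[1L]), call. = FALSE)
  set.seed(seed)
  n <- length(species_tree$tip.label)
  h <- .node_heights(species_tree)
  parent <- integer(n + species_tree$Nnode)
  parent[species_tree$edge[, 2L]] <- species_tree$edge[, 1L]
  root <- n + 1L
  # lineages entering each species-tree node, filled tips-first
  pending <- vector("list", n + species_tree$Nnode)
  for (i in seq_len(n)) {
    sp <- species_tree$tip.label[i]
    ids <- samples_per_species[[sp]]
    pending[[i]] <- lapply(ids, function(id)
      list(node = .rnode(id), height = 0))
  }
  # postorder over edges: every child node is handled before its parent,
  # which matters when radiation compression makes node heights tie
  for (e in ape::postorder(species_tree)) {
    v <- species_tree$edge[e, 2L]
    lin <- pending[[v]]
    if (is.null(lin) || length(lin) == 0L) next
    lin <- .coalesce_interval(lin, h[v], h[parent[v]], coalescent_theta)
    pending[[parent[v]]] <- c(pending[[parent[v]]], lin)
  }
  lin <- .coalesce_interval(pending[[root]], h[root], Inf, coalescent_theta)
  top <- lin[[1L]]$node
  top$length <- NA_real_
  gt <- .rlist_to_phylo(top)
  sp_of <- character()
  for (sp in names(samples_per_species))
    sp_of[samples_per_species[[sp]]] <- sp
  attr(gt, "species_of") <- sp_of[gt$tip.label]
  names(attr(gt, "species_of")) <- gt$tip.label
  gt
}

# replace tip `target` by a cherry (target, newtip) attached at height
# `frac * pendant_length` above the tip
.attach_at_tip <- function(node, target, newtip, frac) {
  if (length(node$children) == 0L) {
    if (identical(node$label, target)) {
      p <- node$length
      hh <- frac * p
      return(.rnode(length = p - hh, children = list(
        .rnode(target, hh), .rnode(newtip, hh))))
    }
    return(node)
  }
  node$children <- lapply(node$children, .attach_at_tip, target = target,
                          newtip = newtip, frac = frac)
  node
}

#' Apply one introgression (organelle-capture-like) event to a gene tree
#'
#' With probability `introgression_prob`, one recipient species' lineages
#' are detached from the gene tree and re-attached onto the pendant edges of
#' a donor species' samples (distinct donor tips are used while available),
#' producing the systematic cross-species association characteristic of
#' post-speciation hybridization and organelle capture. Recipient and donor
#' are drawn among species with at least two samples, so an applied event
#' always leaves the recipient species non-monophyletic in that gene tree.
#'
#' @param gene_tree A gene tree from [simulate_gene_tree()].
#' @param species_tree The species tree (used only for the species list).
#' @param introgression_prob Event probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param species_of Named accession -> species vector; defaults to the
#'   gene tree's `species_of` attribute.
#' @return List with `tree` (the possibly modified gene tree, `species_of`
#'   attribute preserved) and `events` (data.frame with columns `recipient`,
#'   `donor`; zero rows when no event fired).
#' @export
apply_introgression <- function(gene_tree, species_tree, introgression_prob,
                                seed = 1L, species_of = NULL) {
  stopifnot(inherits(gene_tree, "phylo"))
  if (is.null(species_of)) species_of <- attr(gene_tree, "species_of")
  stopifnot(!is.null(species_of))
  set.seed(seed)
  no_event <- list(tree = gene_tree,
                   events = data.frame(recipient = character(),
                                       donor = character(),
                                       stringsAsFactors = FALSE))
  if (runif(1L) >= introgression_prob) return(no_event)
  counts <- table(species_of[gene_tree$tip.label])
  eligible <- names(counts)[counts >= 2L]
  if (length(eligible) < 2L) return(no_event)
  pick <- sample(eligible, 2L)
  recipient <- pick[1L]; donor <- pick[2L]
  rec_tips <- names(species_of)[species_of == recipient]
  rec_tips <- intersect(gene_tree$tip.label, rec_tips)
  don_tips <- names(species_of)[species_of == donor]
  don_tips <- intersect(gene_tree$tip.label, don_tips)
  pruned <- ape::drop.tip(gene_tree, rec_tips)
  rl <- .phylo_to_rlist(pruned)
  targets <- rep(sample(don_tips), length.out = length(rec_tips))
  fracs <- runif(length(rec_tips), 0.1, 0.9)
  for (i in seq_along(rec_tips))
    rl <- .attach_at_tip(rl, targets[i], rec_tips[i], fracs[i])
  out <- .rlist_to_phylo(rl)
  attr(out, "species_of") <- species_of[out$tip.label]
  list(tree = out,
       events = data.frame(recipient = recipient, donor = donor,
                           stringsAsFactors = FALSE))
}

#' Evolve sequences along a gene tree under the K80 model
#'
#' Sites are independent; the root sequence is uniform over A/C/G/T; each
#' branch applies the Kimura two-parameter transition matrix with
#' `branch length * rate_multiplier` expected substitutions per site and
#' transition/transversion rate ratio `kappa`. Output is gap-free.
#'
#' @param gene_tree A rooted [ape::phylo] gene tree.
#' @param length Number of alignment columns (>= 1).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param rate_multiplier Marker rate scaling (>= 0; 0 copies the root draw
#'   to every tip).
#' @param seed Integer seed.
#' @param marker Marker name for the resulting alignment.
#' @param species_of Named accession -> species vector; defaults to the gene
#'   tree's `species_of` attribute.
#' @return A [marker_alignment].
#' @export
evolve_alignment <- function(gene_tree, length, kappa, rate_multiplier = 1,
                             seed = 1L, marker = "sim",
                             species_of = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), length >= 1L, kappa > 0,
            rate_multiplier >= 0)
  if (is.null(species_of)) species_of <- attr(gene_tree, "species_of")
  stopifnot(!is.null(species_of))
  set.seed(seed)
  L <- as.integer(length)
  beta <- 1 / (kappa + 2)
  alpha <- kappa / (kappa + 2)
  pmat <- function(t) {
    e1 <- exp(-4 * beta * t)
    e2 <- exp(-2 * (alpha + beta) * t)
    same <- 0.25 + 0.25 * e1 + 0.5 * e2
    ts <- 0.25 + 0.25 * e1 - 0.5 * e2
    tv <- 0.25 - 0.25 * e1
    P <- matrix(tv, 4L, 4L)
    diag(P) <- same
    for (s in 1:4) P[s, ((s + 1L) %% 4L) + 1L] <- ts   # A<->G, C<->T
    P
  }
  n <- base::length(gene_tree$tip.label)
  nnode <- n + gene_tree$Nnode
  states <- vector("list", nnode)
  root <- n + 1L
  states[[root]] <- sample.int(4L, L, replace = TRUE)
  edges <- reorder(gene_tree, "cladewise")
  for (e in seq_len(nrow(edges$edge))) {
    p <- edges$edge[e, 1L]; ch <- edges$edge[e, 2L]
    t <- edges$edge.length[e] * rate_multiplier
    ps <- states[[p]]
    if (t <= 0) { states[[ch]] <- ps; next }
    P <- pmat(t)
    cs <- integer(L)
    for (s in 1:4) {
      idx <- which(ps == s)
      if (base::length(idx) > 0L)
        cs[idx] <- sample.int(4L, base::length(idx), replace = TRUE,
                              prob = P[s, ])
    }
    states[[ch]] <- cs
  }
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i)
    paste0(bases[states[[i]]], collapse = ""), "")
  acc <- gene_tree$tip.label
  marker_alignment(acc, unname(species_of[acc]), seqs, marker)
}

#' Simulate a complete truth-labeled multi-marker dataset
#'
#' Draws per-species accession counts uniformly in the configured range,
#' simulates the species tree once, then per marker: an independent
#' coalescent gene tree, an optional introgression event, K80 sequences at
#' the marker's rate, and accession-by-marker dropout. Identical
#' configurations produce byte-identical outputs.
#'
#' @param config A [simulation_config].
#' @return An object of class `synthetic_dataset`: `dataset`
#'   ([multimarker_dataset]), `species_tree`, `gene_trees` (marker -> tree),
#'   `event_log` (data.frame marker/recipient/donor) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nmk <- nrow(config$markers)
  ss <- sample.int(2147483646L, 2L + 4L * nmk)
  species <- sprintf("Sim_sp%02d", seq_len(config$n_species))
  set.seed(ss[1L])
  count_range <- seq.int(config$accessions_min, config$accessions_max)
  counts <- count_range[sample.int(length(count_range), config$n_species,
                                   replace = TRUE)]
  samples <- lapply(seq_len(config$n_species), function(i)
    sprintf("sp%02d_%d", i, seq_len(counts[i])))
  names(samples) <- species
  species_of <- character()
  for (sp in species) species_of[samples[[sp]]] <- sp
  sp_tree <- simulate_species_tree(config$n_species, config$tree_depth,
                                   config$radiation_scale, seed = ss[2L],
                                   species = species)
  alns <- list(); gts <- list(); logs <- list()
  for (k in seq_len(nmk)) {
    mk <- config$markers$name[k]
    base <- 2L + 4L * (k - 1L)
    gt <- simulate_gene_tree(sp_tree, samples, config$coalescent_theta,
                             seed = ss[base + 1L])
    ig <- apply_introgression(gt, sp_tree, config$introgression_prob,
                              seed = ss[base + 2L], species_of = species_of)
    gt <- ig$tree
    if (nrow(ig$events) > 0L)
      logs[[mk]] <- cbind(marker = mk, ig$events)
    aln <- evolve_alignment(gt, config$markers$length[k], config$kappa,
                            config$markers$rate_multiplier[k],
                            seed = ss[base + 3L], marker = mk,
                            species_of = species_of)
    if (config$missing_prob > 0) {
      set.seed(ss[base + 4L])
      drop <- runif(base::length(aln$accession)) < config$missing_prob
      if (sum(!drop) >= 2L && any(drop)) {
        keep <- aln$accession[!drop]
        aln <- marker_alignment(keep, unname(aln$species[keep]),
                                unname(aln$seq[keep]), mk)
        gt <- ape::drop.tip(gt, setdiff(gt$tip.label, keep))
        attr(gt, "species_of") <- species_of[gt$tip.label]
      }
    }
    alns[[mk]] <- aln
    gts[[mk]] <- gt
  }
  event_log <- if (base::length(logs) > 0L)
    do.call(rbind, c(logs, make.row.names = FALSE))
  else data.frame(marker = character(), recipient = character(),
                  donor = character(), stringsAsFactors = FALSE)
  structure(list(dataset = multimarker_dataset(alns),
                 species_tree = sp_tree, gene_trees = gts,
                 event_log = event_log, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d species, %d accessions, %d markers, %d introgression events\n",
              x$config$n_species, base::length(x$dataset$species_of),
              base::length(x$dataset$alignments), nrow(x$event_log)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Per-marker FASTA in the package's header dialect, species and gene trees
#' as Newick, the accession-to-species truth table and the introgression
#' event log as TSV.
#'
#' @param x A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_dataset <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mk in names(x$dataset$alignments)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", mk)
    write_fasta(x$dataset$alignments[[mk]],
                file.path(dir, paste0(safe, ".fasta")))
    write_newick(x$gene_trees[[mk]],
                 file.path(dir, paste0(safe, ".gene_tree.nwk")))
  }
  write_newick(x$species_tree, file.path(dir, "species_tree.nwk"))
  write_species_map(x$dataset$species_of, file.path(dir, "species_map.tsv"))
  write.table(x$event_log, file.path(dir, "event_log.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
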