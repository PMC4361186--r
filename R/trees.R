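# Distance-tree construction and species-monophyly scoring.

.check_defined <- function(dm) {
  stopifnot(inherits(dm, "barcode_dist"))
  if (any(!dm$defined))
    stop("distance matrix has undefined (masked) entries; refusing to build a tree",
         call. = FALSE)
  invisible(TRUE)
}

#' Neighbor-joining tree
#'
#' Standard Q-criterion agglomeration. On an additive distance matrix the
#' generating topology and branch lengths are recovered exactly. Ties in Q
#' (or in the final join) are broken by the lexicographically smallest label
#' pair, so the result is deterministic. Negative branch-length estimates
#' are clamped to 0 and flagged via `attr(tree, "clamped")`.
#'
#' @param dm A `barcode_dist` with all entries defined and >= 2 labels.
#' @return An unrooted [ape::phylo] tree (basal trifurcation for n >= 3;
#'   a two-leaf tree for n = 2 splits the single distance evenly).
#' @export
nj_tree <- function(dm) {
  .check_defined(dm)
  n <- length(dm$labels)
  if (n < 2L) stop("need at least 2 labels", call. = FALSE)
  clamped <- FALSE
  clamp <- function(v) {
    if (v < 0) { clamped <<- TRUE; 0 } else v
  }
  if (n == 2L) {
    h <- dm$d[1L, 2L] / 2
    tr <- .rlist_to_phylo(.rnode(children = list(
      .rnode(dm$labels[1L], h), .rnode(dm$labels[2L], h))))
    attr(tr, "clamped") <- FALSE
    return(tr)
  }
  D <- dm$d
  nodes <- lapply(dm$labels, .rnode)        # active subtrees
  tiekey <- dm$labels                       # lexicographic tie-break keys
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(D)
    Qm <- (m - 2) * D - outer(r, r, "+")
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm - qmin <= 0, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      p <- sort(c(tiekey[ij[1L]], tiekey[ij[2L]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- clamp(0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2)))
    vj <- clamp(D[i, j] - (0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))))
    ni <- nodes[[i]]; ni$length <- vi
    nj <- nodes[[j]]; nj$length <- vj
    newnode <- .rnode(children = list(ni, nj))
    newd <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    nodes <- c(nodes[keep], list(newnode))
    tiekey <- c(tiekey[keep], min(tiekey[c(i, j)]))
    D <- D2
  }
  # final star join of the remaining three subtrees
  v1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  v2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  v3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  for (k in 1:3) nodes[[k]]$length <- c(v1, v2, v3)[k]
  tr <- .rlist_to_phylo(.rnode(children = nodes))
  attr(tr, "clamped") <- clamped
  tr
}

#' UPGMA tree
#'
#' Average-linkage agglomeration via [stats::hclust()], returned as a rooted
#' ultrametric [ape::phylo] (heights halved so cophenetic distances
#' reproduce the input on ultrametric matrices).
#'
#' @param dm A `barcode_dist` with all entries defined and >= 2 labels.
#' @return A rooted, ultrametric [ape::phylo] tree.
#' @export
upgma_tree <- function(dm) {
  .check_defined(dm)
  if (length(dm$labels) < 2L) stop("need at least 2 labels", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(dm$d), method = "average")
  ape::as.phylo(hc)
}

# Tip-label sets below each internal node, as a list indexed by
# (node number - n). Computed by post-order accumulation over the edge list.
.node_clades <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  sets <- vector("list", n + nn)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets[(n + 1L):(n + nn)], sort)
}

.clade_key <- function(labels) paste(sort(labels), collapse = "\r")

# Canonical split keys for counting bootstrap bipartitions.
# rooted = TRUE compares clades; rooted = FALSE canonicalizes each
# bipartition to the side containing `ref`.
.tree_split_keys <- function(tree, rooted, ref = NULL) {
  n <- length(tree$tip.label)
  clades <- .node_clades(tree)
  keys <- character(tree$Nnode)
  all_tips <- sort(tree$tip.label)
  if (is.null(ref)) ref <- all_tips[1L]
  for (k in seq_len(tree$Nnode)) {
    cl <- clades[[k]]
    if (length(cl) == n) { keys[k] <- NA_character_; next }  # root: trivial
    if (rooted) keys[k] <- .clade_key(cl)
    else {
      side <- if (ref %in% cl) cl else setdiff(all_tips, cl)
      keys[k] <- .clade_key(side)
    }
  }
  keys
}

#' Bootstrap supports for a distance tree
#'
#' Builds the point-estimate tree on the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds the tree, and
#' scores each internal edge of the point tree by the percentage of
#' replicates whose tree contains the same bipartition (clade for the rooted
#' UPGMA tree, unrooted split for NJ), rounded to the nearest integer and
#' stored as node labels. Replicates whose resampled distance matrix has
#' undefined entries are skipped (a warning is issued if more than 10% are),
#' and the support denominator is the number of replicates actually used.
#'
#' @param alignment A [marker_alignment].
#' @param method `"nj"` or `"upgma"`.
#' @param n_reps Number of bootstrap replicates (>= 1), default 1000.
#' @param seed Integer seed; results are reproducible given
#'   `(seed, n_reps, method)`.
#' @return The point-estimate [ape::phylo] tree with integer supports as
#'   `node.label` (root label empty) and attributes `n_reps_used` and
#'   `n_reps_skipped`.
#' @export
bootstrap_supports <- function(alignment, method = c("nj", "upgma"),
                               n_reps = 1000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(n_reps >= 1L)
  build <- if (method == "nj") nj_tree else upgma_tree
  dm <- build_distance_matrix(alignment)
  point <- build(dm)
  rooted <- method == "upgma"
  ref <- sort(alignment$accession)[1L]
  keys <- .tree_split_keys(point, rooted, ref)
  counts <- setNames(integer(length(keys)), seq_along(keys))
  L <- alignment$length
  set.seed(seed)
  used <- 0L; skipped <- 0L
  M <- .encode_bases(alignment$seq)
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rdm <- .dm_from_encoded(M[, cols, drop = FALSE], alignment$accession)
    if (any(!rdm$defined)) { skipped <- skipped + 1L; next }
    rtree <- build(rdm)
    rkeys <- unique(.tree_split_keys(rtree, rooted, ref))
    hit <- !is.na(keys) & keys %in% rkeys
    counts[hit] <- counts[hit] + 1L
    used <- used + 1L
  }
  if (skipped > 0.1 * n_reps)
    warning(sprintf("%d of %d bootstrap replicates skipped (undefined distances)",
                    skipped, n_reps))
  support <- ifelse(is.na(keys), "",
                    as.character(round(100 * counts / max(used, 1L))))
  point$node.label <- support
  attr(point, "n_reps_used") <- used
  attr(point, "n_reps_skipped") <- skipped
  point
}

#' Test whether a set of leaves is monophyletic
#'
#' On a rooted tree, the set is monophyletic iff some node's descendant-leaf
#' set equals it; on an unrooted tree, iff some edge's bipartition has one
#' side equal to it. A singleton set is monophyletic by convention with
#' support `NA`.
#'
#' @param tree An [ape::phylo] tree.
#' @param leaf_set Non-empty character vector of tip labels.
#' @param rooted Override the rooted/unrooted interpretation; default is
#'   [ape::is.rooted()].
#' @return List with `monophyletic` (logical) and `support` (integer from
#'   the matching node's label, or `NA` when absent).
#' @export
is_monophyletic <- function(tree, leaf_set, rooted = NULL) {
  stopifnot(inherits(tree, "phylo"), length(leaf_set) >= 1L)
  leaf_set <- unique(leaf_set)
  unknown <- setdiff(leaf_set, tree$tip.label)
  if (length(unknown) > 0L)
    stop(sprintf("unknown leaf label: %s", unknown[1L]), call. = FALSE)
  if (length(leaf_set) == 1L)
    return(list(monophyletic = TRUE, support = NA_integer_))
  if (is.null(rooted)) rooted <- ape::is.rooted(tree)
  n <- length(tree$tip.label)
  if (length(leaf_set) == n)       # the whole tree is trivially a clade
    return(list(monophyletic = TRUE, support = NA_integer_))
  if (!rooted && length(leaf_set) == n - 1L)
    # one side of the missing tip's pendant edge
    return(list(monophyletic = TRUE, support = NA_integer_))
  clades <- .node_clades(tree)
  target <- .clade_key(leaf_set)
  comp <- .clade_key(setdiff(tree$tip.label, leaf_set))
  sup_of <- function(k) {
    if (is.null(tree$node.label)) return(NA_integer_)
    lab <- tree$node.label[k]
    if (is.na(lab) || !nzchar(lab)) NA_integer_ else as.integer(round(as.numeric(lab)))
  }
  for (k in seq_along(clades)) {
    cl <- clades[[k]]
    if (length(cl) == n) next
    key <- .clade_key(cl)
    if (key == target) return(list(monophyletic = TRUE, support = sup_of(k)))
    if (!rooted && key == comp)
      return(list(monophyletic = TRUE, support = sup_of(k)))
  }
  list(monophyletic = FALSE, support = NA_integer_)
}

#' Species-resolution rates on a labeled tree
#'
#' Evaluates [is_monophyletic()] for every species among the tree's tips and
#' reports the percentage recovered as monophyletic, plus the percentage
#' additionally qualified by bootstrap support at or above a threshold.
#' Species represented by a single tip count as monophyletic in the raw rate
#' (configurable) but never enter the supported numerator, since no edge
#' subtends them.
#'
#' @param tree An [ape::phylo] tree whose tips are accessions.
#' @param species_of Named character vector mapping accession to species.
#' @param support_threshold Integer bootstrap threshold, default 70.
#' @param count_singletons Count single-tip species as monophyletic in the
#'   raw rate (default `TRUE`, keeping the denominator at the full species
#'   count).
#' @param rooted Passed to [is_monophyletic()].
#' @return An object of class `resolution_report`: counts, `rate` and
#'   `rate_supported` (percentages rounded to 1 decimal), and a
#'   `per_species` data.frame.
#' @export
resolution_rates <- function(tree, species_of, support_threshold = 70L,
                             count_singletons = TRUE, rooted = NULL) {
  stopifnot(inherits(tree, "phylo"))
  missing_lab <- setdiff(tree$tip.label, names(species_of))
  if (length(missing_lab) > 0L)
    stop(sprintf("no species label for tip '%s'", missing_lab[1L]),
         call. = FALSE)
  sp <- species_of[tree$tip.label]
  species <- sort(unique(unname(sp)))
  per <- data.frame(species = species, n_tips = NA_integer_,
                    monophyletic = NA, support = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(species)) {
    tips <- tree$tip.label[sp == species[i]]
    res <- is_monophyletic(tree, tips, rooted = rooted)
    per$n_tips[i] <- length(tips)
    per$monophyletic[i] <- res$monophyletic
    per$support[i] <- res$support
  }
  singleton <- per$n_tips == 1L
  mono_raw <- per$monophyletic & (count_singletons | !singleton)
  mono_sup <- per$monophyletic & !singleton & !is.na(per$support) &
    per$support >= support_threshold
  n_eval <- length(species)
  structure(list(
    n_species_evaluated = n_eval,
    n_monophyletic = sum(mono_raw),
    n_monophyletic_supported = sum(mono_sup),
    rate = round(100 * sum(mono_raw) / n_eval, 1),
    rate_supported = round(100 * sum(mono_sup) / n_eval, 1),
    support_threshold = support_threshold,
    count_singletons = count_singletons,
    per_species = per), class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf("resolution_report: %d/%d species monophyletic (%.1f%%), %d supported (%.1f%%, threshold %d)\n",
              x$n_monophyletic, x$n_species_evaluated, x$rate,
              x$n_monophyletic_supported, x$rate_supported,
              x$support_threshold))
  invisible(x)
}
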