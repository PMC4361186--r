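# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# per-site transition/transversion counting + direct closed form
oracle_k2p <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  a[a == "U"] <- "T"; b[b == "U"] <- "T"
  n <- 0L; ts <- 0L; tv <- 0L
  purine <- c("A", "G")
  for (i in seq_along(a)) {
    if (!(a[i] %in% c("A", "C", "G", "T"))) next
    if (!(b[i] %in% c("A", "C", "G", "T"))) next
    n <- n + 1L
    if (a[i] == b[i]) next
    both_pur <- (a[i] %in% purine) && (b[i] %in% purine)
    both_pyr <- !(a[i] %in% purine) && !(b[i] %in% purine)
    if (both_pur || both_pyr) ts <- ts + 1L else tv <- tv + 1L
  }
  if (n == 0L) return(list(d = NA_real_, P = NA_real_, Q = NA_real_,
                           n_sites = 0L, defined = FALSE))
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    return(list(d = NA_real_, P = P, Q = Q, n_sites = n, defined = FALSE))
  list(d = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q),
       P = P, Q = Q, n_sites = n, defined = TRUE)
}

# exact two-sided rank-sum p by bitmask enumeration of group assignments
oracle_wilcoxon_exact <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  W_obs <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  dev <- abs(W_obs - mu)
  hits <- 0L; total <- 0L
  for (mask in 0:(2^N - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(N - 1))) > 0)
    if (length(idx) != n) next
    total <- total + 1L
    if (abs(sum(r[idx]) - mu) >= dev - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# Mood's median test by direct hypergeometric enumeration
oracle_median_p <- function(x, y) {
  med <- median(c(x, y))
  xa <- sum(x > med); xb <- sum(x < med)
  ya <- sum(y > med); yb <- sum(y < med)
  if (xa + xb + ya + yb == 0) return(1)
  m1 <- xa + xb           # row total x
  m2 <- ya + yb
  k <- xa + ya            # column total "above"
  # P(X = j) for j successes in x row under fixed margins
  pj <- function(j) choose(m1, j) * choose(m2, k - j) / choose(m1 + m2, k)
  support <- max(0, k - m2):min(m1, k)
  probs <- vapply(support, pj, 0)
  p_obs <- pj(xa)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# tip labels below every edge, by naive recursion on the edge matrix
oracle_edge_sides <- function(tree) {
  n <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  lapply(seq_len(nrow(tree$edge)), function(e) sort(desc(tree$edge[e, 2])))
}

oracle_monophyletic <- function(tree, leaf_set, rooted) {
  leaf_set <- sort(unique(leaf_set))
  if (length(leaf_set) == 1L) return(TRUE)
  all_tips <- sort(tree$tip.label)
  if (identical(leaf_set, all_tips)) return(TRUE)   # whole tree: trivial
  comp <- sort(setdiff(all_tips, leaf_set))
  for (side in oracle_edge_sides(tree)) {
    if (identical(side, leaf_set)) return(TRUE)
    if (!rooted && identical(side, comp)) return(TRUE)
  }
  FALSE
}

# exhaustive reclassification of one query under the stated criteria rules
oracle_identify <- function(query, D, defined, sp, criterion, threshold) {
  refs <- setdiff(rownames(D), query)
  d <- D[query, refs]; ok <- defined[query, refs]
  qsp <- sp[[query]]
  if (!any(ok)) return("no_match")
  dmin <- min(d[ok])
  B <- refs[ok][d[ok] == dmin]
  bm <- if (all(sp[B] == qsp)) "correct"
        else if (!any(sp[B] == qsp)) "incorrect" else "ambiguous"
  if (criterion == "best_match") return(bm)
  if (criterion == "best_close_match")
    return(if (dmin > threshold) "no_match" else bm)
  consp <- refs[sp[refs] == qsp]
  if (length(consp) < 2L) return("no_conspecific")
  S <- refs[ok][d[ok] <= threshold]
  if (length(S) == 0L) return("no_match")
  if (any(sp[S] != qsp))
    return(if (any(sp[S] == qsp)) "ambiguous" else "incorrect")
  if (setequal(S, consp)) "correct" else "incorrect"
}

# wrap a plain symmetric matrix as the package's distance-matrix class
dm_from_matrix <- function(D, defined = NULL) {
  labs <- rownames(D)
  if (is.null(defined)) {
    defined <- matrix(TRUE, nrow(D), ncol(D), dimnames = dimnames(D))
  }
  structure(list(labels = labs, d = D, defined = defined,
                 sites = matrix(NA_integer_, nrow(D), ncol(D)),
                 P = NULL, Q = NULL),
            class = "barcode_dist")
}

random_gapped_pair <- function(len) {
  alphabet <- c("A", "C", "G", "T", "-", "N", "R", "Y")
  w <- c(10, 10, 10, 10, 2, 1, 0.5, 0.5)
  a <- sample(alphabet, len, replace = TRUE, prob = w)
  b <- sample(alphabet, len, replace = TRUE, prob = w)
  # correlate the pair so realistic (small) P and Q arise
  same <- runif(len) < 0.8
  b[same] <- a[same]
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# related sequences (shared ancestor + per-sequence mutations) so that
# pairwise K2P distances are mostly defined, with occasional identical pairs
random_toy_alignment <- function(n_seq, len, n_species) {
  sp <- paste0("Sp_", sample(seq_len(n_species), n_seq, replace = TRUE))
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  seqs <- vapply(seq_len(n_seq), function(i) {
    s <- base
    mut <- runif(len) < runif(1, 0.01, 0.25)
    s[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    paste(s, collapse = "")
  }, "")
  marker_alignment(sprintf("q%02d", seq_len(n_seq)), sp, seqs, "toy")
}
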