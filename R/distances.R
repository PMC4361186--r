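# Kimura 2-parameter distances with pairwise deletion.
#
# Only columns where both sequences carry an unambiguous base (A/C/G/T) are
# compared; gaps and IUPAC ambiguity codes are deleted pairwise. Saturated
# pairs (log arguments <= 0) and zero-overlap pairs are flagged undefined
# rather than silently zeroed or imputed.

.encode_bases <- function(seqs) {
  # rows = sequences, values 1..4 for A,C,G,T, 0 otherwise
  mat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  m <- matrix(match(mat, c("A", "C", "G", "T"), nomatch = 0L),
              nrow = nrow(mat))
  rownames(m) <- names(seqs)
  m
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computes the transition proportion `P`, transversion proportion `Q` and
#' the K2P distance `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` over the
#' columns where both sequences have an unambiguous base (pairwise deletion).
#'
#' @param seq_a,seq_b Equal-length gapped DNA strings.
#' @return A list with `d`, `P`, `Q`, `n_sites` and `defined`. `d` is `NA`
#'   (with `defined = FALSE`) when no sites overlap or when the distance is
#'   saturated (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`).
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- strsplit(.normalize_residues(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(.normalize_residues(seq_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("sequences must have equal aligned length", call. = FALSE)
  ia <- match(a, c("A", "C", "G", "T"), nomatch = 0L)
  ib <- match(b, c("A", "C", "G", "T"), nomatch = 0L)
  ok <- ia > 0L & ib > 0L
  n <- sum(ok)
  if (n == 0L)
    return(list(d = NA_real_, P = NA_real_, Q = NA_real_, n_sites = 0L,
                defined = FALSE))
  ia <- ia[ok]; ib <- ib[ok]
  diff <- ia != ib
  # transitions: A<->G (1,3) and C<->T (2,4); purine = odd code
  ts <- diff & ((ia %% 2L) == (ib %% 2L))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(d = NA_real_, P = P, Q = Q, n_sites = n, defined = FALSE))
  list(d = -0.5 * log(w1) - 0.25 * log(w2) + 0, P = P, Q = Q, n_sites = n,
       defined = TRUE)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' All unordered pairs are computed under pairwise deletion. Undefined pairs
#' (no overlapping unambiguous sites, or saturation) are flagged in
#' `defined`, never silently zeroed.
#'
#' @param alignment A [marker_alignment] with at least 2 records.
#' @return An object of class `barcode_dist`: list with `labels`, `d`
#'   (symmetric numeric matrix, `NA` where undefined), `defined` (logical
#'   matrix, diagonal `TRUE`), `sites` (integer matrix of compared columns),
#'   `P` and `Q` matrices.
#' @export
build_distance_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "marker_alignment"))
  n <- length(alignment$accession)
  if (n < 2L) stop("need at least 2 records", call. = FALSE)
  M <- .encode_bases(alignment$seq)
  .dm_from_encoded(M, alignment$accession)
}

# core distance computation on an integer-encoded alignment (rows =
# sequences, 1..4 = A,C,G,T, 0 = gap/ambiguity); used directly by the
# bootstrap so resampled replicates skip string re-validation
.dm_from_encoded <- function(M, labels) {
  n <- nrow(M)
  valid <- (M > 0L) * 1
  IA <- (M == 1L) * 1; IC <- (M == 2L) * 1
  IG <- (M == 3L) * 1; IT <- (M == 4L) * 1
  shared <- round(tcrossprod(valid))
  eq <- round(tcrossprod(IA) + tcrossprod(IC) + tcrossprod(IG) + tcrossprod(IT))
  ts <- round(IA %*% t(IG) + IG %*% t(IA) + IC %*% t(IT) + IT %*% t(IC))
  tv <- shared - eq - ts
  P <- ifelse(shared > 0, ts / shared, NA_real_)
  Q <- ifelse(shared > 0, tv / shared, NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  defined <- shared > 0 & !is.na(w1) & w1 > 0 & w2 > 0
  d <- matrix(NA_real_, n, n)
  d[defined] <- -0.5 * log(w1[defined]) - 0.25 * log(w2[defined]) + 0  # +0: no -0
  diag(d) <- 0
  diag(defined) <- TRUE
  dimnames(d) <- dimnames(defined) <- dimnames(shared) <-
    dimnames(P) <- dimnames(Q) <- list(labels, labels)
  structure(list(labels = labels, d = d, defined = defined,
                 sites = shared, P = P, Q = Q),
            class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  n <- length(x$labels)
  n_undef <- sum(!x$defined[upper.tri(x$defined)])
  cat(sprintf("barcode_dist: %d accessions, %d pairs (%d undefined)\n",
              n, n * (n - 1) / 2, n_undef))
  invisible(x)
}

#' Split pairwise distances into intra- and inter-specific sets
#'
#' Every defined off-diagonal pair (counted once) is assigned to exactly one
#' of the two lists according to whether its two accessions share a species
#' label; undefined pairs are excluded.
#'
#' @param dm A `barcode_dist` from [build_distance_matrix()].
#' @param species_of Named character vector mapping accession to species.
#' @return List with numeric vectors `intra` and `inter`.
#' @export
partition_distances <- function(dm, species_of) {
  stopifnot(inherits(dm, "barcode_dist"))
  missing_lab <- setdiff(dm$labels, names(species_of))
  if (length(missing_lab) > 0L)
    stop(sprintf("no species label for accession '%s'", missing_lab[1L]),
         call. = FALSE)
  sp <- species_of[dm$labels]
  ut <- upper.tri(dm$d)
  same <- outer(sp, sp, "==")
  keep <- ut & dm$defined
  list(intra = unname(dm$d[keep & same]), inter = unname(dm$d[keep & !same]))
}
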