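# Barcoding-gap statistics: two-sample location tests on intra- vs
# inter-specific K2P distances, plus distance histograms.
#
# Caveat (documented, deliberate): pairwise distances are not independent
# observations, but the published evaluation procedure treats them as such;
# these tests replicate that procedure.

.p_floor <- 2.2e-16

#' Format a p-value with the conventional 2.2e-16 floor
#'
#' @param p Numeric p-value.
#' @return Character, `"< 2.2e-16"` for values below the floor.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < .p_floor, "< 2.2e-16", format(p, digits = 4)))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Reports the rank-sum statistic `W` (sum of the ranks of `x` in the pooled
#' sample, midranks for ties). The p-value is computed by exhaustive
#' enumeration of all rank assignments when `length(x) + length(y)` is at
#' most `exact_limit`, and by the tie-corrected normal approximation (with
#' continuity correction) otherwise.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_limit Total sample size up to which the exact enumeration is
#'   used (default 12).
#' @return List with `W`, `p` and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 12L) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  if (N <= exact_limit) {
    dev <- abs(W - mu)
    sets <- combn(N, n)
    stats <- colSums(matrix(r[sets], nrow = n))
    p <- mean(abs(stats - mu) >= dev - 1e-9)
    return(list(W = W, p = p, method = "exact"))
  }
  tie <- table(r)
  sigma2 <- n * m / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(W = W, p = 1, method = "normal"))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(W = W, p = p, method = "normal")
}

#' Mood's median test
#'
#' Classifies each observation as above or below the grand median of the
#' pooled sample (values equal to the grand median are dropped), then tests
#' independence of group and side: Fisher's exact two-sided test when any
#' expected cell count is below 5, otherwise the chi-square test with 1 df.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `table` (2x2 counts: rows = samples, cols =
#'   above/below), `p`, `grand_median`, and `degenerate` (`TRUE` when all
#'   retained values tie with the grand median, in which case `p = 1`).
#' @export
median_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  med <- median(c(x, y))
  xa <- sum(x > med); xb <- sum(x < med)
  ya <- sum(y > med); yb <- sum(y < med)
  tab <- matrix(c(xa, ya, xb, yb), 2L, 2L,
                dimnames = list(c("x", "y"), c("above", "below")))
  if (sum(tab) == 0L)
    return(list(table = tab, p = 1, grand_median = med, degenerate = TRUE))
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  p <- if (any(expd < 5)) fisher.test(tab)$p.value
       else suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  list(table = tab, p = p, grand_median = med, degenerate = FALSE)
}

#' Summarize the barcoding gap between intra- and inter-specific distances
#'
#' Computes Table-style columns (#A = number of interspecific distances,
#' #B = intraspecific), means and ranges, both two-sample tests, and
#' half-open histograms `[0, w), [w, 2w), ...` for plotting the two
#' distributions.
#'
#' @param intra,inter Numeric vectors of intra-/inter-specific distances
#'   (`inter` must be non-empty; an empty `intra` yields a summary with the
#'   tests marked not applicable).
#' @param bin_width Histogram bin width (distance units), default 0.005.
#' @return An object of class `gap_summary`.
#' @export
gap_summary <- function(intra, inter, bin_width = 0.005) {
  if (length(inter) == 0L) stop("inter must be non-empty", call. = FALSE)
  hist_of <- function(v) {
    if (length(v) == 0L)
      return(data.frame(lower = numeric(), upper = numeric(),
                        count = integer()))
    k <- max(1L, floor(max(v) / bin_width) + 1L)
    lower <- (seq_len(k) - 1L) * bin_width
    idx <- pmin(floor(v / bin_width) + 1L, k)
    data.frame(lower = lower, upper = lower + bin_width,
               count = tabulate(idx, nbins = k))
  }
  tests_ok <- length(intra) > 0L
  wt <- if (tests_ok) wilcoxon_rank_sum(intra, inter) else
    list(W = NA_real_, p = NA_real_, method = NA_character_)
  mt <- if (tests_ok) median_test(intra, inter) else
    list(p = NA_real_, grand_median = NA_real_)
  structure(list(
    n_inter = length(inter), n_intra = length(intra),
    mean_intra = if (tests_ok) mean(intra) else NA_real_,
    mean_inter = mean(inter),
    range_intra = if (tests_ok) range(intra) else c(NA_real_, NA_real_),
    range_inter = range(inter),
    median_p = mt$p, grand_median = mt$grand_median,
    wilcoxon_W = wt$W, wilcoxon_p = wt$p,
    tests_applicable = tests_ok,
    histogram_intra = hist_of(intra), histogram_inter = hist_of(inter),
    bin_width = bin_width), class = "gap_summary")
}

#' @export
print.gap_summary <- function(x, ...) {
  cat(sprintf("gap_summary: #A (inter) = %d, #B (intra) = %d\n",
              x$n_inter, x$n_intra))
  if (x$tests_applicable) {
    cat(sprintf("  mean intra %.4f (%.4f-%.4f), mean inter %.4f (%.4f-%.4f)\n",
                x$mean_intra, x$range_intra[1], x$range_intra[2],
                x$mean_inter, x$range_inter[1], x$range_inter[2]))
    cat(sprintf("  median test p %s; Wilcoxon W = %s, p %s\n",
                format_pvalue(x$median_p), format(x$wilcoxon_W),
                format_pvalue(x$wilcoxon_p)))
  } else cat("  no intraspecific distances: tests not applicable\n")
  invisible(x)
}
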