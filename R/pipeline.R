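# Orchestration: marker profiles, marker-combination evaluation, report I/O.

#' Variable and parsimony-informative site counts for an alignment
#'
#' A variable site is a column with at least two distinct unambiguous bases
#' among non-gap residues; a parsimony-informative site additionally has at
#' least two base states each present in at least two sequences.
#'
#' @param alignment A [marker_alignment].
#' @return A one-row data.frame: `marker`, `aligned_length`,
#'   `n_individuals`, `n_variable_sites`, `n_informative_sites`.
#' @export
marker_profile <- function(alignment) {
  stopifnot(inherits(alignment, "marker_alignment"))
  M <- .encode_bases(alignment$seq)
  variable <- 0L; informative <- 0L
  for (j in seq_len(ncol(M))) {
    col <- M[, j]
    col <- col[col > 0L]
    if (length(col) == 0L) next
    tab <- tabulate(col, nbins = 4L)
    states <- sum(tab > 0L)
    if (states >= 2L) variable <- variable + 1L
    if (sum(tab >= 2L) >= 2L) informative <- informative + 1L
  }
  data.frame(marker = alignment$marker, aligned_length = alignment$length,
             n_individuals = length(alignment$accession),
             n_variable_sites = variable, n_informative_sites = informative,
             stringsAsFactors = FALSE)
}

#' Standard marker-combination set
#'
#' For a panel led by a two-marker core (the first two names): all singles,
#' all pairs, the core pair plus each remaining single, the core pair plus
#' each remaining pair, and the full panel. For a five-marker panel this is
#' the classical 22-row evaluation design (5 + 10 + 3 + 3 + 1).
#'
#' @param markers Character vector of marker names, core pair first.
#' @return A list of character vectors (marker combinations).
#' @export
standard_combinations <- function(markers) {
  stopifnot(length(markers) >= 1L)
  combos <- as.list(markers)
  if (length(markers) >= 2L) {
    prs <- combn(markers, 2L, simplify = FALSE)
    combos <- c(combos, prs)
    core <- markers[1:2]
    rest <- markers[-(1:2)]
    if (length(rest) >= 1L)
      combos <- c(combos, lapply(rest, function(x) c(core, x)))
    if (length(rest) >= 2L)
      combos <- c(combos, lapply(combn(rest, 2L, simplify = FALSE),
                                 function(x) c(core, x)))
    if (length(markers) >= 3L &&
        !any(vapply(combos, function(cb) setequal(cb, markers), TRUE)))
      combos <- c(combos, list(markers))
  }
  unique(combos)
}

#' All non-empty marker combinations
#'
#' @param markers Character vector of marker names.
#' @return A list of character vectors.
#' @export
all_combinations <- function(markers) {
  unlist(lapply(seq_along(markers), combn, x = markers, simplify = FALSE),
         recursive = FALSE)
}

.combo_name <- function(combo) paste(combo, collapse = "+")

#' Evaluate marker combinations end to end
#'
#' For each combination: concatenates the selected markers (gap-filling
#' accessions missing a marker), builds the K2P distance matrix, computes
#' the barcoding-gap summary, builds bootstrapped NJ/UPGMA trees, scores
#' species-resolution rates at the support threshold, and runs leave-one-out
#' identification under the requested criteria. Per-marker profiles and gap
#' summaries are also reported. Deterministic given `seed`. Combinations
#' whose concatenation has undefined distance pairs or fewer than two
#' accessions are skipped with a warning and recorded in `skipped`.
#'
#' @param dataset A [multimarker_dataset].
#' @param combos List of marker-name vectors, or `"standard"` /` "all"`.
#' @param methods Tree methods, subset of `c("upgma", "nj")`.
#' @param criteria Identification criteria (see [identify_query()]).
#' @param n_boot Bootstrap replicates per tree (0 disables bootstrap and
#'   leaves supports empty), default 1000.
#' @param support_threshold Bootstrap threshold for the qualified resolution
#'   rate, default 70.
#' @param percentile Threshold percentile for identification, default 95.
#' @param accession_mode Per-combo accession handling passed to
#'   [concatenate_markers()]: `"union"` (default) or `"intersection"`.
#' @param seed Integer seed controlling all bootstrap resampling.
#' @return An object of class `evaluation_report` with `marker_profile`
#'   (data.frame), `gap` (marker -> `gap_summary`), `resolution`
#'   (data.frame: combo x method), `identification` (data.frame: combo x
#'   criterion), `trees` (combo -> method -> tree) and `skipped`.
#' @export
evaluate_combinations <- function(dataset, combos = "standard",
                                  methods = c("upgma", "nj"),
                                  criteria = c("best_match",
                                               "best_close_match",
                                               "all_species_barcodes"),
                                  n_boot = 1000L, support_threshold = 70L,
                                  percentile = 95,
                                  accession_mode = c("union", "intersection"),
                                  seed = 1L) {
  stopifnot(inherits(dataset, "multimarker_dataset"))
  methods <- match.arg(methods, c("upgma", "nj"), several.ok = TRUE)
  accession_mode <- match.arg(accession_mode)
  marker_names <- names(dataset$alignments)
  if (identical(combos, "standard")) combos <- standard_combinations(marker_names)
  else if (identical(combos, "all")) combos <- all_combinations(marker_names)
  stopifnot(is.list(combos), length(combos) >= 1L)
  profile <- do.call(rbind, c(lapply(dataset$alignments, marker_profile),
                              make.row.names = FALSE))
  gap <- lapply(dataset$alignments, function(a) {
    parts <- partition_distances(build_distance_matrix(a), a$species)
    if (length(parts$inter) == 0L) return(NULL)
    gap_summary(parts$intra, parts$inter)
  })
  res_rows <- list(); id_rows <- list(); trees <- list(); skipped <- character()
  for (ci in seq_along(combos)) {
    combo <- combos[[ci]]
    cname <- .combo_name(combo)
    aln <- concatenate_markers(dataset, combo, accessions = accession_mode)
    if (length(aln$accession) < 2L) {
      warning(sprintf("combo %s skipped: fewer than 2 accessions", cname))
      skipped <- c(skipped, cname); next
    }
    dm <- build_distance_matrix(aln)
    if (any(!dm$defined)) {
      warning(sprintf("combo %s skipped: undefined distance pairs", cname))
      skipped <- c(skipped, cname); next
    }
    trees[[cname]] <- list()
    for (mi in seq_along(methods)) {
      method <- methods[mi]
      tr <- if (n_boot > 0L)
        bootstrap_supports(aln, method, n_reps = n_boot,
                           seed = (seed + 1009L * ci + 101L * mi) %% 2147483647L)
      else if (method == "nj") nj_tree(dm) else upgma_tree(dm)
      trees[[cname]][[method]] <- tr
      rr <- resolution_rates(tr, aln$species,
                             support_threshold = support_threshold)
      res_rows[[paste(cname, method)]] <- data.frame(
        combo = cname, method = method,
        n_species = rr$n_species_evaluated,
        n_monophyletic = rr$n_monophyletic,
        n_supported = rr$n_monophyletic_supported,
        rate = rr$rate, rate_supported = rr$rate_supported,
        stringsAsFactors = FALSE)
    }
    sr <- identification_success_rates(aln, criteria = criteria,
                                       percentile = percentile)
    id_rows[[cname]] <- cbind(combo = cname, sr$per_criterion,
                              threshold = sr$threshold)
  }
  structure(list(marker_profile = profile, gap = gap,
                 resolution = do.call(rbind, c(res_rows, make.row.names = FALSE)),
                 identification = do.call(rbind, c(id_rows, make.row.names = FALSE)),
                 trees = trees, skipped = skipped,
                 params = list(n_boot = n_boot,
                               support_threshold = support_threshold,
                               percentile = percentile, seed = seed)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  cat(sprintf("  markers: %s\n", paste(x$marker_profile$marker, collapse = ", ")))
  cat(sprintf("  combos evaluated: %d (skipped: %d)\n",
              length(x$trees), length(x$skipped)))
  cat("  resolution (top rows):\n")
  print(head(x$resolution, 8L), row.names = FALSE)
  invisible(x)
}

.fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

#' Write the four report tables as TSV
#'
#' Emits `profile.tsv`, `gap.tsv` (one row per marker, Table-style columns:
#' counts, median-test p, Wilcoxon W and p with the `< 2.2e-16` floor
#' convention, means and ranges), `resolution.tsv`, `identification.tsv`,
#' per-marker histogram TSVs and Newick trees per combo and method.
#' Formatting is fixed so identical reports are byte-identical.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_evaluation_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f)
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(report$marker_profile, "profile.tsv")
  gr <- lapply(names(report$gap), function(mk) {
    g <- report$gap[[mk]]
    if (is.null(g)) return(NULL)
    data.frame(marker = mk, n_inter = g$n_inter, n_intra = g$n_intra,
               median_p = format_pvalue(g$median_p),
               wilcoxon_W = .fmt_num(g$wilcoxon_W, 10),
               wilcoxon_p = format_pvalue(g$wilcoxon_p),
               mean_inter = .fmt_num(g$mean_inter),
               min_inter = .fmt_num(g$range_inter[1]),
               max_inter = .fmt_num(g$range_inter[2]),
               mean_intra = .fmt_num(g$mean_intra),
               min_intra = .fmt_num(g$range_intra[1]),
               max_intra = .fmt_num(g$range_intra[2]),
               stringsAsFactors = FALSE)
  })
  wt(do.call(rbind, c(gr, make.row.names = FALSE)), "gap.tsv")
  hr <- lapply(names(report$gap), function(mk) {
    g <- report$gap[[mk]]
    if (is.null(g)) return(NULL)
    rbind(
      if (nrow(g$histogram_intra) > 0L)
        cbind(marker = mk, partition = "intra", g$histogram_intra)
      else NULL,
      cbind(marker = mk, partition = "inter", g$histogram_inter))
  })
  wt(do.call(rbind, c(hr, make.row.names = FALSE)), "histograms.tsv")
  wt(report$resolution, "resolution.tsv")
  id <- report$identification
  id$threshold <- .fmt_num(id$threshold)
  wt(id, "identification.tsv")
  for (cname in names(report$trees))
    for (method in names(report$trees[[cname]])) {
      safe <- gsub("[^A-Za-z0-9._-]", "_", cname)
      write_newick(report$trees[[cname]][[method]],
                   file.path(dir, sprintf("%s.%s.nwk", safe, method)))
    }
  invisible(dir)
}
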