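# Leave-one-out distance-based specimen identification under the three
# classical criteria: best match, best close match, all species barcodes.

.criteria <- c("best_match", "best_close_match", "all_species_barcodes")

#' Distance threshold from the intraspecific distance pool
#'
#' Nearest-rank percentile of the sorted intraspecific distances:
#' `rank = ceiling(percentile/100 * n)`.
#'
#' @param intra Non-empty numeric vector of intraspecific distances.
#' @param percentile Percentile in (0, 100], default 95.
#' @return The threshold distance.
#' @export
intraspecific_threshold <- function(intra, percentile = 95) {
  if (length(intra) == 0L)
    stop("threshold unavailable: no intraspecific distances", call. = FALSE)
  stopifnot(percentile > 0, percentile <= 100)
  s <- sort(intra)
  s[ceiling(percentile / 100 * length(s))]
}

#' Identify one query accession against all other references
#'
#' Leave-one-out identification on a precomputed distance matrix. Undefined
#' distances are treated as farther than any defined distance (a query never
#' matches through a masked entry). Threshold comparisons are inclusive
#' (`<=`).
#'
#' Outcomes: `best_match` — the set `B` of references at the minimum defined
#' distance is all conspecific (`correct`), all heterospecific
#' (`incorrect`), or mixed (`ambiguous`). `best_close_match` — as
#' `best_match`, but `no_match` when the minimum distance exceeds the
#' threshold. `all_species_barcodes` — with `S` the references within the
#' threshold: `no_conspecific` when the query has fewer than two conspecific
#' references; `no_match` when `S` is empty; `ambiguous`/`incorrect` when
#' `S` contains heterospecifics (with/without conspecifics alongside);
#' `correct` only when `S` equals the full conspecific reference set (which
#' then has size >= 2); a strict conspecific subset is `incorrect`.
#'
#' @param query Accession id present in `dm`.
#' @param dm A `barcode_dist`.
#' @param species_of Named character vector mapping accession to species.
#' @param criterion One of `"best_match"`, `"best_close_match"`,
#'   `"all_species_barcodes"`.
#' @param threshold Distance threshold; required for the two
#'   threshold-using criteria.
#' @return List with `query`, `criterion`, `outcome`, `best_distance`
#'   (`NA` when no defined distance) and `matched_species`.
#' @export
identify_query <- function(query, dm, species_of,
                           criterion = .criteria, threshold = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(dm, "barcode_dist"))
  if (!query %in% dm$labels) stop(sprintf("unknown query '%s'", query), call. = FALSE)
  if (criterion != "best_match" && is.null(threshold))
    stop(sprintf("criterion '%s' requires a threshold", criterion), call. = FALSE)
  refs <- setdiff(dm$labels, query)
  d <- dm$d[query, refs]
  ok <- dm$defined[query, refs]
  qsp <- species_of[[query]]
  rsp <- species_of[refs]
  res <- function(outcome, best = NA_real_, matched = character())
    list(query = query, criterion = criterion, outcome = outcome,
         best_distance = best, matched_species = sort(unique(matched)))
  if (!any(ok)) return(res("no_match"))
  dmin <- min(d[ok])
  B <- refs[ok & d <= dmin]                       # best-match tie set
  bm_outcome <- if (all(rsp[B] == qsp)) "correct"
                else if (all(rsp[B] != qsp)) "incorrect" else "ambiguous"
  if (criterion == "best_match")
    return(res(bm_outcome, dmin, unname(rsp[B])))
  if (criterion == "best_close_match") {
    if (dmin > threshold) return(res("no_match", dmin))
    return(res(bm_outcome, dmin, unname(rsp[B])))
  }
  # all_species_barcodes
  consp <- refs[rsp == qsp]
  if (length(consp) < 2L) return(res("no_conspecific", dmin))
  S <- refs[ok & d <= threshold]
  if (length(S) == 0L) return(res("no_match", dmin))
  hetero <- S[rsp[S] != qsp]
  if (length(hetero) > 0L) {
    out <- if (any(rsp[S] == qsp)) "ambiguous" else "incorrect"
    return(res(out, dmin, unname(rsp[S])))
  }
  if (setequal(S, consp)) return(res("correct", dmin, qsp))
  res("incorrect", dmin, unname(rsp[S]))          # strict conspecific subset
}

#' Leave-one-out identification success rates
#'
#' Builds the distance matrix once, derives the threshold from the full
#' intraspecific distance pool of the alignment (nearest-rank percentile),
#' queries every accession against all others, and aggregates outcomes per
#' criterion. When the alignment yields no intraspecific distances the
#' threshold-using criteria degrade to never returning `no_match` on
#' distance grounds (threshold `Inf`, with a warning).
#'
#' @param alignment A [marker_alignment] (possibly a concatenation) with
#'   >= 2 accessions.
#' @param species_of Named character vector; defaults to the alignment's
#'   own species labels.
#' @param criteria Character vector of criteria to evaluate.
#' @param percentile Threshold percentile, default 95.
#' @return An object of class `success_rates`: `combo`, `threshold`, and
#'   `per_criterion` data.frame with columns `criterion`, `n_queries`,
#'   `n_correct`, `n_ambiguous`, `n_incorrect`, `n_no_match`,
#'   `n_no_conspecific`, `pct_correct` (2 decimals); plus the per-query
#'   outcome table as `per_query`.
#' @export
identification_success_rates <- function(alignment, species_of = NULL,
                                         criteria = .criteria,
                                         percentile = 95) {
  stopifnot(inherits(alignment, "marker_alignment"))
  criteria <- match.arg(criteria, several.ok = TRUE)
  if (is.null(species_of)) species_of <- alignment$species
  dm <- build_distance_matrix(alignment)
  parts <- partition_distances(dm, species_of)
  threshold <- if (length(parts$intra) > 0L)
    intraspecific_threshold(parts$intra, percentile)
  else {
    warning("no intraspecific distances: threshold set to Inf")
    Inf
  }
  rows <- list(); per_query <- list()
  for (cr in criteria) {
    outs <- lapply(dm$labels, identify_query, dm = dm,
                   species_of = species_of, criterion = cr,
                   threshold = threshold)
    oc <- vapply(outs, `[[`, "", "outcome")
    per_query[[cr]] <- data.frame(
      query = dm$labels, criterion = cr, outcome = oc,
      best_distance = vapply(outs, `[[`, 0, "best_distance"),
      stringsAsFactors = FALSE)
    nq <- length(oc)
    rows[[cr]] <- data.frame(
      criterion = cr, n_queries = nq,
      n_correct = sum(oc == "correct"),
      n_ambiguous = sum(oc == "ambiguous"),
      n_incorrect = sum(oc == "incorrect"),
      n_no_match = sum(oc == "no_match"),
      n_no_conspecific = sum(oc == "no_conspecific"),
      pct_correct = round(100 * sum(oc == "correct") / nq, 2),
      stringsAsFactors = FALSE)
  }
  structure(list(combo = alignment$marker, threshold = threshold,
                 percentile = percentile,
                 per_criterion = do.call(rbind, c(rows, make.row.names = FALSE)),
                 per_query = do.call(rbind, c(per_query, make.row.names = FALSE))),
            class = "success_rates")
}

#' @export
print.success_rates <- function(x, ...) {
  cat(sprintf("success_rates for %s (threshold %.4g at %gth percentile)\n",
              x$combo, x$threshold, x$percentile))
  print(x$per_criterion, row.names = FALSE)
  invisible(x)
}
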