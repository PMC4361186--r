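#' @importFrom stats runif rexp setNames median cophenetic chisq.test fisher.test pnorm quantile sd reorder as.dist hclust
#' @importFrom utils combn write.table read.table head
NULL

# Allowed residue alphabet: unambiguous bases, IUPAC ambiguity codes, gap.
.iupac_alphabet <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                     "B", "D", "H", "V", "N", "-")

.normalize_residues <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

.check_residues <- function(seq, id) {
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, .iupac_alphabet)
  if (length(bad) > 0L)
    stop(sprintf("record '%s' contains invalid residue characters: %s",
                 id, paste(bad, collapse = " ")), call. = FALSE)
  invisible(TRUE)
}

#' Construct a marker alignment
#'
#' A `marker_alignment` holds one pre-aligned marker: equal-length gapped DNA
#' sequences, one per accession, each carrying a species label. Residues are
#' normalized to uppercase and `U` is mapped to `T`.
#'
#' @param accession Character vector of unique accession identifiers.
#' @param species Character vector of species labels (binomial-style,
#'   e.g. `"Genus_species"`), parallel to `accession`.
#' @param seq Character vector of aligned sequences over
#'   `A,C,G,T` + IUPAC ambiguity codes + `-`, all of identical length.
#' @param marker Single marker name.
#' @return An object of class `marker_alignment` with fields `marker`,
#'   `length`, `accession`, `species` and `seq` (named by accession).
#' @export
marker_alignment <- function(accession, species, seq, marker) {
  stopifnot(is.character(accession), is.character(species), is.character(seq),
            length(accession) == length(species),
            length(accession) == length(seq),
            length(marker) == 1L, nzchar(marker))
  if (length(accession) == 0L)
    stop("alignment must contain at least one record", call. = FALSE)
  if (any(!nzchar(accession)))
    stop("accession ids must be non-empty", call. = FALSE)
  if (anyDuplicated(accession))
    stop(sprintf("duplicate accession id: %s",
                 accession[duplicated(accession)][1L]), call. = FALSE)
  seq <- .normalize_residues(seq)
  if (any(!nzchar(seq)))
    stop("sequences must be non-empty", call. = FALSE)
  lens <- nchar(seq)
  if (length(unique(lens)) != 1L) {
    off <- accession[lens != lens[1L]][1L]
    stop(sprintf("alignment error: record '%s' has length %d, expected %d",
                 off, nchar(seq[accession == off]), lens[1L]), call. = FALSE)
  }
  for (i in seq_along(seq)) .check_residues(seq[i], accession[i])
  structure(
    list(marker = marker, length = lens[1L], accession = accession,
         species = setNames(species, accession),
         seq = setNames(seq, accession)),
    class = "marker_alignment")
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat(sprintf("marker_alignment '%s': %d records x %d columns\n",
              x$marker, length(x$accession), x$length))
  cat(sprintf("  species: %d\n", length(unique(x$species))))
  invisible(x)
}

#' Read a marker alignment from FASTA
#'
#' Headers must follow the dialect `>ACCESSION species=Genus_species`
#' (optionally `marker=NAME`; anything else after the accession is rejected).
#' Sequences may wrap over multiple lines, must align to equal length, and
#' are normalized to uppercase with `U` mapped to `T`.
#'
#' @param path Path to a FASTA file.
#' @param marker Marker name to assign; if `NULL`, taken from a `marker=`
#'   field in the first header (error if absent).
#' @return A [marker_alignment].
#' @export
read_fasta <- function(path, marker = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !any(nzchar(trimws(lines))))
    stop(sprintf("empty FASTA input: %s", path), call. = FALSE)
  acc <- character(); sp <- character(); mk <- character()
  seqs <- character(); cur <- NULL
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      header <- sub("^>", "", line)
      fields <- strsplit(header, "\\s+")[[1]]
      id <- fields[1L]
      if (is.na(id) || !nzchar(id))
        stop(sprintf("FASTA parse error at line %d: missing accession id", i),
             call. = FALSE)
      kv <- fields[-1L]
      if (any(!grepl("^[A-Za-z_]+=", kv)))
        stop(sprintf(
          "FASTA parse error at line %d: expected key=value fields after accession, got '%s'",
          i, header), call. = FALSE)
      keys <- sub("=.*$", "", kv)
      vals <- sub("^[A-Za-z_]+=", "", kv)
      if (!"species" %in% keys)
        stop(sprintf("FASTA parse error at line %d: header lacks species= field", i),
             call. = FALSE)
      if (id %in% acc)
        stop(sprintf("duplicate accession id '%s' at line %d", id, i),
             call. = FALSE)
      acc <- c(acc, id)
      sp <- c(sp, vals[match("species", keys)])
      mk <- c(mk, if ("marker" %in% keys) vals[match("marker", keys)] else NA_character_)
      seqs <- c(seqs, "")
      cur <- length(seqs)
    } else {
      if (is.null(cur))
        stop(sprintf("FASTA parse error at line %d: sequence before any header", i),
             call. = FALSE)
      seqs[cur] <- paste0(seqs[cur], gsub("\\s", "", line))
    }
  }
  if (length(acc) == 0L)
    stop(sprintf("empty FASTA input (no records): %s", path), call. = FALSE)
  if (is.null(marker)) {
    marker <- mk[1L]
    if (is.na(marker))
      stop("no marker name given and first header lacks marker= field",
           call. = FALSE)
  }
  marker_alignment(acc, sp, seqs, marker)
}

#' Write a marker alignment to FASTA
#'
#' Emits the `>ACCESSION species=... marker=...` header dialect that
#' [read_fasta()] consumes.
#'
#' @param aln A [marker_alignment].
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @export
write_fasta <- function(aln, path, width = 80L) {
  stopifnot(inherits(aln, "marker_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$accession)) {
    id <- aln$accession[i]
    writeLines(sprintf(">%s species=%s marker=%s", id, aln$species[[id]],
                       aln$marker), con)
    s <- aln$seq[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Bundle per-marker alignments into a multi-marker dataset
#'
#' @param alignments A named list of [marker_alignment] objects (names are
#'   marker names; if unnamed, marker fields are used).
#' @return An object of class `multimarker_dataset` with fields `alignments`
#'   (marker -> alignment) and `species_of` (accession -> species, pooled over
#'   markers).
#' @export
multimarker_dataset <- function(alignments) {
  stopifnot(is.list(alignments), length(alignments) >= 1L)
  lapply(alignments, function(a) stopifnot(inherits(a, "marker_alignment")))
  nm <- names(alignments)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(alignments, `[[`, "", "marker")
  if (anyDuplicated(nm)) stop("marker names must be unique", call. = FALSE)
  names(alignments) <- nm
  species_of <- character()
  for (a in alignments) {
    conflict <- intersect(names(species_of), a$accession)
    bad <- conflict[species_of[conflict] != a$species[conflict]]
    if (length(bad) > 0L)
      stop(sprintf("accession '%s' has conflicting species labels across markers",
                   bad[1L]), call. = FALSE)
    species_of[a$accession] <- a$species
  }
  structure(list(alignments = alignments, species_of = species_of),
            class = "multimarker_dataset")
}

#' @export
print.multimarker_dataset <- function(x, ...) {
  cat(sprintf("multimarker_dataset: %d markers, %d accessions, %d species\n",
              length(x$alignments), length(x$species_of),
              length(unique(x$species_of))))
  for (m in names(x$alignments))
    cat(sprintf("  %s: %d records x %d bp\n", m,
                length(x$alignments[[m]]$accession), x$alignments[[m]]$length))
  invisible(x)
}

#' Concatenate marker alignments into a supermatrix
#'
#' Lays the selected alignments end-to-end in the given order. Under the
#' default `"union"` mode an accession missing from a selected marker
#' receives a full block of `-` for that marker (distance computation
#' downstream handles this under pairwise deletion, but two accessions with
#' complementary missing markers can end up with no shared sites);
#' `"intersection"` keeps only accessions present in every selected marker.
#' Accession order is order of first appearance over the selected markers.
#'
#' @param dataset A [multimarker_dataset].
#' @param markers Ordered character vector of marker names to concatenate.
#' @param accessions `"union"` (gap-fill, default) or `"intersection"`
#'   (strict: only accessions sequenced for every selected marker).
#' @return A [marker_alignment] whose `marker` is the `+`-joined combo name,
#'   with attribute `blocks`: a data.frame of per-marker column ranges.
#' @export
concatenate_markers <- function(dataset, markers,
                                accessions = c("union", "intersection")) {
  stopifnot(inherits(dataset, "multimarker_dataset"))
  accessions <- match.arg(accessions)
  if (length(markers) == 0L) stop("empty marker list", call. = FALSE)
  unknown <- setdiff(markers, names(dataset$alignments))
  if (length(unknown) > 0L)
    stop(sprintf("unknown marker: %s", unknown[1L]), call. = FALSE)
  alns <- dataset$alignments[markers]
  accs <- unique(unlist(lapply(alns, `[[`, "accession"), use.names = FALSE))
  if (accessions == "intersection")
    accs <- accs[Reduce(`&`, lapply(alns, function(a) accs %in% a$accession))]
  if (length(accs) == 0L)
    stop("no accession is present in every selected marker", call. = FALSE)
  pieces <- vapply(alns, function(a) {
    out <- setNames(strrep("-", a$length), NULL)[rep(1L, length(accs))]
    present <- accs %in% a$accession
    out[present] <- unname(a$seq[accs[present]])
    out
  }, character(length(accs)))
  if (length(accs) == 1L) pieces <- matrix(pieces, nrow = 1L)
  seqs <- apply(pieces, 1L, paste0, collapse = "")
  lens <- vapply(alns, `[[`, 0L, "length")
  ends <- cumsum(lens)
  blocks <- data.frame(marker = markers, start = c(1L, head(ends, -1L) + 1L),
                       end = ends, row.names = NULL)
  out <- marker_alignment(accs, unname(dataset$species_of[accs]), seqs,
                          marker = paste(markers, collapse = "+"))
  attr(out, "blocks") <- blocks
  out
}

#' Write / read an accession-to-species map as TSV
#'
#' Two tab-separated columns, `accession` and `species`, UTF-8, with header.
#'
#' @param species_of Named character vector (accession -> species).
#' @param path File path.
#' @return `read_species_map` returns a named character vector.
#' @export
write_species_map <- function(species_of, path) {
  write.table(data.frame(accession = names(species_of),
                         species = unname(species_of)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_species_map
#' @export
read_species_map <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  setNames(df$species, df$accession)
}
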