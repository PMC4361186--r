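#' Read a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] with a pre-scan for unbalanced
#' parentheses (reported with the character offset). Integer internal-node
#' labels are interpreted downstream as bootstrap supports.
#'
#' @param path Path to a Newick file, or a Newick string via `text=`.
#' @param text Optional Newick string (overrides `path`).
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop(sprintf("Newick parse error: unbalanced ')' at offset %d", i),
           call. = FALSE)
  }
  if (depth != 0L)
    stop(sprintf("Newick parse error: %d unclosed '(' at end of input (offset %d)",
                 depth, length(chars)), call. = FALSE)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop(sprintf("Newick parse error: %s",
                                                  conditionMessage(e)), call. = FALSE),
                 warning = function(w) stop(sprintf("Newick parse error: %s",
                                                    conditionMessage(w)), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: unreadable input", call. = FALSE)
  tr
}

#' Write a tree as Newick
#'
#' Branch lengths are written with enough digits to round-trip to at least
#' 10 significant figures; bootstrap supports are emitted as internal-node
#' labels.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path; if `NULL`, the Newick string is returned.
#' @return The path (invisibly), or the Newick string when `path` is `NULL`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("tree has duplicate leaf labels", call. = FALSE)
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

# ---- internal phylo assembly -------------------------------------------
# Trees are assembled as nested lists (node = list(label, length, children))
# and serialized through Newick with %.17g so branch lengths round-trip at
# full double precision.

.rnode <- function(label = NULL, length = NA_real_, children = list()) {
  list(label = label, length = length, children = children)
}

.rlist_to_newick <- function(node) {
  paste0(.rlist_nwk(node), ";")
}

.rlist_nwk <- function(node) {
  lab <- if (is.null(node$label)) "" else node$label
  body <- if (length(node$children) == 0L) lab else
    paste0("(", paste(vapply(node$children, .rlist_nwk, ""), collapse = ","),
           ")", lab)
  if (is.na(node$length)) body else sprintf("%s:%.17g", body, node$length)
}

.rlist_to_phylo <- function(node) {
  ape::read.tree(text = .rlist_to_newick(node))
}

.phylo_to_rlist <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  labs <- tree$node.label
  build <- function(node, len) {
    if (node <= n) return(.rnode(tree$tip.label[node], len))
    ch <- kids[[as.character(node)]]
    lab <- if (!is.null(labs) && nzchar(labs[node - n])) labs[node - n] else NULL
    .rnode(lab, len,
           lapply(ch, function(e) build(tree$edge[e, 2L], tree$edge.length[e])))
  }
  build(root, NA_real_)
}
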