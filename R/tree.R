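#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration; a matrix of exact tree (additive)
#' distances is recovered exactly, topology and branch lengths. Negative
#' branch-length estimates (possible on non-additive matrices) are clamped
#' to zero with a warning.
#'
#' @param dm A `dist` object or symmetric labeled matrix with at least 3
#'   taxa (e.g. from [chordDistanceMatrix()]).
#' @return An unrooted `phylo` tree (class from \pkg{ape}).
#' @export
njTree <- function(dm) {
  if (!inherits(dm, "dist")) dm <- stats::as.dist(as.matrix(dm))
  if (attr(dm, "Size") < 3) stop("neighbor-joining needs at least 3 taxa")
  tree <- ape::nj(dm)
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length estimate(s) clamped to 0")
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  tree
}

#' Midpoint-root a tree
#'
#' Places the root halfway along the longest leaf-to-leaf path.
#'
#' @param tree An unrooted `phylo` tree with at least 2 leaves.
#' @return A rooted `phylo` tree; leaf-to-leaf path lengths are preserved.
#' @export
midpointRoot <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (length(tree$tip.label) < 2) stop("need at least 2 leaves")
  if (is.null(tree$edge.length) || all(tree$edge.length == 0)) {
    warning("all branch lengths are zero; rooting on an arbitrary edge")
    return(ape::root(tree, outgroup = tree$tip.label[1],
                     resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

.needsQuoting <- function(labels) grepl("[][ \t(),:;']", labels)

#' Write a tree in Newick format
#'
#' Branch lengths are written with 6-decimal precision; labels containing
#' spaces or Newick metacharacters are single-quoted per the format
#' convention.
#'
#' @param tree A `phylo` tree.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [readNewick()] for the quoted-label-aware reader.
#' @export
writeNewick <- function(tree, path) {
  # ape sanitizes labels (spaces -> underscores), so awkward labels are
  # swapped for placeholders and re-inserted single-quoted afterwards
  quote_me <- which(.needsQuoting(tree$tip.label))
  originals <- tree$tip.label[quote_me]
  tree$tip.label[quote_me] <-
    sprintf("QUOTEDLABEL%dX", seq_along(quote_me))
  txt <- ape::write.tree(tree, digits = 6)
  for (i in seq_along(quote_me)) {
    quoted <- paste0("'", gsub("'", "''", originals[i]), "'")
    txt <- sub(sprintf("QUOTEDLABEL%dX", i), quoted, txt, fixed = TRUE)
  }
  writeLines(txt, path)
  invisible(path)
}

#' Read a Newick tree, accepting quoted labels
#'
#' @param path Newick file path.
#' @return A `phylo` tree with quoting stripped from labels.
#' @export
readNewick <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  # protect quoted labels from the parser, restore afterwards
  m <- gregexpr("'(?:[^']|'')*'", txt)[[1]]
  labels <- character(0)
  if (m[1] != -1) {
    labels <- regmatches(txt, gregexpr("'(?:[^']|'')*'", txt))[[1]]
    for (i in seq_along(labels)) {
      txt <- sub(labels[i], sprintf("QUOTEDLABEL%dX", i),
                 txt, fixed = TRUE)
    }
  }
  tree <- ape::read.tree(text = txt)
  if (length(labels) > 0) {
    unq <- gsub("''", "'", substr(labels, 2, nchar(labels) - 1))
    for (i in seq_along(labels)) {
      hit <- tree$tip.label == sprintf("QUOTEDLABEL%dX", i)
      tree$tip.label[hit] <- unq[i]
      if (!is.null(tree$node.label)) {
        nhit <- tree$node.label == sprintf("QUOTEDLABEL%dX", i)
        tree$node.label[nhit] <- unq[i]
      }
    }
  }
  tree
}

#' Write a labeled distance matrix as TSV
#'
#' @param dm A `dist` object or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(dm, path) {
  m <- as.matrix(dm)
  df <- data.frame(strain_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
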