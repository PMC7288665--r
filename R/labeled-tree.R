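# LabeledTree: phylogeny with one foreground branch, and the PAML-style
# `#1` Newick label dialect.

.FG_SENTINEL <- "@@FG@@"

#' Construct a labeled tree
#'
#' @param phy an \code{ape::phylo} tree with branch lengths.
#' @param foreground either a taxon name (the terminal branch leading to
#'   that tip becomes the foreground) or an integer edge index into
#'   `phy$edge`.
#' @return a [LabeledTree-class].
#' @examples
#' phy <- ape::read.tree(text = "((a:0.1,b:0.1):0.05,c:0.2);")
#' tr <- labeledTree(phy, foreground = "a")
#' @export
labeledTree <- function(phy, foreground) {
  if (is.character(foreground)) {
    tip <- match(foreground, phy$tip.label)
    if (is.na(tip)) stop("foreground taxon '", foreground,
                         "' is not a tip of the tree")
    edge <- which(phy$edge[, 2] == tip)
  } else {
    edge <- as.integer(foreground)
  }
  new("LabeledTree", phy = phy, foregroundEdge = as.integer(edge))
}

#' Foreground edge index
#' @param tree a [LabeledTree-class].
#' @return integer row index into `tree@phy$edge`.
#' @export
foregroundEdge <- function(tree) tree@foregroundEdge

#' Foreground taxon, if the foreground branch is terminal
#' @param tree a [LabeledTree-class].
#' @return the tip label, or `NA` for an internal foreground branch.
#' @export
foregroundTaxon <- function(tree) {
  child <- tree@phy$edge[tree@foregroundEdge, 2]
  if (child <= length(tree@phy$tip.label))
    tree@phy$tip.label[child] else NA_character_
}

#' Re-flag the foreground branch
#' @param tree a [LabeledTree-class].
#' @param foreground taxon name or edge index (see [labeledTree()]).
#' @return a new [LabeledTree-class].
#' @export
setForeground <- function(tree, foreground) labeledTree(tree@phy, foreground)

#' Read a Newick tree with a `#1` foreground label
#'
#' Accepts the branch-label dialect used by codeml: a `#1` after a tip
#' name or after a closing parenthesis marks that branch as the
#' foreground lineage, e.g. `"((a:1,b:1)#1:0.5,c:1);"` or
#' `"(a #1:1, b:1, c:1);"`.  Plain branch lengths are required.
#'
#' @param file path to a Newick file, or `NULL` when `text` is given.
#' @param text Newick string.
#' @return a [LabeledTree-class]; errors if no `#1` (or more than one)
#'   is present.
#' @export
readLabeledNewick <- function(file = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(file), collapse = "")
  n_marks <- lengths(regmatches(text, gregexpr("#\\s*1", text)))
  if (n_marks != 1L)
    stop("expected exactly one '#1' foreground mark, found ", n_marks)
  marked <- gsub("([A-Za-z0-9_.|/-]+)\\s*#\\s*1",
                 paste0("\\1", .FG_SENTINEL), text)
  marked <- gsub("\\)\\s*#\\s*1", paste0(")", .FG_SENTINEL), marked)
  phy <- ape::read.tree(text = marked)
  if (is.null(phy)) stop("failed to parse Newick string")
  tipHit <- grep(.FG_SENTINEL, phy$tip.label, fixed = TRUE)
  nodeHit <- if (!is.null(phy$node.label))
    grep(.FG_SENTINEL, phy$node.label, fixed = TRUE) else integer(0)
  if (length(tipHit) + length(nodeHit) != 1L)
    stop("could not locate the '#1' foreground mark after parsing")
  if (length(tipHit)) {
    phy$tip.label <- sub(.FG_SENTINEL, "", phy$tip.label, fixed = TRUE)
    node <- tipHit
  } else {
    phy$node.label <- sub(.FG_SENTINEL, "", phy$node.label, fixed = TRUE)
    node <- length(phy$tip.label) + nodeHit
  }
  edge <- which(phy$edge[, 2] == node)
  if (length(edge) != 1L)
    stop("the '#1' mark must sit on a non-root branch")
  if (is.null(phy$edge.length))
    phy$edge.length <- rep(0.1, nrow(phy$edge))
  labeledTree(phy, edge)
}

#' Write a labeled tree as Newick with the `#1` foreground mark
#' @param tree a [LabeledTree-class].
#' @param file optional output path; when `NULL` the string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
writeLabeledNewick <- function(tree, file = NULL) {
  phy <- tree@phy
  node <- phy$edge[tree@foregroundEdge, 2]
  ntip <- length(phy$tip.label)
  if (node <= ntip) {
    phy$tip.label[node] <- paste0(phy$tip.label[node], .FG_SENTINEL)
  } else {
    if (is.null(phy$node.label))
      phy$node.label <- rep("", phy$Nnode)
    phy$node.label[node - ntip] <-
      paste0(phy$node.label[node - ntip], .FG_SENTINEL)
  }
  txt <- ape::write.tree(phy)
  txt <- gsub(.FG_SENTINEL, " #1", txt, fixed = TRUE)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

setMethod("show", "LabeledTree", function(object) {
  fg <- foregroundTaxon(object)
  cat("LabeledTree: ", length(object@phy$tip.label), " tips, foreground ",
      if (is.na(fg)) paste0("internal edge ", object@foregroundEdge)
      else paste0("branch leading to '", fg, "'"), "\n", sep = "")
})
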