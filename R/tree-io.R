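#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] adding the checks the downstream
#' phylogenetic statistics need: unique tip labels and branch lengths
#' (missing lengths are set to 0 with a warning).
#'
#' @param path Path to a Newick file, or a Newick string via `text`.
#' @param text Optional Newick string (overrides `path`).
#' @return An [ape::phylo] tree with an `edge.length` component.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not supported", call. = FALSE)
  }
  tree
}

#' Total branch length of a tree
#'
#' @param tree An [ape::phylo] tree.
#' @return Sum of all branch lengths.
#' @export
total_branch_length <- function(tree) {
  if (is.null(tree$edge.length)) return(0)
  sum(tree$edge.length)
}
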