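#' Read and validate a rooted phylogeny
#'
#' Thin validating wrapper around \code{ape::read.tree}. The tree must have
#' unique tip labels and a finite non-negative length on every edge.
#' Polytomies are allowed and reported via a message. Slightly
#' non-ultrametric trees (as mega-tree pruning pipelines sometimes emit) are
#' accepted with a warning.
#'
#' @param path Newick file, or a literal Newick string via \code{text}.
#' @param text Newick string (alternative to \code{path}).
#' @return an \code{ape} \code{"phylo"} object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text)
          else ape::read.tree(path)
  if (is.null(tree))
    stop("failed to parse Newick input")
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  bad <- which(!is.finite(tree$edge.length) | tree$edge.length < 0)
  if (length(bad))
    stop("missing/negative branch lengths on edges: ",
         paste(bad, collapse = ", "))
  if (!ape::is.binary(tree))
    message("tree contains polytomies; they are retained for covariance ",
            "and resolved (zero-length, deterministic) where a binary tree ",
            "is required")
  ht <- max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (ht > 0 && diff(range(depths)) > 1e-6 * ht)
    warning("tree is not ultrametric (tip depth range ",
            signif(diff(range(depths)), 3), "); accepted as-is")
  tree
}

#' Canonicalize species labels
#'
#' Trims whitespace, collapses internal runs of whitespace, and maps spaces
#' to underscores so trait tables and tree tip labels match exactly. No
#' fuzzy taxonomic matching is attempted.
#'
#' @param x character vector of labels.
#' @return canonicalized character vector.
#' @export
canonical_labels <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("[ \t]+", " ", x)
  gsub(" ", "_", x)
}

#' Prune a phylogeny to a set of tips
#'
#' Returns the induced subtree: path lengths between retained tips are
#' preserved exactly and degree-2 nodes are suppressed with their edge
#' lengths summed. Labels absent from the tree are reported in the
#' \code{"rejected"} attribute, never silently dropped.
#'
#' @param tree a \code{"phylo"} object.
#' @param keep character vector of tip labels (canonicalized before
#'   matching).
#' @return pruned \code{"phylo"} with attribute \code{"rejected"} listing
#'   requested labels not found in the tree.
#' @export
prune_to <- function(tree, keep) {
  keep <- canonical_labels(keep)
  labs <- canonical_labels(tree$tip.label)
  tree$tip.label <- labs
  missing <- setdiff(keep, labs)
  present <- intersect(keep, labs)
  if (length(present) < 2L)
    stop("fewer than 2 requested tips present in the tree (",
         length(present), " found)")
  out <- ape::keep.tip(tree, present)
  # keep.tip reroots at the MRCA of the retained set; record the dropped
  # stem as a root edge so root-to-tip depths (and the Brownian covariance)
  # of the original tree are preserved
  mrca <- ape::getMRCA(tree, present)
  stem <- ape::node.depth.edgelength(tree)[mrca] + (tree$root.edge %||% 0)
  if (stem > 0) out$root.edge <- stem
  attr(out, "rejected") <- missing
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phylogenetic covariance matrix of a tree
#'
#' Under Brownian motion the covariance between two tips is the shared
#' root-to-MRCA path length; the diagonal holds root-to-tip distances.
#' With \code{normalize = TRUE} (the default used for model fitting) the
#' matrix is divided by its maximum diagonal entry so tree height is 1,
#' making variance components comparable across trees.
#'
#' @param tree a \code{"phylo"} object.
#' @param normalize divide by max diagonal so height = 1. Default FALSE.
#' @return symmetric matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree, normalize = FALSE) {
  C <- ape::vcv.phylo(tree)
  # a root edge is shared history common to all tips
  if (!is.null(tree$root.edge)) C <- C + tree$root.edge
  if (normalize) C <- C / max(diag(C))
  C
}

#' Rescale a phylogenetic covariance by Pagel's lambda
#'
#' Multiplies all off-diagonal entries by \code{lambda} while leaving the
#' diagonal unchanged: lambda = 1 returns the Brownian covariance, lambda =
#' 0 erases all shared history.
#'
#' @param C phylogenetic covariance matrix.
#' @param lambda scalar in [0, 1].
#' @return rescaled matrix.
#' @export
lambda_rescale <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L ||
      is.na(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  d <- diag(C)
  out <- lambda * C
  diag(out) <- d
  out
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's contrasts: differences between sister lineages standardized
#' by branch lengths, rendering trait values independent under Brownian
#' motion. Polytomies are resolved deterministically with zero-length
#' branches first. Computed with \code{ape::pic}.
#'
#' @param tree a \code{"phylo"} object.
#' @param trait named numeric vector covering every tip.
#' @return numeric vector of N-1 contrasts (N = tips), named by node.
#' @export
independent_contrasts <- function(tree, trait) {
  trait <- match_to_tips(tree, trait, "trait")
  if (!ape::is.binary(tree))
    tree <- ape::multi2di(tree, random = FALSE)
  ape::pic(trait, tree)
}

# Match a named trait vector to tree tips; error listing missing tips.
match_to_tips <- function(tree, trait, what = "trait") {
  labs <- canonical_labels(tree$tip.label)
  if (is.null(names(trait))) {
    if (length(trait) != length(labs))
      stop(what, " must be named by tip or have one value per tip")
    names(trait) <- labs
    return(trait)
  }
  names(trait) <- canonical_labels(names(trait))
  miss <- setdiff(labs, names(trait))
  if (length(miss))
    stop(what, " missing for tips: ", paste(miss, collapse = ", "))
  trait[labs]
}
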