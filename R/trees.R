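# Neighbor-joining phenogram from the K2P matrix, with nonparametric
# bootstrap support. Agglomeration is delegated to ape's NJ; this module
# adds the distance plumbing, the negative-branch policy and seeded,
# reproducible bootstrap supports.

#' Neighbor-joining phenogram from a K2P distance matrix
#'
#' @param dm a `k2p_dist` from [distance_matrix()], with all pairwise
#'   distances defined.
#' @param clamp_negative replace negative branch lengths by zero, moving
#'   the deficit onto the sister edge so path lengths are conserved
#'   (default `TRUE`).
#' @return an unrooted `phylo` tree (branch lengths in
#'   substitutions/site).
#' @export
nj_phenogram <- function(dm, clamp_negative = TRUE) {
  stopifnot(inherits(dm, "k2p_dist"))
  n <- length(dm$ids)
  if (n < 3) stop("NJ needs at least 3 taxa")
  und <- which(is.na(dm$d) & upper.tri(dm$d), arr.ind = TRUE)
  if (nrow(und))
    stop("undefined distances for pair(s): ",
         paste(paste(dm$ids[und[, 1]], dm$ids[und[, 2]], sep = "~"),
               collapse = ", "))
  tr <- ape::nj(dm$d)
  if (clamp_negative && any(tr$edge.length < 0))
    tr <- .clamp_negative_edges(tr)
  tr
}

# Set negative edges to zero and add the deficit to the sister edge
# sharing the same parent node, preserving tip-to-tip path lengths.
.clamp_negative_edges <- function(tr) {
  for (e in which(tr$edge.length < 0)) {
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs))
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + deficit
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for an NJ phenogram
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate's K2P + NJ tree is scanned for the original tree's internal
#' bipartitions, and support is the percentage of replicates containing
#' each one. Seeded and fully reproducible.
#'
#' @param x an aligned [barcode_library()] or character alignment matrix.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @return the NJ `phylo` tree with `node.label` holding support values
#'   (0-100; root label empty).
#' @export
bootstrap_support <- function(x, n_reps = 1000, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  aln <- .alignment_of(x)
  build <- function(mat) {
    dm <- distance_matrix(mat)
    if (anyNA(dm$d)) dm$d[is.na(dm$d)] <- max(dm$d, na.rm = TRUE)
    nj_phenogram(dm)
  }
  tr <- build(aln)
  set.seed(seed)
  counts <- ape::boot.phylo(tr, aln, build, B = n_reps, quiet = TRUE,
                            rooted = FALSE)
  support <- round(100 * counts / n_reps, 1)
  tr$node.label <- c("", support[-1])
  attr(tr, "n_reps") <- n_reps
  tr
}

#' Write a phenogram to a newick file
#'
#' @param tree a `phylo` (support values, if present, are written as
#'   internal node labels).
#' @param path output file.
#' @export
write_phenogram <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
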