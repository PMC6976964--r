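#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via ape) on a symmetric labelled
#' distance matrix. Negative branch-length estimates - possible on
#' non-additive inputs such as Fst matrices - are clamped to 0 and the
#' deficit transferred to the sibling edge at the same node, preserving the
#' path length between the joined pair; each clamp is reported with a
#' message.
#'
#' @param d Symmetric numeric matrix with labels and >= 3 rows; no NA/NaN.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) abort("need at least 3 taxa")
  if (anyNA(d)) abort("distance matrix contains NA/NaN")
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("distance matrix not symmetric")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  tr <- ape::nj(d)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sib)) {
      tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + tr$edge.length[e]
    }
    inform(sprintf("clamped negative branch length %.4g to 0", tr$edge.length[e]))
    tr$edge.length[e] <- 0
  }
  tr
}

#' Write / read a tree in newick format
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @return `path` (writer) or a `phylo` (reader).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
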