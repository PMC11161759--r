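#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion
#' `Q(i,j) = (n-2) d(i,j) - R(i) - R(j)` (`R` the row sums). At each
#' step the minimal-Q pair is joined; ties are broken deterministically
#' by the lexicographically lowest label pair. Limb lengths follow the
#' usual formulas, negative estimates are clamped to 0 (the clamped
#' deficit is reported via a message), and the final three nodes are
#' joined to a central node by the three-point formulas, producing an
#' unrooted tree whose internal nodes have degree 3. On additive
#' matrices the tree's path-length distances reproduce the input
#' exactly.
#'
#' @param d symmetric numeric matrix with zero diagonal and labels as
#'   dimnames (at least 3), or a [stats::dist].
#' @return an unrooted `"phylo"` tree.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (nrow(d) < 3L) stop("need at least 3 labels")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix is not symmetric")
  labels <- rownames(d)
  if (anyDuplicated(labels)) stop("duplicate labels in distance matrix")

  # each active node carries a newick fragment
  frag <- setNames(as.list(labels), labels)
  D <- d
  clamped <- 0
  len_str <- function(l) sprintf("%.17g", max(l, 0))
  clamp <- function(l) { if (l < 0) clamped <<- clamped + (-l); max(l, 0) }

  while (nrow(D) > 3L) {
    n <- nrow(D)
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    m <- min(Q)
    cand <- which(Q - m <= 1e-12 * max(1, abs(m)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lab_pairs <- cbind(pmin(rownames(D)[cand[, 1]], rownames(D)[cand[, 2]]),
                       pmax(rownames(D)[cand[, 1]], rownames(D)[cand[, 2]]))
    pick <- order(lab_pairs[, 1], lab_pairs[, 2], method = "radix")[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- clamp(D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))))
    new_lab <- paste0("(", rownames(D)[i], ",", rownames(D)[j], ")")
    new_frag <- paste0("(", frag[[rownames(D)[i]]], ":", len_str(li), ",",
                       frag[[rownames(D)[j]]], ":", len_str(lj), ")")
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], new_lab)
    frag[[new_lab]] <- new_frag
    frag[rownames(D)[c(i, j)]] <- NULL
    D <- D2
  }

  # join the last three nodes at a central point
  l1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", frag[[rownames(D)[1]]], ":", len_str(l1), ",",
                frag[[rownames(D)[2]]], ":", len_str(l2), ",",
                frag[[rownames(D)[3]]], ":", len_str(l3), ");")
  if (clamped > 0) {
    message(sprintf("neighbor_joining: clamped negative branch length(s), total deficit %.3g", clamped))
  }
  ape::read.tree(text = nwk)
}

#' Path-length (patristic) distances of a tree
#'
#' Convenience wrapper over [ape::cophenetic.phylo()], with rows and
#' columns ordered by the given labels.
#'
#' @param tree a `"phylo"` object.
#' @param labels optional label order.
#' @return symmetric matrix of path-length distances.
#' @export
tree_path_distances <- function(tree, labels = NULL) {
  m <- ape::cophenetic.phylo(tree)
  if (!is.null(labels)) m <- m[labels, labels]
  m
}
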