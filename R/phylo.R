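#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei neighbor joining with two determinism refinements:
#' ties in the Q-criterion are broken by the lexicographically smallest pair
#' of cluster labels (a cluster is labelled by its smallest member id), and
#' a negative branch length is clamped to zero with the deficit moved to its
#' sister branch, preserving the joined pair's path length.  The result is
#' an unrooted [ape::read.tree()] `"phylo"` object whose basal node
#' trifurcates, as usual for NJ.
#'
#' @param D Symmetric numeric distance matrix, zero diagonal, no NA/NaN.
#' @param labels Taxon labels; default `rownames(D)`.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D, labels = rownames(D)) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (n < 3L) stop_kin("neighbor joining needs at least 3 taxa")
  if (anyNA(D) || any(!is.finite(D))) stop_kin("distance matrix contains NA/NaN")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop_kin("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop_kin("distance matrix diagonal must be zero")
  dimnames(D) <- list(labels, labels)

  # each active cluster: newick fragment + smallest member label
  frag <- stats::setNames(labels, labels)
  smallest <- stats::setNames(labels, labels)
  act <- labels
  n_clusters <- 0L

  fmt <- function(x) sprintf("%.10g", max(x, 0))
  rsort <- function(x) sort(x, method = "radix")

  while (length(act) > 3L) {
    N <- length(act)
    Dm <- D[act, act]
    r <- rowSums(Dm)
    Q <- (N - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      paste(rsort(c(smallest[act[ij[1]]], smallest[act[ij[2]]])), collapse = "\r")
    })
    pick <- cand[order(key, method = "radix")[1], ]
    i <- act[pick[1]]; j <- act[pick[2]]
    dij <- D[i, j]
    li <- dij / 2 + (r[pick[1]] - r[pick[2]]) / (2 * (N - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    n_clusters <- n_clusters + 1L
    new <- sprintf("\x01%d", n_clusters) # internal name, cannot collide with labels
    frag[new] <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    smallest[new] <- rsort(c(smallest[i], smallest[j]))[1]
    d_new <- (D[i, act] + D[j, act] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- new
    D[new, act] <- d_new
    D[act, new] <- d_new
    D[new, new] <- 0
    act <- c(setdiff(act, c(i, j)), new)
  }

  a <- act[order(smallest[act], method = "radix")]
  d12 <- D[a[1], a[2]]; d13 <- D[a[1], a[3]]; d23 <- D[a[2], a[3]]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[a[1]], fmt(l1),
                 frag[a[2]], fmt(l2), frag[a[3]], fmt(l3))
  ape::read.tree(text = txt)
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, so the
#' two farthest leaves are equidistant from the root (rooting convention of
#' the family phylograms).  A tree whose branch lengths are all zero has no
#' midpoint; it is returned as-is — rooted at its basal multifurcation —
#' with a warning.  Rooting mechanics are delegated to
#' [phangorn::midpoint()].
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop_kin("tree has no branch lengths")
  if (all(tree$edge.length <= 0)) {
    warning("all branch lengths are zero; no midpoint exists, returning the tree rooted at its basal multifurcation")
    return(tree)
  }
  phangorn::midpoint(tree)
}

#' Newick serialization
#'
#' [to_newick()] writes a tree (branch lengths to 10 significant digits,
#' internal support labels retained); [from_newick()] parses Newick text or
#' a file, checking parenthesis balance (reporting the character offset of
#' the first imbalance) and rejecting duplicate leaf labels.  Internal node
#' labels (e.g. posterior probabilities of an imported consensus tree) are
#' kept in `$node.label`.
#'
#' @param tree A `phylo` object.
#' @param path Optional output path; omitted, the Newick string is returned.
#' @return `to_newick`: Newick string (invisibly if written to `path`);
#'   `from_newick`: a `phylo` object.
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 10)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @rdname to_newick
#' @param text Newick string, or path to a file containing one.
#' @export
from_newick <- function(text) {
  if (length(text) == 1L && !grepl("(", text, fixed = TRUE) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  depth <- 0L
  chars <- str_chars(text)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop_kin("unbalanced ')' at character %d", k)
    }
  }
  if (depth != 0L) stop_kin("unbalanced '(': %d unclosed at end of input", depth)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop_kin("could not parse Newick input")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) stop_kin("duplicate leaf label '%s'", dup[1])
  tree
}

#' Robinson–Foulds distance
#'
#' Number of bipartitions present in exactly one of the two trees (0 iff
#' the unrooted topologies agree).  Computed with [phangorn::RF.dist()]
#' after an explicit leaf-set check.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  only1 <- setdiff(t1$tip.label, t2$tip.label)
  only2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(only1) || length(only2)) {
    stop_kin("leaf sets differ; only in first: [%s]; only in second: [%s]",
             paste(only1, collapse = ", "), paste(only2, collapse = ", "))
  }
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}

#' Leaf-to-leaf path lengths
#'
#' Convenience wrapper around [ape::cophenetic.phylo()]; used for
#' diameter/midpoint diagnostics.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Symmetric matrix of patristic distances.
#' @export
leaf_distances <- function(tree) stats::cophenetic(tree)

#' Poisson-corrected distance
#'
#' `-log(1 - p)`, the usual correction of a protein p-distance for multiple
#' hits; an optional transform of [distance_matrix()] output before
#' [neighbor_joining()].
#'
#' @param p p-distance value(s) in `[0, 1)`.
#' @return Corrected distance(s).
#' @export
poisson_correct <- function(p) {
  if (any(p < 0 | p >= 1)) stop_kin("p-distances must lie in [0, 1) for Poisson correction")
  -log(1 - p)
}
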