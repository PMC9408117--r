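# Neighbor-joining on a pairwise distance matrix, bootstrap bipartition
# supports, and Newick round-trip. Trees are held as ape "phylo" objects so
# the whole phylogenetics ecosystem applies downstream.

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the Studier-Keppler criterion
#' \deqn{Q(i,j) = (n-2) d(i,j) - \sum_k d(i,k) - \sum_k d(j,k),}
#' standard branch-length formulas and distance reduction. Ties in the Q
#' minimum are broken by the lowest (row, column) index pair in the current
#' label order, so the result is deterministic. Negative branch lengths are
#' clamped to zero with the deficit moved to the sister branch (leaf-to-leaf
#' path lengths are preserved); the raw lengths are kept in the
#' `raw_edge.length` attribute.
#'
#' @param d A symmetric matrix (or [pairwise_matrix()]) with finite entries
#'   and at least 3 labelled rows.
#' @return An unrooted `phylo` (class from \pkg{ape}) with `edge.length`.
#' @export
neighbor_joining <- function(d) {
  m <- unclass(as.matrix(d))
  n <- nrow(m)
  if (n < 3) stop("need at least 3 taxa")
  if (any(!is.finite(m))) stop("non-finite distance entry")
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix is not symmetric")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  n_int <- n - 2L                       # internal nodes of the unrooted tree
  active <- seq_len(n)                  # temp ids of live nodes
  D <- m
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  next_temp <- n + 1L

  while (length(active) > 3L) {
    k <- length(active)
    R <- rowSums(D)
    Q <- (k - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    # lowest (row, col) pair among minima
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2])[1], ]
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (k - 2))
    lj <- D[i, j] - li
    # clamp negatives, preserving the path length through the pair
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    edges <- rbind(edges, c(next_temp, active[i]), c(next_temp, active[j]))
    lens <- c(lens, li, lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    active <- c(active[keep], next_temp)
    next_temp <- next_temp + 1L
  }
  # resolve the final 3-star around the last internal node
  a <- D[1, 2]; b <- D[1, 3]; cc <- D[2, 3]
  l3 <- c((a + b - cc) / 2, (a + cc - b) / 2, (b + cc - a) / 2)
  l3 <- pmax(l3, 0)
  edges <- rbind(edges, cbind(next_temp, active))
  lens <- c(lens, l3)

  # renumber: tips 1..n keep ids; internals map so the 3-way hub = n + 1
  renum <- function(t) ifelse(t <= n, t, n + n_int + 1L - (t - n))
  edge <- cbind(renum(edges[, 1]), renum(edges[, 2]))
  tr <- structure(list(edge = edge, edge.length = unname(lens),
                       tip.label = labels, Nnode = n_int),
                  class = "phylo", order = NULL)
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "raw_edge.length") <- tr$edge.length
  tr
}

# Leaf bipartitions induced by internal edges, as canonical key strings.
# The side not containing the first label (alphabetically) is sorted and
# joined; the trivial (leaf) edges are skipped.
.bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- tree$tip.label[p]
    if (length(side) <= 1 || length(side) >= n - 1) next
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap supports on a point-estimate tree
#'
#' For every internal edge of `point_tree`, the percentage of bootstrap
#' replicate trees (neighbor-joining on each replicate matrix) whose
#' topology contains the same leaf bipartition. Supports are attached as
#' `node.label` on the child node of each internal edge (the 3-way hub
#' carries no label) and returned in the `supports` attribute.
#'
#' @param point_tree A `phylo` from [neighbor_joining()].
#' @param replicates A [bootstrap_distance()] result (matrices must share
#'   the tree's label set).
#' @return `point_tree` with integer-percentage `node.label` and a
#'   `supports` attribute (named by bipartition key).
#' @export
bootstrap_supports <- function(point_tree, replicates) {
  if (!setequal(replicates$labels, point_tree$tip.label))
    stop("replicate labels do not match tree labels")
  keys <- .bipartitions(point_tree)
  hits <- setNames(numeric(length(keys)), keys)
  for (mtx in replicates$matrices) {
    rep_keys <- .bipartitions(neighbor_joining(mtx))
    hits[keys %in% rep_keys] <- hits[keys %in% rep_keys] + 1
  }
  supports <- 100 * hits / replicates$B
  # map: internal (non-hub) node -> its bipartition key
  n <- length(point_tree$tip.label)
  node_lab <- rep("", point_tree$Nnode)
  anchor <- sort(point_tree$tip.label)[1]
  parts <- ape::prop.part(point_tree)
  for (q in seq_along(parts)) {
    side <- point_tree$tip.label[parts[[q]]]
    if (length(side) <= 1 || length(side) >= n - 1) next
    if (anchor %in% side) side <- setdiff(point_tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    node_lab[q] <- as.character(round(supports[key]))
  }
  point_tree$node.label <- node_lab
  attr(point_tree, "supports") <- supports
  point_tree
}

#' Serialize a tree to Newick
#'
#' Newick text with branch lengths; bootstrap supports (if present as
#' `node.label`) appear after the internal closing parentheses.
#'
#' @param tree A `phylo`.
#' @param path Optional file path; when given the text is also written
#'   there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
to_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Parse a Newick string or file
#'
#' @param text Newick text (or `NULL` when reading from `path`).
#' @param path Optional file path.
#' @return A `phylo`.
#' @export
from_newick <- function(text = NULL, path = NULL) {
  if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text)
}
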