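#' Node heights of a rooted tree
#'
#' Heights are time before present: tips at (approximately) zero, the root
#' at the tree height. Entry `i` corresponds to ape node number `i`
#' (tips `1..n`, then internal nodes).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return Numeric vector of node heights.
#' @export
node_heights <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' Validate a tree as ultrametric
#'
#' Checks that the tree is rooted, has no negative branch lengths, and that
#' all tips sit at height zero within `tol * root height` (absolute `tol`
#' for a zero-height tree). Polytomies are resolved arbitrarily with
#' zero-length branches, with a warning. A non-ultrametric tree is rejected
#' with the pair of offending tips named.
#'
#' @param tree A `phylo`.
#' @param tol Relative tolerance on tip heights. Default `1e-6`.
#' @return The validated (binary, rooted) `phylo`.
#' @export
as_ultrametric <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) .stop_input("tree has no branch lengths")
  if (any(tree$edge.length < 0)) .stop_input("negative branch lengths")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    # a basal multifurcation is a root polytomy: resolve it like any other
    warning("polytomies resolved arbitrarily with zero-length branches")
    tree <- ape::multi2di(tree)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (!ape::is.rooted(tree)) .stop_input("tree must be rooted")
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)[seq_len(n)]
  h <- max(depth)
  eps <- if (h > 0) tol * h else tol
  if (diff(range(depth)) > eps) {
    lo <- which.min(depth)
    hi <- which.max(depth)
    .stop_input("tree is not ultrametric: tips ", tree$tip.label[lo], " and ",
                tree$tip.label[hi], " differ in root-to-tip length (",
                format(depth[lo]), " vs ", format(depth[hi]), ")")
  }
  tree
}

#' Read and write ultrametric Newick trees
#'
#' `read_ultrametric()` parses a Newick file with branch lengths, resolves
#' polytomies (zero-length, with a warning) and validates ultrametricity;
#' `write_ultrametric()` writes Newick with enough digits for round-trips to
#' preserve heights to ~1e-9.
#'
#' @param path Newick file path.
#' @param tol Relative ultrametricity tolerance (see [as_ultrametric()]).
#' @return `read_ultrametric()`: a validated `phylo`.
#' @export
read_ultrametric <- function(path, tol = 1e-6) {
  if (!file.exists(path)) .stop_input("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) .stop_input("could not parse Newick file: ", path)
  as_ultrametric(tree, tol = tol)
}

#' @rdname read_ultrametric
#' @param tree A `phylo`.
#' @export
write_ultrametric <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' UPGMA tree from a K2P distance matrix
#'
#' Average-linkage agglomerative clustering; node height is half the merge
#' distance, so the output is always ultrametric. Intended as a fallback
#' when no time-calibrated gene tree is available; a dedicated Bayesian or
#' rate-smoothed chronogram is preferable for real analyses.
#'
#' @param m A `k2p_dist` object with no saturated pairs.
#' @return An ultrametric `phylo`.
#' @export
upgma_tree <- function(m) {
  stopifnot(inherits(m, "k2p_dist"))
  if (any(m$saturated)) {
    pr <- which(m$saturated & upper.tri(m$saturated), arr.ind = TRUE)[1L, ]
    .stop_input("saturated distance between ", m$ids[pr[1L]], " and ",
                m$ids[pr[2L]], "; exclude these sequences before UPGMA")
  }
  phangorn::upgma(stats::as.dist(m$d))
}

#' Entities defined by a height threshold on an ultrametric tree
#'
#' Each branch crossing height `T` defines one entity: the set of tips below
#' it. Entities with two or more tips are clusters, single-tip entities are
#' singletons. `T` at or above the root height yields one entity (all tips);
#' `T = 0` yields one singleton per tip.
#'
#' @param tree An ultrametric `phylo` (see [as_ultrametric()]).
#' @param T Threshold height, >= 0.
#' @return A list with `cluster_map` (named character vector tip -> entity
#'   label), `n_entities`, `n_clusters` and `n_singletons`.
#' @export
entities_at_threshold <- function(tree, T) {
  stopifnot(inherits(tree, "phylo"), T >= 0)
  n <- ape::Ntip(tree)
  h <- node_heights(tree)
  root_h <- max(h)
  if (T >= root_h) {
    cm <- stats::setNames(rep("E1", n), tree$tip.label)
    return(list(cluster_map = cm, n_entities = 1L,
                n_clusters = if (n >= 2L) 1L else 0L,
                n_singletons = if (n >= 2L) 0L else 1L))
  }
  if (T <= 0) {
    cm <- stats::setNames(paste0("E", seq_len(n)), tree$tip.label)
    return(list(cluster_map = cm, n_entities = n, n_clusters = 0L,
                n_singletons = n))
  }
  cross <- .crossing_edges(tree, h, T)
  ent_of_node <- .propagate_entities(tree, cross)
  labs <- paste0("E", ent_of_node[seq_len(n)])
  sizes <- table(labs)
  list(cluster_map = stats::setNames(labs, tree$tip.label),
       n_entities = length(cross),
       n_clusters = sum(sizes >= 2L),
       n_singletons = sum(sizes == 1L))
}

# edges (rows of tree$edge) whose child is below h and parent above h
.crossing_edges <- function(tree, heights, h) {
  child <- tree$edge[, 2L]
  parent <- tree$edge[, 1L]
  which(heights[child] < h & heights[parent] > h)
}

# entity index per node: children of crossing edges seed entities, then
# membership propagates rootward->tipward
.propagate_entities <- function(tree, cross) {
  nnode <- ape::Ntip(tree) + tree$Nnode
  ent <- rep(NA_integer_, nnode)
  ent[tree$edge[cross, 2L]] <- seq_along(cross)
  # preorder: parents before children
  ord <- order(ape::node.depth.edgelength(tree)[tree$edge[, 2L]])
  for (e in ord) {
    ch <- tree$edge[e, 2L]
    if (is.na(ent[ch])) ent[ch] <- ent[tree$edge[e, 1L]]
  }
  ent
}

# build a phylo from tips (height 0) and internal nodes given as a list of
# child pairs; children are encoded as negative tip indices or positive
# internal-node indices. Internal node k has height heights[k]. The node
# with no parent is the root.
.phylo_from_nodes <- function(tip_labels, children, heights) {
  n <- length(tip_labels)
  stopifnot(length(children) == n - 1L, length(heights) == n - 1L)
  # root = internal node that is nobody's child
  kids <- unlist(children)
  internal_refs <- kids[kids > 0]
  root <- setdiff(seq_len(n - 1L), internal_refs)
  stopifnot(length(root) == 1L)
  # ape numbering: tips 1..n, root n+1, remaining internals in input order
  ape_id <- integer(n - 1L)
  ape_id[root] <- n + 1L
  rest <- setdiff(seq_len(n - 1L), root)
  ape_id[rest] <- n + 1L + seq_along(rest)
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  row <- 0L
  for (k in seq_len(n - 1L)) {
    for (c in children[[k]]) {
      row <- row + 1L
      edge[row, 1L] <- ape_id[k]
      if (c < 0) {
        edge[row, 2L] <- -c
        elen[row] <- heights[k]
      } else {
        edge[row, 2L] <- ape_id[c]
        elen[row] <- heights[k] - heights[c]
      }
    }
  }
  phy <- structure(list(edge = edge, edge.length = elen, Nnode = n - 1L,
                        tip.label = tip_labels),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}
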