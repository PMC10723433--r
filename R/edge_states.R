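# Branch-level category labels derived from node-state reconstructions.

#' Label every branch with the state of its descendant node
#'
#' The branch `(u -> v)` takes the state of `v`, so terminal branches always
#' carry the observed tip category; the root has no branch of its own.
#'
#' @param tree `phylo` (postorder branch ordering is used, see
#'   [branch_index()]).
#' @param node_states Vector (factor or character) of states for all nodes,
#'   indexed as in `phylo` (tips `1..n`, then internals).
#' @return Factor of length `Nedge(tree)` aligned to [branch_index()];
#'   names are the branch ids.
#' @export
assign_edge_states <- function(tree, node_states) {
  tree <- stats::reorder(tree, "postorder")
  nnode <- length(tree$tip.label) + tree$Nnode
  if (length(node_states) != nnode)
    stop("node_states must cover all ", nnode, " nodes")
  if (anyNA(node_states)) stop("node_states contains missing states")
  lev <- if (is.factor(node_states)) levels(node_states) else
    unique(as.character(node_states))
  out <- factor(as.character(node_states)[tree$edge[, 2L]], levels = lev)
  names(out) <- seq_len(nrow(tree$edge))
  out
}

#' Carry master-tree edge states onto composite edges
#'
#' Each composite edge of a pruned tree takes the state of the most recent
#' (tipward) master edge it spans, so composite edges leading to extant
#' species keep the observed state.
#'
#' @param paths A `path_map` from [build_paths()].
#' @param master_edge_states Factor over master branches, as returned by
#'   [assign_edge_states()] on the master tree.
#' @return Factor over the pruned tree's branches.
#' @export
composite_edge_states <- function(paths, master_edge_states) {
  stopifnot(inherits(paths, "path_map"))
  nb <- nrow(paths$master_branches)
  if (length(master_edge_states) != nb)
    stop("master_edge_states length ", length(master_edge_states),
         " does not match ", nb, " master branches")
  ids <- vapply(paths$paths, function(p) {
    if (any(p < 1L | p > nb)) stop("path references unknown master edge")
    p[length(p)]
  }, 0L)
  out <- master_edge_states[ids]
  names(out) <- seq_along(ids)
  out
}

#' Count state transitions along branches
#'
#' Entry `(a, b)` is the number of branches whose ancestor node is in state
#' `a` and descendant node in state `b` (`a != b`); the symmetric "direct
#' transitions between a and b" count is `(a,b) + (b,a)`.
#'
#' @inheritParams assign_edge_states
#' @return `k x k` integer matrix with zero diagonal.
#' @export
count_transitions <- function(tree, node_states) {
  tree <- stats::reorder(tree, "postorder")
  lev <- if (is.factor(node_states)) levels(node_states) else
    unique(as.character(node_states))
  s <- factor(as.character(node_states), levels = lev)
  if (anyNA(s)) stop("node_states contains missing states")
  a <- as.integer(s[tree$edge[, 1L]])
  b <- as.integer(s[tree$edge[, 2L]])
  k <- length(lev)
  m <- matrix(0L, k, k, dimnames = list(lev, lev))
  for (e in which(a != b)) m[a[e], b[e]] <- m[a[e], b[e]] + 1L
  m
}

#' Edge-state report table
#'
#' @inheritParams assign_edge_states
#' @param edge_states Factor from [assign_edge_states()].
#' @return `data.frame` with `branch`, `parent_node`, `child_node`,
#'   `category`.
#' @export
edge_state_table <- function(tree, edge_states) {
  bi <- branch_index(tree)
  data.frame(branch = bi$branch, parent_node = bi$parent,
             child_node = bi$child,
             category = as.character(edge_states),
             stringsAsFactors = FALSE)
}
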