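#' Read a phylogeny from newick text or file
#'
#' Thin wrapper around [ape::read.tree()] that validates the tree for use in
#' this package and fixes a reproducible branch ordering. Polytomies and
#' unrooted (basal multifurcation) trees are preserved, never arbitrarily
#' resolved. Edges are reordered postorder at parse time so that
#' [branch_index()] is stable across sessions; RER matrix columns join on
#' this ordering.
#'
#' @param text Newick string (exactly one tree). Mutually exclusive with
#'   `file`.
#' @param file Path to a newick file.
#' @return An [ape::phylo] object in postorder edge ordering. Missing branch
#'   lengths default to 0.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  tree <- tryCatch(
    if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) stop("newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tree)) stop("newick parse error: no tree found")
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected exactly one tree")
    tree <- tree[[1L]]
  }
  validate_tree(tree)
}

#' @keywords internal
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0, nrow(tree$edge))
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  stats::reorder(tree, "postorder")
}

#' Write a phylogeny as newick
#'
#' Deterministic output: children in stored order, branch lengths at full
#' precision. Trees whose lengths are all zero and that were parsed from a
#' length-free newick can be written without `:` fields via
#' `lengths = FALSE`.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @param lengths Write branch lengths? Default `TRUE` when present.
#' @param digits Significant digits for branch lengths.
#' @return The newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL, lengths = !is.null(tree$edge.length),
                         digits = 15) {
  tr <- tree
  if (!lengths) tr$edge.length <- NULL
  s <- ape::write.tree(tr, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Branch index table for a phylogeny
#'
#' One row per non-root edge in the package's canonical (postorder) branch
#' ordering; `branch` is the column index RER matrices must use.
#'
#' @param tree A `phylo` object (will be put in postorder if it is not).
#' @return `data.frame` with columns `branch`, `parent`, `child`, `length`
#'   and `label` (tip label for terminal branches, `NA` otherwise).
#' @export
branch_index <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2L]
  data.frame(
    branch = seq_len(nrow(tree$edge)),
    parent = tree$edge[, 1L],
    child = child,
    length = tree$edge.length,
    label = ifelse(child <= ntip, tree$tip.label[pmin(child, ntip)], NA_character_),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
tree_height <- function(tree) {
  nd <- ape::node.depth.edgelength(tree)
  max(nd[seq_len(length(tree$tip.label))])
}

#' Composite-edge paths for a species subset
#'
#' When species are dropped from the master tree, internal nodes of degree 2
#' disappear and chains of master edges collapse into single "composite"
#' edges of the induced subtree. The path map records, for every branch of
#' the induced subtree, the ordered (ancestor to descendant) master branches
#' it spans. The induced subtree is rooted at the most recent common
#' ancestor of the retained species; master edges above the MRCA are not
#' part of any path, matching [ape::keep.tip()] semantics.
#'
#' @param master Master phylogeny (`phylo`).
#' @param kept_species Character vector of retained tip labels
#'   (at least 2, all present in `master`).
#' @return Object of class `path_map`: list with elements `tree` (the induced
#'   `phylo`, postorder), `paths` (list, one integer vector of master branch
#'   ids per induced branch, ancestor to descendant), `master_branches`
#'   (the master [branch_index()] table) and `kept` (the species).
#' @export
build_paths <- function(master, kept_species) {
  master <- stats::reorder(master, "postorder")
  tips <- master$tip.label
  kept_species <- as.character(kept_species)
  unknown <- setdiff(kept_species, tips)
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "))
  kept_species <- unique(kept_species)
  if (length(kept_species) < 2L)
    stop("need at least 2 retained species")

  ntip <- length(tips)
  nnode <- ntip + master$Nnode
  edge <- master$edge
  parent_of <- integer(nnode)
  parent_edge <- integer(nnode)          # branch id of edge above each node
  parent_of[edge[, 2L]] <- edge[, 1L]
  parent_edge[edge[, 2L]] <- seq_len(nrow(edge))

  keep <- tips %in% kept_species
  nkept <- integer(nnode)
  nkept[seq_len(ntip)] <- as.integer(keep)
  for (e in seq_len(nrow(edge)))         # postorder accumulate
    nkept[edge[e, 1L]] <- nkept[edge[e, 1L]] + nkept[edge[e, 2L]]
  K <- sum(keep)

  # MRCA = deepest node subtending all kept tips
  depth <- integer(nnode)
  root <- ntip + 1L
  for (e in rev(seq_len(nrow(edge))))    # preorder
    depth[edge[e, 2L]] <- depth[edge[e, 1L]] + 1L
  cands <- which(nkept == K)
  mrca <- cands[which.max(depth[cands])]

  # vertices of the induced subtree: kept tips, branching nodes, the MRCA
  nchild_kept <- integer(nnode)
  for (e in seq_len(nrow(edge)))
    if (nkept[edge[e, 2L]] > 0L)
      nchild_kept[edge[e, 1L]] <- nchild_kept[edge[e, 1L]] + 1L
  is_vertex <- (seq_len(nnode) <= ntip & nkept[seq_len(nnode)] > 0L) |
    (nchild_kept >= 2L)
  is_vertex[mrca] <- TRUE
  below_mrca <- nkept > 0L & depth >= depth[mrca]
  below_mrca[mrca] <- TRUE
  is_vertex <- is_vertex & below_mrca
  verts <- which(is_vertex)

  # walk each non-MRCA vertex up to its nearest ancestral vertex
  comp_parent <- integer(0)
  comp_child <- integer(0)
  comp_paths <- list()
  for (v in setdiff(verts, mrca)) {
    chain <- integer(0)
    node <- v
    repeat {
      chain <- c(chain, parent_edge[node])
      node <- parent_of[node]
      if (is_vertex[node]) break
    }
    comp_parent <- c(comp_parent, node)
    comp_child <- c(comp_child, v)
    comp_paths[[length(comp_paths) + 1L]] <- rev(chain)  # ancestor -> descendant
  }

  # assemble the induced phylo with renumbered nodes (tips first)
  new_tips <- verts[verts <= ntip]
  new_int <- c(mrca, setdiff(verts[verts > ntip], mrca))
  remap <- integer(nnode)
  remap[new_tips] <- seq_along(new_tips)
  remap[new_int] <- length(new_tips) + seq_along(new_int)
  lens <- vapply(comp_paths, function(p) sum(master$edge.length[p]), 0)
  sub <- list(
    edge = cbind(remap[comp_parent], remap[comp_child]),
    edge.length = lens,
    tip.label = tips[new_tips],
    Nnode = length(new_int)
  )
  class(sub) <- "phylo"
  attr(sub, "order") <- NULL
  ord <- order_postorder(sub)
  sub$edge <- sub$edge[ord, , drop = FALSE]
  sub$edge.length <- sub$edge.length[ord]
  attr(sub, "order") <- "postorder"
  structure(
    list(tree = sub, paths = comp_paths[ord],
         master_branches = branch_index(master), kept = sub$tip.label),
    class = "path_map"
  )
}

# postorder permutation of an edge matrix built child-first by hand
#' @keywords internal
order_postorder <- function(tree) {
  tr <- tree
  attr(tr, "order") <- NULL
  po <- stats::reorder(tr, "postorder")
  key <- function(e) paste(e[, 1L], e[, 2L])
  match(key(po$edge), key(tree$edge))
}

#' @export
print.path_map <- function(x, ...) {
  cat("Path map:", length(x$kept), "retained species,",
      length(x$paths), "composite branches over",
      nrow(x$master_branches), "master branches\n")
  invisible(x)
}
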