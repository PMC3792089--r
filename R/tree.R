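#' Read a rooted species tree
#'
#' Reads a Newick file into an [ape::read.tree()] `phylo` object and validates
#' it for use by the detection pipeline: the tree must be rooted and binary,
#' and (when `genomes` is supplied) its tip labels must match the genome ids
#' of the SNP matrix exactly. Branch lengths are optional and default to 1.
#'
#' Node numbering follows the `phylo` convention: tips are `1..n` in tree
#' order, internal nodes are `n+1 .. 2n-1` with the root at `n+1`. All event
#' reports refer to these numbers.
#'
#' @param path path to a Newick file.
#' @param genomes optional character vector of genome ids to validate tip
#'   labels against.
#' @return A `phylo` object.
#' @export
read_tree <- function(path, genomes = NULL) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick in ", path)
  validate_tree(phy, genomes)
}

#' @rdname read_tree
#' @param phy a `phylo` object to validate in place.
#' @export
validate_tree <- function(phy, genomes = NULL) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  if (!ape::is.rooted(phy))
    stop("tree is unrooted (trifurcating root); root it first, e.g. with root_by_homoplasy()")
  if (!ape::is.binary(phy)) stop("tree must be binary")
  if (!is.null(genomes)) {
    extra <- setdiff(phy$tip.label, genomes)
    miss <- setdiff(genomes, phy$tip.label)
    if (length(extra) || length(miss))
      stop("tree/SNP genome mismatch; in tree only: [",
           paste(extra, collapse = ", "), "]; in SNP matrix only: [",
           paste(miss, collapse = ", "), "]")
  }
  phy
}

# Indexed view of a phylo tree used by every algorithm: parent pointers,
# children lists, post-order, and descendant sets (parent pointers and
# descendant sets are cross-checked by independent traversals in tests).
tree_index <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, n_node)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  children <- vector("list", n_node)
  for (i in seq_len(nrow(phy$edge)))
    children[[phy$edge[i, 1]]] <- c(children[[phy$edge[i, 1]]], phy$edge[i, 2])
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("tree must have exactly one root")
  edge_len <- rep(NA_real_, n_node)
  edge_len[phy$edge[, 2]] <- if (is.null(phy$edge.length)) 1 else phy$edge.length
  # post-order over node ids (children before parents)
  post <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    post <- c(post, v)
    stack <- c(stack, children[[v]])
  }
  post <- rev(post)
  is_leaf <- seq_len(n_node) <= n_tip
  desc <- vector("list", n_node) # proper descendants
  for (v in post) {
    d <- integer(0)
    for (ch in children[[v]]) d <- c(d, ch, desc[[ch]])
    desc[[v]] <- d
  }
  list(n_tip = n_tip, n_node = n_node, root = root, parent = parent,
       children = children, edge_len = edge_len, postorder = post,
       is_leaf = is_leaf, desc = desc, labels = phy$tip.label)
}

#' Eligible HRE donor nodes for a destination
#'
#' A node may receive a horizontally transferred segment from any node of the
#' tree that is neither itself nor one of its proper descendants (ancestors,
#' the root, and leaves all qualify). The root is never a destination and has
#' an empty donor set by convention.
#'
#' @param phy a rooted binary `phylo` tree.
#' @param dest destination node id.
#' @return Sorted integer vector of eligible donor node ids.
#' @export
eligible_sources <- function(phy, dest) {
  idx <- if (is.list(phy) && !inherits(phy, "phylo")) phy else tree_index(phy)
  if (dest < 1 || dest > idx$n_node) stop("no such node: ", dest)
  if (dest == idx$root) return(integer(0))
  sort(setdiff(seq_len(idx$n_node), c(dest, idx$desc[[dest]])))
}

# --- rooting by homoplasy ----------------------------------------------------

# tip-set "below" each edge (child side) for an arbitrary phylo orientation
edge_tipsets <- function(phy) {
  idx <- tree_index(phy)
  lapply(seq_len(nrow(phy$edge)), function(i) {
    ch <- phy$edge[i, 2]
    sort(c(if (ch <= idx$n_tip) ch, idx$desc[[ch]][idx$desc[[ch]] <= idx$n_tip]))
  })
}

# clade system (list of tip-id sets) induced by rooting an unrooted tree on
# edge `e`, derived purely from the splits: the clade contributed by edge f is
# the side of f's split that does not contain e.
clades_for_rooting <- function(tipsets, n_tip, e) {
  all_tips <- seq_len(n_tip)
  Be <- tipsets[[e]]
  clades <- list(Be, setdiff(all_tips, Be), all_tips)
  for (f in seq_along(tipsets)) {
    if (f == e) next
    Bf <- tipsets[[f]]
    if (all(Be %in% Bf)) clades <- c(clades, list(setdiff(all_tips, Bf)))
    else clades <- c(clades, list(Bf))
  }
  unique(lapply(clades, sort))
}

# is the allele column (ints, NA = missing) consistent with vertical
# inheritance under a clade system: every observed allele class must equal
# some clade restricted to the observed tips
column_fits_clades <- function(column, clades) {
  obs <- which(!is.na(column))
  if (length(obs) == 0L) return(TRUE)
  keys <- vapply(clades, function(cl) paste(intersect(cl, obs), collapse = ","), "")
  for (a in unique(column[obs])) {
    cls <- paste(obs[column[obs] == a], collapse = ",")
    if (!cls %in% keys) return(FALSE)
  }
  TRUE
}

#' Root an unrooted tree by minimizing homoplastic loci
#'
#' Considers rooting the tree on every edge and counts, for each candidate
#' rooting, the loci whose allele pattern cannot be mapped onto the rooted
#' tree: a locus is consistent only if each of its observed allele classes is
#' exactly the set of observed leaves descending from some node. The rooting
#' with the fewest inconsistent (homoplastic) loci wins; ties go to the first
#' edge in the tree's edge-matrix order.
#'
#' @param phy an unrooted (or rooted; it is treated as unrooted) binary
#'   `phylo` with at least 3 tips.
#' @param leaf_alleles character or integer matrix, rows = tips (rownames are
#'   tip labels or rows in tip order), columns = loci; NA / "." = missing.
#' @return The rooted `phylo`, with attributes `homoplasy_count` (the
#'   minimum) and `root_edge_index`.
#' @export
root_by_homoplasy <- function(phy, leaf_alleles) {
  if (length(phy$tip.label) < 3L) stop("need at least 3 leaves to root")
  un <- ape::unroot(phy)
  if (is.null(un$edge.length)) un$edge.length <- rep(1, nrow(un$edge))
  alle <- as_allele_matrix(leaf_alleles, un$tip.label)
  tipsets <- edge_tipsets(un)
  n_tip <- length(un$tip.label)
  counts <- vapply(seq_len(nrow(un$edge)), function(e) {
    clades <- clades_for_rooting(tipsets, n_tip, e)
    sum(!apply(alle, 2L, column_fits_clades, clades = clades))
  }, 0)
  best <- which.min(counts) # which.min takes the first on ties
  child <- un$edge[best, 2]
  rooted <- phytools::reroot(un, child, position = un$edge.length[best] / 2)
  rooted <- validate_tree(rooted)
  attr(rooted, "homoplasy_count") <- counts[best]
  attr(rooted, "root_edge_index") <- best
  rooted
}

# normalize a leaf allele matrix: integer coding, rows ordered by tip labels
as_allele_matrix <- function(x, tip_labels) {
  if (is.character(x)) {
    m <- matrix(encode_allele(x), nrow = nrow(x), dimnames = dimnames(x))
  } else m <- x
  if (!is.null(rownames(m))) {
    if (!all(tip_labels %in% rownames(m)))
      stop("allele matrix rownames do not cover all tip labels")
    m <- m[tip_labels, , drop = FALSE]
  } else if (nrow(m) != length(tip_labels)) {
    stop("allele matrix must have one row per tip")
  }
  storage.mode(m) <- "integer"
  m
}
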