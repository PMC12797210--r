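#' Read and validate a rooted newick tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces what the
#' simulator needs: a rooted topology, branch lengths on every edge,
#' nonnegative lengths, and unique leaf names.
#'
#' @param x Path to a newick file, or a newick string.
#' @return An \code{ape} \code{phylo} object.
#' @export
read_newick <- function(x) {
  tr <- if (length(x) == 1L && !grepl("(", x, fixed = TRUE) && file.exists(x))
    ape::read.tree(x)
  else
    ape::read.tree(text = x)
  if (is.null(tr)) stop("could not parse newick input", call. = FALSE)
  validate_sim_tree(tr)
  tr
}

validate_sim_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo tree", call. = FALSE)
  if (!ape::is.rooted(tr)) stop("tree must be rooted", call. = FALSE)
  if (is.null(tr$edge.length))
    stop("tree must have branch lengths on all edges", call. = FALSE)
  if (any(is.na(tr$edge.length)) || any(tr$edge.length < 0))
    stop("branch lengths must be nonnegative", call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("leaf names must be unique", call. = FALSE)
  invisible(tr)
}

#' Preorder topology of a phylo tree
#'
#' Edges sorted root-first so a parent's sequence always exists before
#' its children are simulated. Internal nodes without labels are named
#' \code{N1..Nk} in node-id order (the root is \code{N1}).
#'
#' @param tr A validated \code{phylo}.
#' @return List with \code{edges} (2-column matrix of node ids,
#'   preorder), \code{lengths}, \code{root}, \code{n_nodes},
#'   \code{labels} (per node id), and \code{tips} (tip node ids).
#' @keywords internal
tree_topology <- function(tr) {
  validate_sim_tree(tr)
  ntip <- length(tr$tip.label)
  n_nodes <- ntip + tr$Nnode
  root <- ntip + 1L
  ord <- reorder(tr, order = "cladewise")  # parent-before-child edge order
  labels <- character(n_nodes)
  labels[seq_len(ntip)] <- tr$tip.label
  internal <- (ntip + 1L):n_nodes
  if (!is.null(tr$node.label) && all(nzchar(tr$node.label))) {
    labels[internal] <- tr$node.label
  } else {
    labels[internal] <- paste0("N", seq_along(internal))
  }
  list(edges = ord$edge, lengths = ord$edge.length, root = root,
       n_nodes = n_nodes, labels = labels, tips = seq_len(ntip))
}

# deterministic per-branch substream seed below 2^31
derive_seed <- function(seed, node_id, salt) {
  s <- (as.double(seed) %% 2147483647) + 1
  v <- (s * 48271 + as.double(node_id) * 16807 + as.double(salt) * 69621)
  as.integer(v %% 2147483629)
}
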