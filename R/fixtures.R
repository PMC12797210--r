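#' Reproducible synthetic tree fixtures
#'
#' Generates random rooted trees emulating a mammalian orthologous-gene
#' regime: a fixed leaf count and independent exponentially distributed
#' branch lengths (right-skewed, standard deviation equal to the mean)
#' with a chosen mean in substitutions per site.
#'
#' @param n_trees Number of trees.
#' @param n_leaves Leaves per tree (default 40).
#' @param mean_branch_length Mean branch length (default 0.038).
#' @param seed Master seed.
#' @param dir Optional directory: each tree is written as
#'   \code{tree_<i>.nwk}.
#' @return List of \code{phylo} trees (invisibly returns file paths in
#'   attribute \code{"paths"} when \code{dir} is given).
#' @export
generate_fixtures <- function(n_trees, n_leaves = 40L,
                              mean_branch_length = 0.038,
                              seed = 1L, dir = NULL) {
  trees <- vector("list", n_trees)
  paths <- character(0)
  for (i in seq_len(n_trees)) {
    set.seed(derive_seed(seed, i, 3L))
    tr <- ape::rtree(n_leaves, rooted = TRUE)
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / mean_branch_length)
    tr$tip.label <- sprintf("t%02d", seq_len(n_leaves))
    trees[[i]] <- tr
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      p <- file.path(dir, sprintf("tree_%03d.nwk", i))
      ape::write.tree(tr, file = p)
      paths <- c(paths, p)
    }
  }
  if (!is.null(dir)) attr(trees, "paths") <- paths
  trees
}

#' Operation-count benchmark of the indel engines
#'
#' Replays identical per-branch event streams through the instrumented
#' engines and records, per branch, the bookkeeping work each one did:
#' element updates for the naive engine (sum of sequence lengths at each
#' event), blocks scanned for the block list, and AVL nodes visited for
#' the block tree. This is the qualitative content of a timing benchmark
#' without wall-clock claims: naive work grows like k n', list work like
#' k b, and tree work like k log b.
#'
#' @param trees List of \code{phylo} trees (e.g. from
#'   [generate_fixtures()]).
#' @param config A [sim_config()]; its engine field is ignored (all
#'   engines run).
#' @return data.frame with one row per (tree, branch): columns
#'   \code{tree}, \code{branch}, \code{k} (events), \code{n0} (parent
#'   length), \code{b} (final block count), \code{naive_ops},
#'   \code{list_ops}, \code{avl_ops}.
#' @export
benchmark_operations <- function(trees, config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list()
  for (ti in seq_along(trees)) {
    topo <- tree_topology(trees[[ti]])
    lens <- integer(topo$n_nodes)
    lens[topo$root] <- config$root_length
    for (e in seq_len(nrow(topo$edges))) {
      par <- topo$edges[e, 1L]; child <- topo$edges[e, 2L]
      set.seed(derive_seed(config$seed + ti, child, 1L))
      sim <- simulate_branch_events(lens[par], topo$lengths[e],
                                    config$params)
      ev <- sim$events
      # naive: O(n) element updates per event
      n <- lens[par]; naive_ops <- 0
      if (nrow(ev) > 0) {
        for (i in seq_len(nrow(ev))) {
          naive_ops <- naive_ops + n
          n <- n + ifelse(ev$kind[i] == "insertion", ev$eff_length[i],
                          -ev$eff_length[i])
        }
      }
      blocks <- evolve_branch_blocks(lens[par], ev, instrument = TRUE)
      st <- attr(blocks, "stats")
      avl <- evolve_branch_avl(lens[par], ev)
      rows[[length(rows) + 1L]] <- data.frame(
        tree = ti, branch = topo$labels[child], k = nrow(ev),
        n0 = lens[par], b = length(blocks),
        naive_ops = naive_ops,
        list_ops = if (nrow(ev)) sum(st$visits) else 0L,
        avl_ops = avl$visits)
      lens[child] <- sim$final_length
    }
  }
  do.call(rbind, rows)
}

#' Synthetic block sequence of a given size
#'
#' Deterministic valid block sequence with \code{b} blocks (anchor block
#' first, disjoint increasing OPs, alternating AP sizes), used to measure
#' how locate cost scales with the number of blocks.
#'
#' @param b Number of blocks (\code{>= 1}).
#' @return A block sequence.
#' @export
synthetic_blocks <- function(b) {
  stopifnot(b >= 1L)
  blocks <- vector("list", b)
  blocks[[1L]] <- c(0L, 3L, 1L)
  s <- 4L
  for (j in seq_len(b - 1L) + 1L) {
    blocks[[j]] <- c(s, 2L, j %% 2L)
    s <- s + 3L
  }
  blocks
}

#' Locate-cost scaling of the list and tree stores
#'
#' For each block count \code{b}, builds the same synthetic block
#' sequence in both stores and performs \code{n_queries} random locates,
#' returning the mean number of blocks scanned (list) and nodes visited
#' (AVL tree). List cost grows linearly with \code{b}; tree cost grows
#' logarithmically.
#'
#' @param b_values Integer vector of block counts.
#' @param n_queries Locates per block count.
#' @param seed RNG seed for the query positions.
#' @return data.frame with columns \code{b}, \code{list_visits},
#'   \code{avl_visits}.
#' @export
locate_scaling <- function(b_values, n_queries = 200L, seed = 1L) {
  out <- data.frame(b = as.integer(b_values), list_visits = NA_real_,
                    avl_visits = NA_real_)
  for (i in seq_along(b_values)) {
    blocks <- synthetic_blocks(b_values[i])
    tree <- avl_from_blocks(blocks)
    total <- avl_t(tree, tree$root)
    set.seed(derive_seed(seed, b_values[i], 4L))
    qs <- sample.int(total, n_queries, replace = TRUE)
    lv <- 0
    for (q in qs) lv <- lv + locate_block(blocks, q)$index
    tree$visits <- 0L
    for (q in qs) avl_locate(tree, q)
    out$list_visits[i] <- lv / n_queries
    out$avl_visits[i] <- tree$visits / n_queries
  }
  out
}
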