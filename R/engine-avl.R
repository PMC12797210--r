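#' AVL block-tree engine
#'
#' Order-statistic AVL storage of the block sequence of one branch. Nodes
#' are kept in in-order block order and augmented with two subtree
#' aggregates: the element total (sum of \code{length + insertion} over
#' the subtree, which drives the cumulative-offset search) and the node
#' count (which drives rank addressing). Locating, splitting and removing
#' a block all cost O(log b); positions are never stored explicitly, so no
#' renumbering is needed after an event.
#'
#' The tree is a mutable handle (an environment holding index vectors);
#' all update functions modify it in place and return it invisibly.
#'
#' @name block_tree_engine
NULL

avl_new <- function(capacity = 16L) {
  tr <- new.env(parent = emptyenv())
  tr$S <- integer(capacity); tr$L <- integer(capacity); tr$I <- integer(capacity)
  tr$lft <- integer(capacity); tr$rgt <- integer(capacity)
  tr$ht <- integer(capacity); tr$cnt <- integer(capacity); tr$tot <- integer(capacity)
  tr$n <- 0L
  tr$root <- 0L
  tr$visits <- 0L
  tr
}

avl_grow <- function(tr) {
  cap <- length(tr$S) * 2L
  for (f in c("S", "L", "I", "lft", "rgt", "ht", "cnt", "tot"))
    tr[[f]] <- c(tr[[f]], integer(cap - length(tr[[f]])))
  invisible(tr)
}

avl_node <- function(tr, S, L, I) {
  if (tr$n == length(tr$S)) avl_grow(tr)
  i <- tr$n + 1L
  tr$n <- i
  tr$S[i] <- S; tr$L[i] <- L; tr$I[i] <- I
  tr$lft[i] <- 0L; tr$rgt[i] <- 0L
  tr$ht[i] <- 1L; tr$cnt[i] <- 1L; tr$tot[i] <- L + I
  i
}

avl_h <- function(tr, i) if (i == 0L) 0L else tr$ht[i]
avl_c <- function(tr, i) if (i == 0L) 0L else tr$cnt[i]
avl_t <- function(tr, i) if (i == 0L) 0L else tr$tot[i]

avl_fix <- function(tr, i) {
  l <- tr$lft[i]; r <- tr$rgt[i]
  tr$ht[i] <- 1L + max(avl_h(tr, l), avl_h(tr, r))
  tr$cnt[i] <- 1L + avl_c(tr, l) + avl_c(tr, r)
  tr$tot[i] <- tr$L[i] + tr$I[i] + avl_t(tr, l) + avl_t(tr, r)
  invisible(NULL)
}

avl_rot_right <- function(tr, i) {
  l <- tr$lft[i]
  tr$lft[i] <- tr$rgt[l]
  tr$rgt[l] <- i
  avl_fix(tr, i); avl_fix(tr, l)
  l
}

avl_rot_left <- function(tr, i) {
  r <- tr$rgt[i]
  tr$rgt[i] <- tr$lft[r]
  tr$lft[r] <- i
  avl_fix(tr, i); avl_fix(tr, r)
  r
}

avl_balance <- function(tr, i) {
  avl_fix(tr, i)
  bf <- avl_h(tr, tr$lft[i]) - avl_h(tr, tr$rgt[i])
  if (bf > 1L) {
    l <- tr$lft[i]
    if (avl_h(tr, tr$lft[l]) < avl_h(tr, tr$rgt[l]))
      tr$lft[i] <- avl_rot_left(tr, l)
    return(avl_rot_right(tr, i))
  }
  if (bf < -1L) {
    r <- tr$rgt[i]
    if (avl_h(tr, tr$rgt[r]) < avl_h(tr, tr$lft[r]))
      tr$rgt[i] <- avl_rot_right(tr, r)
    return(avl_rot_left(tr, i))
  }
  i
}

# insert node `nd` so that it becomes the (pos)-th block in in-order
avl_insert_at <- function(tr, i, pos, nd) {
  if (i == 0L) return(nd)
  lc <- avl_c(tr, tr$lft[i])
  if (pos <= lc + 1L) {
    tr$lft[i] <- avl_insert_at(tr, tr$lft[i], pos, nd)
  } else {
    tr$rgt[i] <- avl_insert_at(tr, tr$rgt[i], pos - lc - 1L, nd)
  }
  avl_balance(tr, i)
}

avl_leftmost <- function(tr, i) {
  while (tr$lft[i] != 0L) i <- tr$lft[i]
  i
}

# remove the block at in-order rank `pos`
avl_remove_at <- function(tr, i, pos) {
  lc <- avl_c(tr, tr$lft[i])
  if (pos <= lc) {
    tr$lft[i] <- avl_remove_at(tr, tr$lft[i], pos)
  } else if (pos == lc + 1L) {
    if (tr$lft[i] == 0L) return(tr$rgt[i])
    if (tr$rgt[i] == 0L) return(tr$lft[i])
    s <- avl_leftmost(tr, tr$rgt[i])
    tr$S[i] <- tr$S[s]; tr$L[i] <- tr$L[s]; tr$I[i] <- tr$I[s]
    tr$rgt[i] <- avl_remove_at(tr, tr$rgt[i], 1L)
  } else {
    tr$rgt[i] <- avl_remove_at(tr, tr$rgt[i], pos - lc - 1L)
  }
  avl_balance(tr, i)
}

# fetch / overwrite the block at rank `pos` (overwrite fixes totals upward)
avl_get_at <- function(tr, pos) {
  i <- tr$root
  repeat {
    lc <- avl_c(tr, tr$lft[i])
    if (pos <= lc) { i <- tr$lft[i] }
    else if (pos == lc + 1L) return(i)
    else { pos <- pos - lc - 1L; i <- tr$rgt[i] }
  }
}

avl_set_at <- function(tr, i, pos, S, L, I) {
  lc <- avl_c(tr, tr$lft[i])
  if (pos <= lc) {
    avl_set_at(tr, tr$lft[i], pos, S, L, I)
  } else if (pos == lc + 1L) {
    tr$S[i] <- S; tr$L[i] <- L; tr$I[i] <- I
  } else {
    avl_set_at(tr, tr$rgt[i], pos - lc - 1L, S, L, I)
  }
  avl_fix(tr, i)
  invisible(NULL)
}

#' Build an AVL block tree from a block sequence
#'
#' @param blocks A block sequence (list of \code{c(start, length,
#'   insertion)} triples).
#' @return An AVL block-tree handle whose in-order traversal yields
#'   exactly \code{blocks}.
#' @export
avl_from_blocks <- function(blocks) {
  tr <- avl_new(max(16L, length(blocks)))
  build <- function(lo, hi) {
    if (lo > hi) return(0L)
    mid <- (lo + hi) %/% 2L
    b <- blocks[[mid]]
    i <- avl_node(tr, b[1L], b[2L], b[3L])
    tr$lft[i] <- build(lo, mid - 1L)
    tr$rgt[i] <- build(mid + 1L, hi)
    avl_fix(tr, i)
    i
  }
  tr$root <- build(1L, length(blocks))
  tr
}

#' Flatten an AVL block tree to a block sequence
#'
#' In-order traversal, O(b).
#'
#' @param tree An AVL block-tree handle.
#' @return A block sequence (list of integer triples).
#' @export
flatten <- function(tree) {
  out <- vector("list", avl_c(tree, tree$root))
  k <- 0L
  walk <- function(i) {
    if (i == 0L) return(invisible(NULL))
    walk(tree$lft[i])
    k <<- k + 1L
    out[[k]] <<- c(tree$S[i], tree$L[i], tree$I[i])
    walk(tree$rgt[i])
  }
  walk(tree$root)
  out
}

#' Locate a block in the AVL tree by cumulative offset
#'
#' Descends using subtree element totals, giving the same
#' \code{(block, residual offset)} answer as [locate_block()] on the
#' flattened sequence, in O(log b) node visits. Visited nodes are counted
#' on the handle's \code{visits} field.
#'
#' @param tree An AVL block-tree handle.
#' @param q Scan position (see [locate_block()]).
#' @param deletion If \code{TRUE}, use deletion-scan semantics (find the
#'   block containing element offset \code{q}); otherwise insertion-scan
#'   semantics (first block whose cumulative total reaches \code{q}).
#' @return List with \code{rank} (in-order block index) and \code{offset}.
#' @export
avl_locate <- function(tree, q, deletion = FALSE) {
  if (q < 0 || q > avl_t(tree, tree$root))
    stop("position ", q, " outside the block tree", call. = FALSE)
  q <- as.integer(q)
  i <- tree$root
  rank <- 0L
  repeat {
    if (i == 0L) stop("position ", q, " beyond the end of the block tree",
                      call. = FALSE)
    tree$visits <- tree$visits + 1L
    tl <- avl_t(tree, tree$lft[i])
    Ti <- tree$L[i] + tree$I[i]
    inleft <- if (deletion) q < tl else (tree$lft[i] != 0L && q <= tl)
    if (inleft) {
      i <- tree$lft[i]
    } else {
      q2 <- q - tl
      here <- if (deletion) q2 < Ti else q2 <= Ti
      if (here)
        return(list(rank = rank + avl_c(tree, tree$lft[i]) + 1L, offset = q2))
      q <- q2 - Ti
      rank <- rank + avl_c(tree, tree$lft[i]) + 1L
      i <- tree$rgt[i]
    }
  }
}

#' Apply one indel event to an AVL block tree
#'
#' Same block-level semantics as [apply_insertion_blocks()] and
#' [apply_deletion_blocks()] (including the anchor-counting scan
#' arithmetic and orphan-AP reattachment), realized with rank-addressed
#' node updates, insertions and removals followed by rebalancing.
#' Aggregates are repaired along the search path.
#'
#' @param tree An AVL block-tree handle (modified in place).
#' @param kind \code{"insertion"} or \code{"deletion"}.
#' @param pos Scan position (insertions) or first deleted position
#'   (deletions), as for the list-engine update functions.
#' @param len Event size (effective size for deletions).
#' @return The handle, invisibly.
#' @export
apply_event_avl <- function(tree, kind, pos, len) {
  len <- as.integer(len)
  if (kind == "insertion") {
    loc <- avl_locate(tree, pos)
    i <- avl_get_at(tree, loc$rank)
    S <- tree$S[i]; L <- tree$L[i]; I <- tree$I[i]
    r <- loc$offset
    if (loc$rank == 1L) {
      if (r >= L - 1L) {
        avl_set_at(tree, tree$root, loc$rank, S, L, I + len)
      } else {
        avl_set_at(tree, tree$root, loc$rank, S, r + 1L, len)
        nd <- avl_node(tree, S + r + 1L, L - r - 1L, I)
        tree$root <- avl_insert_at(tree, tree$root, loc$rank + 1L, nd)
      }
    } else {
      if (r >= L) {
        avl_set_at(tree, tree$root, loc$rank, S, L, I + len)
      } else {
        avl_set_at(tree, tree$root, loc$rank, S, r, len)
        nd <- avl_node(tree, S + r, L - r, I)
        tree$root <- avl_insert_at(tree, tree$root, loc$rank + 1L, nd)
      }
    }
  } else if (kind == "deletion") {
    if (pos < 1L) stop("the anchor position cannot be deleted", call. = FALSE)
    m <- len
    while (m > 0L) {
      loc <- avl_locate(tree, pos, deletion = TRUE)
      i <- avl_get_at(tree, loc$rank)
      S <- tree$S[i]; L <- tree$L[i]; I <- tree$I[i]; Ti <- L + I
      off <- loc$offset
      del <- min(Ti - off, m)
      e_end <- off + del - 1L
      op_before <- min(off, L)
      ap_before <- max(0L, off - L)
      op_after <- max(0L, L - 1L - e_end)
      ap_after <- max(0L, (Ti - 1L) - max(e_end, L - 1L))
      if (op_after > 0L) {
        if (op_before > 0L) {
          avl_set_at(tree, tree$root, loc$rank, S, op_before, 0L)
          nd <- avl_node(tree, S + e_end + 1L, op_after, I)
          tree$root <- avl_insert_at(tree, tree$root, loc$rank + 1L, nd)
        } else {
          avl_set_at(tree, tree$root, loc$rank, S + e_end + 1L, op_after, I)
        }
      } else {
        kept_ap <- ap_before + ap_after
        if (op_before > 0L) {
          avl_set_at(tree, tree$root, loc$rank, S, op_before, kept_ap)
        } else {
          tree$root <- avl_remove_at(tree, tree$root, loc$rank)
          if (kept_ap > 0L) {
            p <- avl_get_at(tree, loc$rank - 1L)
            avl_set_at(tree, tree$root, loc$rank - 1L,
                       tree$S[p], tree$L[p], tree$I[p] + kept_ap)
          }
        }
      }
      m <- m - del
    }
  } else {
    stop("unknown event kind: ", kind, call. = FALSE)
  }
  invisible(tree)
}

#' Evolve a branch with the AVL block-tree engine
#'
#' Same event semantics and physical-slot-to-scan-coordinate conversion
#' as [evolve_branch_blocks()], with all block operations running in
#' O(log b).
#'
#' @param n0 Parent sequence length.
#' @param events Event data.frame from [simulate_branch_events()].
#' @return The final AVL block-tree handle; \code{flatten()} it to get
#'   the block sequence.
#' @export
evolve_branch_avl <- function(n0, events) {
  tree <- avl_from_blocks(initial_block_sequence(n0))
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      if (events$kind[i] == "insertion") {
        first <- avl_leftmost(tree, tree$root)
        T1 <- tree$L[first] + tree$I[first]
        q <- events$pos[i]
        scan_q <- if (q <= T1 - 1L) q else q + 1L
        apply_event_avl(tree, "insertion", scan_q, events$eff_length[i])
      } else {
        apply_event_avl(tree, "deletion", events$pos[i], events$eff_length[i])
      }
    }
  }
  tree
}
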