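#' Naive explicit-sequence engine
#'
#' The reference engine: every event is applied directly to an explicit
#' vector of position identities. Ancestral positions are positive integers
#' (indices into the parent sequence, or root positions at the root);
#' characters inserted along the current branch are fresh tokens. This
#' engine is intentionally O(n) per event and serves as the correctness
#' oracle for the block-based engines.
#'
#' @name naive_engine
NULL

#' Apply a single indel event to an explicit sequence
#'
#' @param seq Integer vector of position identities.
#' @param kind \code{"insertion"} or \code{"deletion"}.
#' @param pos Insertion slot \code{q} in \code{0..length(seq)} (insert
#'   after element \code{q}), or deletion start in \code{1..length(seq)}.
#' @param len Event length; deletions are trimmed at the right edge if they
#'   overrun the sequence.
#' @param fresh Integer vector of \code{len} fresh token ids for an
#'   insertion (defaults to zeros, the anonymous-fresh marker).
#' @return The updated sequence.
#' @export
apply_event_naive <- function(seq, kind, pos, len, fresh = integer(0)) {
  n <- length(seq)
  if (kind == "insertion") {
    if (pos < 0L || pos > n)
      stop("insertion slot out of range: q = ", pos, ", n = ", n, call. = FALSE)
    if (length(fresh) == 0L) fresh <- rep.int(0L, len)
    if (length(fresh) != len)
      stop("need exactly `len` fresh tokens", call. = FALSE)
    append(seq, fresh, after = pos)
  } else if (kind == "deletion") {
    if (pos < 1L || pos > n)
      stop("deletion start out of range: start = ", pos, ", n = ", n,
           call. = FALSE)
    end <- min(pos + len - 1L, n)  # trim to the maximal available size
    seq[-(pos:end)]
  } else {
    stop("unknown event kind: ", kind, call. = FALSE)
  }
}

#' Evolve an explicit sequence along one branch
#'
#' Folds [apply_event_naive()] over a time-ordered event stream. Fresh
#' tokens inserted along the branch are numbered \code{-(counter+1),
#' -(counter+2), ...} from a caller-supplied monotone counter so that
#' every inserted character has a globally unique identity.
#'
#' @param parent Integer vector of parent position identities.
#' @param events Event data.frame from [simulate_branch_events()].
#' @param token_counter Starting value of the fresh-token counter.
#' @return List with \code{seq} (child sequence) and \code{token_counter}
#'   (updated counter).
#' @export
evolve_branch_naive <- function(parent, events, token_counter = 0L) {
  seq <- parent
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      if (events$kind[i] == "insertion") {
        S <- events$eff_length[i]
        fresh <- -(token_counter + seq_len(S))
        token_counter <- token_counter + S
        seq <- apply_event_naive(seq, "insertion", events$pos[i], S, fresh)
      } else {
        seq <- apply_event_naive(seq, "deletion", events$pos[i],
                                 events$eff_length[i])
      }
    }
  }
  list(seq = seq, token_counter = token_counter)
}

#' Child sequence in parent-relative form
#'
#' Relabels a naive child sequence relative to its parent: surviving parent
#' positions keep their index in the parent (1..n), characters inserted on
#' this branch become 0. This is the common currency in which all engines
#' report a branch outcome.
#'
#' @param parent Parent identity vector.
#' @param child Child identity vector produced by [evolve_branch_naive()].
#' @return Integer vector: parent index or 0 for fresh characters.
#' @export
relative_child_naive <- function(parent, child) {
  idx <- match(child, parent)
  idx[is.na(idx)] <- 0L
  as.integer(idx)
}

#' Evolve every node of a tree with the naive engine
#'
#' Preorder recursion from the root: each node's sequence is obtained by
#' replaying that branch's event stream on its parent's sequence. Root
#' positions are labelled 1..n0; insertions carry globally unique negative
#' token ids.
#'
#' @param tree A rooted \code{phylo} tree with branch lengths.
#' @param n0 Root sequence length.
#' @param params An [indel_params()].
#' @param seed Master seed; each branch uses a substream derived from
#'   \code{(seed, child node id)} so streams are traversal-order
#'   independent.
#' @return List with \code{sequences} (per-node identity vectors, indexed
#'   by node id) and \code{events} (per-branch event data.frames).
#' @export
evolve_tree_naive <- function(tree, n0, params, seed = 1L) {
  topo <- tree_topology(tree)
  nseq <- vector("list", topo$n_nodes)
  evs <- vector("list", topo$n_nodes)
  nseq[[topo$root]] <- seq_len(n0)
  counter <- 0L
  for (e in seq_len(nrow(topo$edges))) {
    par <- topo$edges[e, 1L]; child <- topo$edges[e, 2L]
    set.seed(derive_seed(seed, child, 1L))
    sim <- simulate_branch_events(length(nseq[[par]]),
                                  topo$lengths[e], params)
    out <- evolve_branch_naive(nseq[[par]], sim$events, counter)
    counter <- out$token_counter
    nseq[[child]] <- out$seq
    evs[[child]] <- sim$events
  }
  list(sequences = nseq, events = evs)
}
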