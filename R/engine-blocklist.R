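#' Run-length block bookkeeping of a branch
#'
#' A block is a 3-tuple \code{(start, length, insertion)}: a run of
#' contiguous, undisturbed positions from the parent sequence (the
#' original part, OP) followed by characters inserted along the current
#' branch (the added part, AP). \code{start} is the parent coordinate at
#' which the OP begins and \code{length} its size; \code{insertion} is the
#' AP size. A virtual anchor occupies position 0 and is counted inside the
#' first block's OP, so a parent of length \code{n0} starts as the single
#' block \code{(0, n0 + 1, 0)}. Updating the list costs O(b) per event,
#' where \code{b} is the number of blocks.
#'
#' Block sequences are represented as plain lists of integer triples;
#' [blocks_df()] gives a data.frame view.
#'
#' @name block_list_engine
NULL

#' Initial single-block sequence
#'
#' @param n0 Parent sequence length (\code{>= 0}).
#' @return A block sequence: \code{list(c(0, n0 + 1, 0))}.
#' @examples
#' initial_block_sequence(100)  # list(c(0, 101, 0))
#' @export
initial_block_sequence <- function(n0) {
  if (n0 < 0) stop("n0 must be >= 0", call. = FALSE)
  list(c(0L, as.integer(n0) + 1L, 0L))
}

#' Data.frame view of a block sequence
#'
#' @param blocks A block sequence (list of \code{c(start, length, insertion)}).
#' @return data.frame with columns \code{start}, \code{length},
#'   \code{insertion}.
#' @export
blocks_df <- function(blocks) {
  m <- do.call(rbind, blocks)
  data.frame(start = m[, 1L], length = m[, 2L], insertion = m[, 3L])
}

#' Current sequence length described by a block sequence
#'
#' Sum of block totals minus the virtual anchor.
#'
#' @inheritParams blocks_df
#' @return Integer length.
#' @export
current_length <- function(blocks) {
  tot <- 0L
  for (b in blocks) tot <- tot + b[2L] + b[3L]
  tot - 1L
}

#' Locate the block affected by an event
#'
#' Scans the list cumulatively: while the residual position \code{q}
#' exceeds a block's total \code{T = length + insertion}, subtract
#' \code{T} and move on. Returns the first block whose total is not
#' exhausted, and the residual offset within it.
#'
#' @inheritParams blocks_df
#' @param q Scan position, \code{0 <= q <=} total size of the list.
#' @return List with \code{index} and \code{offset}.
#' @export
locate_block <- function(blocks, q) {
  if (q < 0) stop("q must be >= 0", call. = FALSE)
  j <- 1L
  r <- as.integer(q)
  nb <- length(blocks)
  repeat {
    if (j > nb) stop("position ", q, " beyond the end of the block sequence",
                     call. = FALSE)
    Tj <- blocks[[j]][2L] + blocks[[j]][3L]
    if (r <= Tj) return(list(index = j, offset = r))
    r <- r - Tj
    j <- j + 1L
  }
}

#' Apply an insertion to a block sequence
#'
#' Scan semantics follow the block arithmetic in which the virtual anchor
#' is counted inside the first block: in the anchor block a split at
#' residual offset \code{r} keeps \code{r + 1} elements (anchor included)
#' in the prefix, while in any later block it keeps \code{r} elements. An
#' insertion landing in (or immediately at the end of) a block's AP simply
#' grows that AP. Blocks after the affected one are untouched.
#'
#' @inheritParams blocks_df
#' @param q Scan position of the insertion.
#' @param S Insertion size (\code{>= 1}).
#' @return Updated block sequence.
#' @export
apply_insertion_blocks <- function(blocks, q, S) {
  if (S < 1) stop("insertion size must be >= 1", call. = FALSE)
  loc <- locate_block(blocks, q)
  j <- loc$index; r <- loc$offset
  blk <- blocks[[j]]
  Sj <- blk[1L]; L <- blk[2L]; I <- blk[3L]
  S <- as.integer(S)
  if (j == 1L) {
    if (r >= L - 1L) {           # within (or at the end of) the AP
      blocks[[j]] <- c(Sj, L, I + S)
    } else {                     # split the OP; prefix keeps anchor + r chars
      blocks[[j]] <- c(Sj, r + 1L, S)
      blocks <- append(blocks, list(c(Sj + r + 1L, L - r - 1L, I)), after = j)
    }
  } else {
    if (r >= L) {                # within the AP
      blocks[[j]] <- c(Sj, L, I + S)
    } else {                     # split the OP; prefix keeps r elements
      blocks[[j]] <- c(Sj, r, S)
      blocks <- append(blocks, list(c(Sj + r, L - r, I)), after = j)
    }
  }
  blocks
}

#' Apply a clipped deletion to a block sequence
#'
#' Removes \code{S} consecutive characters starting at current-sequence
#' position \code{start} (the virtual anchor at position 0 is never
#' deletable). A deletion inside one OP splits the block in two, with the
#' AP staying on the suffix; a deletion inside one AP shrinks it; a
#' spanning deletion consumes the tail of the first affected block and
#' continues into subsequent blocks, dropping any block whose OP is fully
#' deleted. If such a block leaves a surviving AP, that orphan AP is
#' appended to the AP of the nearest surviving preceding block (the anchor
#' block always survives, so a home always exists).
#'
#' @inheritParams blocks_df
#' @param start First deleted position (\code{>= 1}), in current-sequence
#'   coordinates.
#' @param S Effective deletion length; \code{start + S - 1} must be within
#'   the current sequence.
#' @return Updated block sequence.
#' @export
apply_deletion_blocks <- function(blocks, start, S) {
  if (start < 1L || S < 1L)
    stop("deletions must start at position >= 1 and have length >= 1",
         call. = FALSE)
  if (start + S - 1L > current_length(blocks))
    stop("deletion extends beyond the end of the sequence", call. = FALSE)
  # walk to the first affected block (element-offset scan; the anchor is
  # element 0 of the first block, so a character position is directly an
  # element offset)
  j <- 1L
  d <- as.integer(start)
  repeat {
    Tj <- blocks[[j]][2L] + blocks[[j]][3L]
    if (d < Tj) break
    d <- d - Tj
    j <- j + 1L
  }
  out <- blocks[seq_len(j - 1L)]
  m <- as.integer(S)
  off <- d
  nb <- length(blocks)
  while (m > 0L) {
    blk <- blocks[[j]]
    Sj <- blk[1L]; L <- blk[2L]; I <- blk[3L]; Tj <- L + I
    del <- min(Tj - off, m)
    e_end <- off + del - 1L
    op_before <- min(off, L)
    ap_before <- max(0L, off - L)
    op_after <- max(0L, L - 1L - e_end)
    ap_after <- (Tj - 1L) - max(e_end, L - 1L)
    if (op_after > 0L) {
      # deletion ends inside this block's OP: AP fully kept on the suffix
      if (op_before > 0L) out <- c(out, list(c(Sj, op_before, 0L)))
      out <- c(out, list(c(Sj + e_end + 1L, op_after, I)))
    } else {
      kept_ap <- ap_before + max(0L, ap_after)
      if (op_before > 0L) {
        out <- c(out, list(c(Sj, op_before, kept_ap)))
      } else if (kept_ap > 0L) {
        # orphan AP: OP fully deleted, surviving AP joins the preceding block
        prev <- out[[length(out)]]
        out[[length(out)]] <- c(prev[1L], prev[2L], prev[3L] + kept_ap)
      }
      # else the whole block is consumed
    }
    m <- m - del
    j <- j + 1L
    off <- 0L
    if (m > 0L && j > nb)
      stop("internal error: deletion ran past the block sequence",
           call. = FALSE)
  }
  if (j <= nb) out <- c(out, blocks[j:nb])
  out
}

#' Evolve a branch with the block list engine
#'
#' Folds the insertion/deletion block updates over an engine-agnostic
#' event stream, starting from the single-block representation of the
#' parent. Physical insertion slots are converted to scan coordinates
#' before the update: the anchor-counting block arithmetic places a raw
#' scan position one element left of the physical slot once past the
#' anchor block, so slots beyond the first block's total are shifted by
#' one. Deletion coordinates need no adjustment.
#'
#' @param n0 Parent sequence length.
#' @param events Event data.frame from [simulate_branch_events()].
#' @param instrument If \code{TRUE}, attach an attribute \code{"stats"}
#'   with the per-event block counts and scan visits.
#' @return Final block sequence; with \code{instrument}, attribute
#'   \code{"stats"} holds a data.frame with columns \code{b} (block count
#'   after each event) and \code{visits} (blocks scanned).
#' @export
evolve_branch_blocks <- function(n0, events, instrument = FALSE) {
  blocks <- initial_block_sequence(n0)
  k <- nrow(events)
  bcount <- integer(k); visits <- integer(k)
  if (k > 0) {
    for (i in seq_len(k)) {
      if (events$kind[i] == "insertion") {
        T1 <- blocks[[1L]][2L] + blocks[[1L]][3L]
        q <- events$pos[i]
        scan_q <- if (q <= T1 - 1L) q else q + 1L
        if (instrument) visits[i] <- locate_block(blocks, scan_q)$index
        blocks <- apply_insertion_blocks(blocks, scan_q, events$eff_length[i])
      } else {
        if (instrument)
          visits[i] <- locate_block(blocks,
                                    min(events$pos[i],
                                        current_length(blocks)))$index
        blocks <- apply_deletion_blocks(blocks, events$pos[i],
                                        events$eff_length[i])
      }
      if (instrument) bcount[i] <- length(blocks)
    }
  }
  if (instrument)
    attr(blocks, "stats") <- data.frame(b = bcount, visits = visits)
  blocks
}

#' Child sequence in parent-relative form, from blocks
#'
#' Expands a block sequence into the relative child representation used by
#' the MSA builder: surviving parent positions by index, 0 for characters
#' inserted along the branch.
#'
#' @inheritParams blocks_df
#' @return Integer vector (parent index or 0).
#' @export
blocks_to_relative <- function(blocks) {
  parts <- vector("list", 2L * length(blocks))
  i <- 0L
  first <- TRUE
  for (b in blocks) {
    op <- if (first) {
      if (b[2L] > 1L) (b[1L] + 1L):(b[1L] + b[2L] - 1L) else integer(0)
    } else {
      b[1L]:(b[1L] + b[2L] - 1L)
    }
    first <- FALSE
    i <- i + 1L; parts[[i]] <- op
    if (b[3L] > 0L) { i <- i + 1L; parts[[i]] <- rep.int(0L, b[3L]) }
  }
  as.integer(unlist(parts[seq_len(i)]))
}
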