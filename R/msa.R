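#' Super-sequence of all positions that ever existed
#'
#' The super-sequence is an ordered master template integrating the root
#' sequence with every insertion that occurred anywhere in the simulation.
#' Each element has a unique id (assigned at creation, never reused) and
#' a column flag; each tree node holds a pointer sequence, an ordered list
#' of references into the super-sequence. The final alignment has one
#' column per flagged element, which prevents gap-only columns.
#'
#' Internally the order is a linked list (id 0 is a virtual head), so a
#' run of fresh elements can be spliced after any element in O(run).
#'
#' @name msa_assembly
NULL

#' Initialize a super-sequence
#'
#' Creates elements \code{1..n0} in order, referenced by the root pointer
#' sequence.
#'
#' @param n0 Root sequence length.
#' @return List with \code{super} (a super-sequence handle) and
#'   \code{root_pointers} (integer vector \code{1..n0}).
#' @export
init_super_sequence <- function(n0) {
  ss <- new.env(parent = emptyenv())
  n0 <- as.integer(n0)
  # nxt[id + 1] is the id following `id` (0 = virtual head, -1 = end)
  ss$nxt <- c(if (n0 > 0) seq_len(n0) else integer(0), -1L)
  ss$n <- n0
  list(super = ss, root_pointers = if (n0 > 0) seq_len(n0) else integer(0))
}

# splice `k` fresh elements immediately after element `anchor` (0 = front)
super_insert_run <- function(ss, anchor, k) {
  ids <- ss$n + seq_len(k)
  after <- ss$nxt[anchor + 1L]
  ss$nxt <- c(ss$nxt, integer(k))
  ss$nxt[anchor + 1L] <- ids[1L]
  if (k > 1L) ss$nxt[ids[-k] + 1L] <- ids[-1L]
  ss$nxt[ids[k] + 1L] <- after
  ss$n <- ss$n + k
  ids
}

#' Total order of super-sequence elements
#'
#' @param ss A super-sequence handle.
#' @return Integer vector of element ids in template order.
#' @export
super_order <- function(ss) {
  out <- integer(ss$n)
  i <- ss$nxt[1L]
  k <- 0L
  while (i != -1L) {
    k <- k + 1L
    out[k] <- i
    i <- ss$nxt[i + 1L]
  }
  out[seq_len(k)]
}

#' Child pointer sequence from a parent-relative child description
#'
#' Walks the relative child sequence (parent index, or 0 for a character
#' inserted along the branch): surviving positions copy the parent's
#' reference; each maximal run of fresh characters creates new
#' super-sequence elements spliced immediately after the element
#' referenced by the last copied position (at the front for a leading
#' run). Total work is O(n') for the whole branch.
#'
#' @param ss Super-sequence handle (modified in place).
#' @param parent_pointers Parent node's pointer sequence.
#' @param rel Relative child description (see [blocks_to_relative()] and
#'   [relative_child_naive()]).
#' @return The child's pointer sequence.
#' @export
child_pointers_from_relative <- function(ss, parent_pointers, rel) {
  if (length(rel) == 0L) return(integer(0))
  out <- integer(length(rel))
  runs <- rle(rel > 0L)
  idx <- 1L
  last_id <- 0L
  for (r in seq_along(runs$lengths)) {
    take <- idx:(idx + runs$lengths[r] - 1L)
    if (runs$values[r]) {
      ids <- parent_pointers[rel[take]]
      out[take] <- ids
      last_id <- ids[length(ids)]
    } else {
      out[take] <- super_insert_run(ss, last_id, length(take))
      last_id <- out[take[length(take)]]
    }
    idx <- idx + runs$lengths[r]
  }
  out
}

#' Child pointer sequence from a branch block record
#'
#' Convenience wrapper: expands the block sequence produced by a block
#' engine to the relative form and delegates to
#' [child_pointers_from_relative()], so the MSA construction is identical
#' for every engine.
#'
#' @param ss Super-sequence handle (modified in place).
#' @param parent_pointers Parent node's pointer sequence.
#' @param blocks Branch block sequence.
#' @return The child's pointer sequence.
#' @export
child_pointer_sequence <- function(ss, parent_pointers, blocks) {
  child_pointers_from_relative(ss, parent_pointers, blocks_to_relative(blocks))
}

#' Column flags over a set of emitted rows
#'
#' An element produces an alignment column iff it is referenced by at
#' least one emitted pointer sequence; elements referenced only by rows
#' that are not emitted (e.g. ancestors when only leaves are written, or
#' insertions later deleted everywhere) yield no column.
#'
#' @param ss Super-sequence handle.
#' @param rows List of pointer sequences for the emitted rows.
#' @return Logical vector indexed by element id.
#' @export
mark_columns <- function(ss, rows) {
  flag <- logical(ss$n)
  for (p in rows) flag[p] <- TRUE
  flag
}

#' Assemble the alignment implied by the event history
#'
#' One column per flagged super-sequence element, in template order. Cell
#' values are the placeholder character where the row references the
#' element and the gap character otherwise; degapping any row recovers
#' exactly that node's simulated sequence.
#'
#' @param ss Super-sequence handle.
#' @param rows Named list of pointer sequences (the emitted rows).
#' @param placeholder Template character (default \code{"N"}).
#' @param gap Gap character (default \code{"-"}).
#' @return An object of class \code{"indel_alignment"}: a character matrix
#'   (rows = emitted nodes, columns = flagged elements) with the column
#'   element ids in attribute \code{"column_ids"}.
#' @export
assemble_alignment <- function(ss, rows, placeholder = "N", gap = "-") {
  flag <- mark_columns(ss, rows)
  ord <- super_order(ss)
  cols <- ord[flag[ord]]
  colpos <- integer(ss$n)
  colpos[cols] <- seq_along(cols)
  m <- matrix(gap, nrow = length(rows), ncol = length(cols),
              dimnames = list(names(rows), NULL))
  for (i in seq_along(rows)) m[i, colpos[rows[[i]]]] <- placeholder
  structure(m, column_ids = cols, gap = gap, class = "indel_alignment")
}

#' @export
print.indel_alignment <- function(x, ...) {
  cat(sprintf("True MSA: %d sequences, %d columns\n", nrow(x), ncol(x)))
  show <- apply(x[, seq_len(min(ncol(x), 60L)), drop = FALSE], 1L, paste,
                collapse = "")
  for (i in seq_along(show))
    cat(sprintf("  %-12s %s%s\n", rownames(x)[i], show[i],
                if (ncol(x) > 60L) "..." else ""))
  invisible(x)
}

#' Degap one alignment row
#'
#' @param aln An \code{indel_alignment}.
#' @param row Row name or index.
#' @return Character vector of the row's residues without gaps.
#' @export
degap_row <- function(aln, row) {
  v <- aln[row, ]
  v[v != attr(aln, "gap")]
}

#' Write a gapped FASTA alignment
#'
#' 60-column wrapping, \code{">"}-prefixed headers, rows in matrix order.
#'
#' @param aln An \code{indel_alignment} or character matrix with row names.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    s <- paste(aln[i, ], collapse = "")
    starts <- seq(1L, max(nchar(s), 1L), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Render an alignment as one string per row
#'
#' @param x An \code{indel_alignment}.
#' @param ... Unused.
#' @return Named character vector of row strings.
#' @export
as.character.indel_alignment <- function(x, ...) {
  stats::setNames(apply(unclass(x), 1L, paste, collapse = ""), rownames(x))
}
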