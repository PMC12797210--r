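# Shared fixtures and independent oracles, built in code at test time.

# the two-block list used throughout the worked examples
worked_blocks <- function() list(c(0L, 30L, 5L), c(30L, 25L, 0L))

default_params <- function() {
  indel_params(0.03, 0.09, length_distribution("zipf", 2.0, 50))
}

# Independent brute-force transcription of the branch Gillespie process:
# explicit length bookkeeping, inverse-transform waiting times. Used only
# to cross-check event counts; shares no code with simulate_branch_events.
oracle_branch_count <- function(n0, branch_length, r_ins, r_del, pmf) {
  n <- n0; t <- 0; k <- 0L
  repeat {
    S <- sample.int(length(pmf), 1L, prob = pmf)
    R_ins <- (n + 1) * r_ins
    R_del <- if (n >= 1) r_del * (n + S - 1) else 0
    lambda <- R_ins + R_del
    if (lambda <= 0) break
    t <- t - log(runif(1)) / lambda
    if (t > branch_length) break
    if (runif(1) < R_ins / lambda) {
      n <- n + sample.int(length(pmf), 1L, prob = pmf)
    } else {
      raw <- floor(runif(1) * (n + S - 1)) + (2L - S)
      n <- n - (min(raw + S - 1, n) - max(raw, 1L) + 1L)
    }
    k <- k + 1L
  }
  k
}

# Apply one event stream through all three engines and return the
# parent-relative child sequences (naive is the oracle).
engines_on_stream <- function(n0, events) {
  naive <- relative_child_naive(
    seq_len(n0), evolve_branch_naive(seq_len(n0), events)$seq)
  blocks <- evolve_branch_blocks(n0, events)
  avl <- flatten(evolve_branch_avl(n0, events))
  list(naive = naive,
       list = blocks_to_relative(blocks),
       avl = blocks_to_relative(avl),
       blocks = blocks)
}

# Hand-built event streams (coordinates valid for the evolving sequence)
stream <- function(...) {
  rows <- list(...)
  data.frame(kind = vapply(rows, `[[`, "", 1L),
             pos = as.integer(vapply(rows, `[[`, 0, 2L)),
             length = as.integer(vapply(rows, `[[`, 0, 3L)),
             eff_length = as.integer(vapply(rows, `[[`, 0, 3L)),
             time = seq_along(rows) * 0.01)
}

empty_stream <- function() stream()[0, ]

random_test_tree <- function(n_leaves, mean_bl = 0.05) {
  tr <- ape::rtree(n_leaves, rooted = TRUE)
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / mean_bl)
  tr
}
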