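#' Indel process parameters
#'
#' Bundles the per-site insertion rate, per-site deletion rate, and the
#' indel length distribution. Rates are in events per site per unit branch
#' length (branch lengths are measured in expected substitutions per site).
#'
#' @param insertion_rate Per-available-slot insertion rate (\eqn{r_{ins} \ge 0}).
#' @param deletion_rate Per-site deletion rate (\eqn{r_{del} \ge 0}).
#' @param length_dist A [length_distribution()] shared by insertions and
#'   deletions.
#' @return An object of class \code{"indel_params"}.
#' @examples
#' indel_params(0.03, 0.09, length_distribution("zipf", 2, 50))
#' @export
indel_params <- function(insertion_rate, deletion_rate, length_dist) {
  stopifnot(inherits(length_dist, "length_distribution"))
  if (!is.numeric(insertion_rate) || insertion_rate < 0 ||
      !is.numeric(deletion_rate) || deletion_rate < 0)
    stop("indel rates must be nonnegative numbers", call. = FALSE)
  structure(list(insertion_rate = as.numeric(insertion_rate),
                 deletion_rate = as.numeric(deletion_rate),
                 length_dist = length_dist),
            class = "indel_params")
}

#' @export
print.indel_params <- function(x, ...) {
  cat(sprintf("Indel model: r_ins = %g, r_del = %g per site per unit time\n",
              x$insertion_rate, x$deletion_rate))
  print(x$length_dist)
  invisible(x)
}

#' Sequence-wise event rates
#'
#' For a sequence of current length \code{n} there are \code{n + 1}
#' insertion slots, so \eqn{R_{ins} = (n+1) r_{ins}}. A deletion of
#' candidate length \eqn{S} may start at any of \eqn{n + S - 1} locations
#' (up to \eqn{S-1} positions left of the sequence), so
#' \eqn{R_{del} = r_{del}(n + S - 1)}; this left-overhang correction makes
#' every position equally likely to be deleted.
#'
#' @param n_cur Current sequence length (\code{>= 0}).
#' @param params An [indel_params()].
#' @param s_candidate Candidate deletion length drawn for this Gillespie
#'   step.
#' @return Named numeric vector \code{c(R_ins, R_del, lambda)}.
#' @export
sequence_rates <- function(n_cur, params, s_candidate) {
  stopifnot(inherits(params, "indel_params"))
  if (n_cur < 0 || s_candidate < 1)
    stop("n_cur must be >= 0 and s_candidate >= 1", call. = FALSE)
  r_ins <- (n_cur + 1) * params$insertion_rate
  r_del <- params$deletion_rate * (n_cur + s_candidate - 1)
  c(R_ins = r_ins, R_del = r_del, lambda = r_ins + r_del)
}

#' Exponential waiting times between events
#'
#' @param lambda Total event rate (\code{> 0}).
#' @param n Number of draws.
#' @return Numeric vector of waiting times with mean \code{1/lambda}.
#' @export
sample_waiting_time <- function(lambda, n = 1L) {
  if (!is.numeric(lambda) || lambda <= 0)
    stop("lambda must be > 0; a branch with zero total rate has no events",
         call. = FALSE)
  stats::rexp(n, rate = lambda)
}

#' Classify an event as insertion or deletion
#'
#' An event is an insertion with probability \eqn{R_{ins}/(R_{ins}+R_{del})}.
#'
#' @param R_ins,R_del Sequence-wise insertion and deletion rates.
#' @return Either \code{"insertion"} or \code{"deletion"}.
#' @export
classify_event <- function(R_ins, R_del) {
  if (R_ins < 0 || R_del < 0 || R_ins + R_del <= 0)
    stop("need R_ins + R_del > 0", call. = FALSE)
  if (stats::runif(1) < R_ins / (R_ins + R_del)) "insertion" else "deletion"
}

#' Draw insertion positions
#'
#' Insertion positions are uniform over the \code{n + 1} slots of a
#' sequence of length \code{n}: \code{q = 0} means before the first
#' character and \code{q = n} after the last.
#'
#' @param n_cur Current sequence length.
#' @param n Number of draws.
#' @return Integer vector with values in \code{0..n_cur}.
#' @export
sample_insertion_position <- function(n_cur, n = 1L) {
  if (n_cur < 0) stop("n_cur must be >= 0", call. = FALSE)
  sample.int(n_cur + 1L, size = n, replace = TRUE) - 1L
}

#' Draw an edge-corrected deletion event
#'
#' The raw start is uniform over the \code{n_cur + S - 1} integers
#' \code{(2 - S)..n_cur}, then the event is clipped to the sequence:
#' \code{start = max(raw, 1)}, \code{end = min(raw + S - 1, n_cur)}.
#' With this correction every position is deleted with probability
#' exactly \code{S / (n_cur + S - 1)}.
#'
#' @param n_cur Current sequence length (\code{>= 1}).
#' @param S Drawn deletion length (\code{>= 1}).
#' @param n Number of draws.
#' @return A data.frame with integer columns \code{start} and
#'   \code{length} (the clipped, effective length, always \code{>= 1}).
#' @export
sample_deletion_event <- function(n_cur, S, n = 1L) {
  if (n_cur < 1)
    stop("cannot place a deletion on an empty sequence", call. = FALSE)
  if (S < 1) stop("deletion length must be >= 1", call. = FALSE)
  raw <- sample.int(n_cur + S - 1L, size = n, replace = TRUE) + (1L - as.integer(S))
  start <- pmax(raw, 1L)
  end <- pmin(raw + as.integer(S) - 1L, as.integer(n_cur))
  data.frame(start = start, length = end - start + 1L)
}

#' Simulate the indel event stream along one branch
#'
#' Runs the Gillespie process: at each step a candidate deletion length is
#' drawn, the sequence-wise rates and the exponential waiting time are
#' computed from it, and the event is classified and placed. An event whose
#' cumulative time exceeds the branch length is discarded and the branch
#' ends. The emitted stream is engine-agnostic: every bookkeeping engine
#' consumes it identically.
#'
#' Event coordinates refer to the sequence as it exists at the moment of the
#' event: insertions carry the slot \code{q} in \code{0..n} (insert after
#' character \code{q}), deletions carry the clipped start position and
#' effective length (always fully in range).
#'
#' @param n0 Parent sequence length at the top of the branch.
#' @param branch_length Branch length in expected substitutions per site.
#' @param params An [indel_params()].
#' @return A list with \code{events} (data.frame with columns \code{kind},
#'   \code{pos}, \code{length} (drawn), \code{eff_length} (applied),
#'   \code{time}) and \code{final_length}.
#' @export
simulate_branch_events <- function(n0, branch_length, params) {
  stopifnot(inherits(params, "indel_params"))
  if (n0 < 0 || branch_length < 0)
    stop("n0 and branch_length must be nonnegative", call. = FALSE)
  n <- as.integer(n0)
  t <- 0
  kind <- character(0); pos <- integer(0); len <- integer(0)
  eff <- integer(0); tim <- numeric(0)
  dist <- params$length_dist
  repeat {
    s_cand <- sample_indel_length(dist)
    r_ins <- (n + 1) * params$insertion_rate
    # an empty sequence admits no deletions, whatever the formula says
    r_del <- if (n >= 1L) params$deletion_rate * (n + s_cand - 1) else 0
    lambda <- r_ins + r_del
    if (lambda <= 0) break
    t <- t + stats::rexp(1, rate = lambda)
    if (t > branch_length) break
    if (stats::runif(1) < r_ins / lambda) {
      S <- sample_indel_length(dist)
      q <- sample_insertion_position(n)
      kind <- c(kind, "insertion"); pos <- c(pos, q)
      len <- c(len, S); eff <- c(eff, S); tim <- c(tim, t)
      n <- n + S
    } else {
      ev <- sample_deletion_event(n, s_cand)
      kind <- c(kind, "deletion"); pos <- c(pos, ev$start)
      len <- c(len, as.integer(s_cand)); eff <- c(eff, ev$length)
      tim <- c(tim, t)
      n <- n - ev$length
    }
  }
  list(
    events = data.frame(kind = kind, pos = pos, length = len,
                        eff_length = eff, time = tim),
    final_length = n
  )
}
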