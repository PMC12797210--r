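#' Continuous-time substitution models
#'
#' A reversible substitution model is built from symmetric
#' exchangeabilities \eqn{s_{ij}} and stationary frequencies \eqn{\pi}:
#' \eqn{Q_{ij} = s_{ij}\pi_j} for \eqn{i \ne j}, diagonal set so rows sum
#' to zero, and the whole matrix scaled so the expected substitution rate
#' at stationarity is one (\eqn{-\sum_i \pi_i Q_{ii} = 1}), which makes
#' branch lengths expected substitutions per site. Transition matrices
#' are computed by spectral decomposition of the symmetrized generator.
#'
#' @param exchangeabilities Symmetric nonnegative matrix (diagonal
#'   ignored).
#' @param freqs Stationary distribution (positive, sums to 1).
#' @param alphabet Character vector of state labels.
#' @return An object of class \code{"substitution_model"} with elements
#'   \code{Q}, \code{pi}, \code{alphabet} and cached eigendecomposition.
#' @export
normalize_rate_matrix <- function(exchangeabilities, freqs, alphabet = NULL) {
  s <- as.matrix(exchangeabilities)
  k <- nrow(s)
  if (ncol(s) != k) stop("exchangeabilities must be square", call. = FALSE)
  if (max(abs(s - t(s))) > 1e-8)
    stop("exchangeabilities must be symmetric", call. = FALSE)
  if (any(s[upper.tri(s)] < 0))
    stop("exchangeabilities must be nonnegative", call. = FALSE)
  if (length(freqs) != k || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-6)
    stop("freqs must be a positive probability vector over the alphabet",
         call. = FALSE)
  freqs <- freqs / sum(freqs)
  if (is.null(alphabet)) alphabet <- rownames(s)
  if (is.null(alphabet)) alphabet <- as.character(seq_len(k))
  Q <- s * rep(freqs, each = k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  if (mu <= 0) stop("degenerate model: zero total rate", call. = FALSE)
  Q <- Q / mu
  # symmetrize: B = D^{1/2} Q D^{-1/2} has real spectrum
  d <- sqrt(freqs)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  structure(list(Q = Q, pi = freqs, alphabet = alphabet,
                 values = e$values,
                 U = e$vectors / d,        # D^{-1/2} V
                 Uinv = t(e$vectors) * rep(d, each = k)),  # V' D^{1/2}
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("Reversible substitution model over {%s} (%d states)\n",
              paste(x$alphabet, collapse = ""), length(x$alphabet)))
  cat(sprintf("  expected rate at stationarity: %.6f\n",
              -sum(x$pi * diag(x$Q))))
  invisible(x)
}

#' JTT amino-acid model
#'
#' The Jones-Taylor-Thornton empirical amino-acid replacement model
#' (exchangeabilities and frequencies as shipped with phangorn), in
#' one-letter amino-acid alphabet order ARNDCQEGHILKMFPSTWYV.
#'
#' @return A \code{substitution_model}.
#' @export
jtt_model <- function() {
  jtt <- utils::getFromNamespace(".JTT", "phangorn")
  k <- 20L
  s <- matrix(0, k, k)
  s[lower.tri(s)] <- jtt$Q
  s <- s + t(s)
  alphabet <- toupper(names(jtt$bf))
  dimnames(s) <- list(alphabet, alphabet)
  normalize_rate_matrix(s, as.numeric(jtt$bf), alphabet)
}

#' One-parameter nucleotide model
#'
#' Jukes-Cantor: equal exchangeabilities and uniform base frequencies.
#'
#' @return A \code{substitution_model}.
#' @export
nucleotide_model <- function() {
  s <- matrix(1, 4, 4)
  diag(s) <- 0
  normalize_rate_matrix(s, rep(0.25, 4), c("A", "C", "G", "T"))
}

#' Read a custom model in PAML rate-file layout
#'
#' Lower-triangle exchangeability rows (one fewer values per line than
#' states, starting with a single value) followed by one line of
#' stationary frequencies.
#'
#' @param path Path to the rate file.
#' @param alphabet State labels; default is the 20 amino acids in
#'   ARNDCQEGHILKMFPSTWYV order.
#' @return A \code{substitution_model}.
#' @export
read_paml_matrix <- function(path, alphabet = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]) {
  vals <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  k <- length(alphabet)
  need <- k * (k - 1) / 2 + k
  if (length(vals) < need)
    stop("rate file holds ", length(vals), " numbers; need ", need,
         call. = FALSE)
  s <- matrix(0, k, k)
  # PAML order: row-wise lower triangle (row 2 first)
  idx <- 1L
  for (i in 2:k) for (j in 1:(i - 1)) {
    s[i, j] <- vals[idx]; idx <- idx + 1L
  }
  s <- s + t(s)
  freqs <- vals[idx:(idx + k - 1L)]
  dimnames(s) <- list(alphabet, alphabet)
  normalize_rate_matrix(s, freqs, alphabet)
}

#' Branch transition probabilities
#'
#' \eqn{P(t) = \exp(Qt)} via the cached spectral decomposition.
#'
#' @param model A \code{substitution_model}.
#' @param t Branch length (\code{>= 0}).
#' @return Row-stochastic matrix.
#' @export
transition_probabilities <- function(model, t) {
  stopifnot(inherits(model, "substitution_model"))
  if (t < 0) stop("branch length must be >= 0", call. = FALSE)
  P <- model$U %*% (exp(model$values * t) * model$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Draw a root sequence from the stationary distribution
#'
#' @param model A \code{substitution_model}.
#' @param L Sequence length.
#' @return Character vector of \code{L} residues.
#' @export
draw_root_sequence <- function(model, L) {
  if (L == 0L) return(character(0))
  model$alphabet[sample.int(length(model$pi), L, replace = TRUE,
                            prob = model$pi)]
}

#' Simulate substitutions over fixed-length sequences along a tree
#'
#' Residue content is simulated at the alignment length \code{L}
#' determined by the indel template: the root is drawn from the
#' stationary distribution and each child site from the parent's row of
#' the branch transition matrix; no length changes occur.
#'
#' @param tree A rooted \code{phylo} tree with branch lengths.
#' @param L Alignment length.
#' @param model A \code{substitution_model}.
#' @return Character matrix, one row per tree node (row order = node id),
#'   \code{L} columns.
#' @export
evolve_substitutions <- function(tree, L, model) {
  topo <- tree_topology(tree)
  k <- length(model$alphabet)
  res <- matrix(NA_character_, nrow = topo$n_nodes, ncol = L)
  rownames(res) <- topo$labels
  res[topo$root, ] <- draw_root_sequence(model, L)
  if (L == 0L) return(res)
  code <- stats::setNames(seq_len(k), model$alphabet)
  for (e in seq_len(nrow(topo$edges))) {
    par <- topo$edges[e, 1L]; child <- topo$edges[e, 2L]
    P <- transition_probabilities(model, topo$lengths[e])
    pstates <- code[res[par, ]]
    out <- integer(L)
    for (s in unique(pstates)) {
      w <- which(pstates == s)
      out[w] <- sample.int(k, length(w), replace = TRUE, prob = P[s, ])
    }
    res[child, ] <- model$alphabet[out]
  }
  res
}

#' Superimpose residue content on an indel template
#'
#' Gaps stay gaps; every placeholder cell is replaced by that row's
#' residue at that column. Indels and substitutions are independent, so
#' the combination order does not matter.
#'
#' @param template An \code{indel_alignment} (template mode).
#' @param residues Character matrix from [evolve_substitutions()] with
#'   \code{ncol(template)} columns; rows are matched to the template by
#'   row name.
#' @return The final \code{indel_alignment} with residue content.
#' @export
superimpose <- function(template, residues) {
  if (ncol(residues) != ncol(template))
    stop("residue matrix has ", ncol(residues), " columns; template has ",
         ncol(template), call. = FALSE)
  out <- unclass(template)
  gap <- attr(template, "gap")
  for (i in seq_len(nrow(out))) {
    r <- residues[rownames(out)[i], ]
    keep <- out[i, ] != gap
    out[i, keep] <- r[keep]
  }
  structure(out, column_ids = attr(template, "column_ids"), gap = gap,
            class = "indel_alignment")
}
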