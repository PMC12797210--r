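#' Simulation configuration
#'
#' Validates and bundles all options of an end-to-end simulation run.
#'
#' @param root_length Root sequence length (\code{>= 0}).
#' @param insertion_rate,deletion_rate Per-site indel rates; defaults are
#'   the benchmark regime 0.03 / 0.09.
#' @param length_dist Indel [length_distribution()]; default truncated
#'   Zipf, exponent 2.0, truncation 50.
#' @param engine Indel bookkeeping engine: \code{"block_list"},
#'   \code{"block_tree"}, or \code{"naive"}. All three produce identical
#'   output for the same seed.
#' @param model Substitution model: \code{"none"} (template alignment of
#'   'N' and gaps), \code{"jtt"}, \code{"nucleotide"}, or a
#'   \code{substitution_model} object.
#' @param seed Master seed; every random stream derives from it.
#' @param ancestors If \code{TRUE}, emit ancestral rows in the alignment
#'   (column flags are then computed over leaves and ancestors).
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(root_length,
                       insertion_rate = 0.03,
                       deletion_rate = 0.09,
                       length_dist = length_distribution("zipf", 2.0, 50),
                       engine = c("block_list", "block_tree", "naive"),
                       model = "none",
                       seed = 1L,
                       ancestors = FALSE) {
  engine <- match.arg(engine)
  if (!is.numeric(root_length) || root_length < 0)
    stop("root_length must be >= 0", call. = FALSE)
  params <- indel_params(insertion_rate, deletion_rate, length_dist)
  if (is.character(model)) {
    model <- match.arg(model, c("none", "jtt", "nucleotide"))
  } else if (!inherits(model, "substitution_model")) {
    stop("model must be \"none\", \"jtt\", \"nucleotide\", or a substitution_model",
         call. = FALSE)
  }
  structure(list(root_length = as.integer(root_length), params = params,
                 engine = engine, model = model, seed = as.integer(seed),
                 ancestors = isTRUE(ancestors)),
            class = "sim_config")
}

resolve_model <- function(model) {
  if (inherits(model, "substitution_model")) return(model)
  switch(model,
         none = NULL,
         jtt = jtt_model(),
         nucleotide = nucleotide_model())
}

#' Simulate sequences and their true alignment along a tree
#'
#' Runs the full pipeline: per-branch Gillespie indel streams (preorder,
#' one deterministic substream per branch), the chosen bookkeeping
#' engine, super-sequence/pointer-sequence assembly of the true MSA, and
#' (unless \code{model = "none"}) an independent substitution simulation
#' superimposed on the indel template. Identical seeds with different
#' engines give byte-identical output.
#'
#' @param tree A rooted \code{phylo} tree with branch lengths, or a
#'   newick string/path accepted by [read_newick()].
#' @param config A [sim_config()].
#' @param out_dir Optional output directory; when given, writes
#'   \code{msa.fasta} (true alignment), \code{leaves.fasta} (degapped
#'   leaf sequences), \code{events.tsv} (replayable event log) and
#'   \code{manifest.yaml}.
#' @return An object of class \code{"indel_simulation"}: list with
#'   \code{alignment} (final \code{indel_alignment}), \code{template}
#'   (indel-only alignment), \code{lengths} (per-node sequence lengths),
#'   \code{pointers} (per-node pointer sequences into the super-sequence),
#'   \code{events} (event log data.frame), \code{tree}, \code{config},
#'   and \code{manifest}.
#' @examples
#' tr <- read_newick("((A:0.05,B:0.05):0.02,C:0.08);")
#' sim <- simulate_alignment(tr, sim_config(root_length = 40, seed = 7))
#' sim$alignment
#' @export
simulate_alignment <- function(tree, config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(tree, "phylo")) tree <- read_newick(tree)
  topo <- tree_topology(tree)
  n0 <- config$root_length
  params <- config$params

  init <- init_super_sequence(n0)
  ss <- init$super
  ptr <- vector("list", topo$n_nodes)
  ptr[[topo$root]] <- init$root_pointers
  lens <- integer(topo$n_nodes)
  lens[topo$root] <- n0
  logs <- vector("list", nrow(topo$edges))
  naive_counter <- 0L

  for (e in seq_len(nrow(topo$edges))) {
    par <- topo$edges[e, 1L]; child <- topo$edges[e, 2L]
    set.seed(derive_seed(config$seed, child, 1L))
    sim <- simulate_branch_events(lens[par], topo$lengths[e], params)
    rel <- switch(config$engine,
      naive = {
        out <- evolve_branch_naive(seq_len(lens[par]), sim$events,
                                   naive_counter)
        naive_counter <- out$token_counter
        relative_child_naive(seq_len(lens[par]), out$seq)
      },
      block_list = blocks_to_relative(
        evolve_branch_blocks(lens[par], sim$events)),
      block_tree = blocks_to_relative(
        flatten(evolve_branch_avl(lens[par], sim$events)))
    )
    stopifnot(length(rel) == sim$final_length)
    ptr[[child]] <- child_pointers_from_relative(ss, ptr[[par]], rel)
    lens[child] <- sim$final_length
    ev <- sim$events
    if (nrow(ev) > 0) {
      ev$branch <- topo$labels[child]
      logs[[e]] <- ev
    }
  }

  emit <- if (config$ancestors) seq_len(topo$n_nodes) else topo$tips
  rows <- stats::setNames(ptr[emit], topo$labels[emit])
  template <- assemble_alignment(ss, rows)

  model <- resolve_model(config$model)
  alignment <- template
  if (!is.null(model)) {
    set.seed(derive_seed(config$seed, 0L, 2L))
    residues <- evolve_substitutions(tree, ncol(template), model)
    alignment <- superimpose(template, residues)
  }

  events <- if (any(!vapply(logs, is.null, logical(1)))) {
    do.call(rbind, logs[!vapply(logs, is.null, logical(1))])
  } else {
    data.frame(kind = character(0), pos = integer(0), length = integer(0),
               eff_length = integer(0), time = numeric(0),
               branch = character(0))
  }

  manifest <- list(
    package = "indelsim",
    version = as.character(utils::packageVersion("indelsim")),
    seed = config$seed,
    engine = config$engine,
    model = if (inherits(config$model, "substitution_model"))
      "custom" else config$model,
    root_length = n0,
    insertion_rate = params$insertion_rate,
    deletion_rate = params$deletion_rate,
    length_distribution = list(
      family = params$length_dist$family,
      parameter = params$length_dist$parameter,
      truncation = params$length_dist$truncation,
      truncation_inclusive = params$length_dist$truncation_inclusive),
    ancestors = config$ancestors,
    alignment_length = ncol(template),
    n_events = nrow(events),
    config_hash = config_hash(config)
  )

  res <- structure(list(alignment = alignment, template = template,
                        lengths = stats::setNames(lens, topo$labels),
                        pointers = stats::setNames(ptr, topo$labels),
                        events = events, tree = tree, config = config,
                        manifest = manifest),
                   class = "indel_simulation")
  if (!is.null(out_dir)) write_simulation(res, out_dir)
  res
}

#' @export
print.indel_simulation <- function(x, ...) {
  cat(sprintf("Indel simulation (%s engine, seed %d): %d events, alignment %d x %d\n",
              x$config$engine, x$config$seed, nrow(x$events),
              nrow(x$alignment), ncol(x$alignment)))
  print(x$alignment)
  invisible(x)
}

#' Write simulation outputs to a directory
#'
#' @param sim An \code{indel_simulation}.
#' @param out_dir Directory (created if missing).
#' @return \code{out_dir}, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_alignment(sim$alignment, file.path(out_dir, "msa.fasta"))
  gap <- attr(sim$alignment, "gap")
  con <- file(file.path(out_dir, "leaves.fasta"), "w")
  tips <- sim$tree$tip.label
  for (nm in tips) {
    writeLines(paste0(">", nm), con)
    s <- paste(degap_row(sim$alignment, nm), collapse = "")
    if (nchar(s) > 0) {
      starts <- seq(1L, nchar(s), by = 60L)
      writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
    }
  }
  close(con)
  utils::write.table(sim$events, file.path(out_dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(sim$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

# small rolling hash over the serialized config, for the manifest
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
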