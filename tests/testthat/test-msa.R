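test_that("super-sequence initialization seeds the root pointers", {
  init <- init_super_sequence(5)
  expect_identical(init$root_pointers, 1:5)
  expect_identical(super_order(init$super), 1:5)
  empty <- init_super_sequence(0)
  expect_identical(empty$root_pointers, integer(0))
  expect_identical(super_order(empty$super), integer(0))
})

test_that("a three-species history threads insertions into the template", {
  # root (5 chars) -> internal node via two insertions creating elements
  # 6-7 and 8-10; two leaves descend from the internal node, the third
  # from the root
  init <- init_super_sequence(5)
  ss <- init$super
  root <- init$root_pointers
  # branch root -> internal: insert 2 after position 2, then 3 after
  # position 6 (coordinates of the evolving sequence)
  ev <- stream(list("insertion", 2, 2), list("insertion", 6, 3))
  rel <- blocks_to_relative(evolve_branch_blocks(5, ev))
  node2 <- child_pointers_from_relative(ss, root, rel)
  expect_identical(ss$n, 10L)                   # ids 6..10 created
  expect_length(node2, 10)
  expect_true(all(6:10 %in% node2))
  expect_identical(node2[node2 <= 5], c(1L, 2L, 3L, 4L, 5L))
  # leaf A: deletion of two characters; leaf B: event-free
  evA <- stream(list("deletion", 4, 2))
  relA <- blocks_to_relative(evolve_branch_blocks(10, evA))
  leafA <- child_pointers_from_relative(ss, node2, relA)
  leafB <- child_pointers_from_relative(ss, node2, seq_len(10))
  expect_identical(leafB, node2)                # event-free branch copies
  # leaf C straight from the root
  leafC <- child_pointers_from_relative(ss, root, seq_len(5))
  aln <- assemble_alignment(ss, list(A = leafA, B = leafB, C = leafC))
  expect_identical(ncol(aln), 10L)              # no column lost: B has all
  expect_identical(length(degap_row(aln, "A")), 8L)
  expect_identical(length(degap_row(aln, "C")), 5L)
  # rows share a column exactly where they reference the same element
  expect_identical(sum(aln["A", ] != "-" & aln["C", ] != "-"),
                   length(intersect(leafA, leafC)))
})

test_that("columns deleted from every emitted row are dropped", {
  init <- init_super_sequence(3)
  ss <- init$super
  root <- init$root_pointers
  # internal branch inserts 2 fresh characters after position 1
  ev <- stream(list("insertion", 1, 2))
  internal <- child_pointers_from_relative(
    ss, root, blocks_to_relative(evolve_branch_blocks(3, ev)))
  expect_length(internal, 5)
  # both leaves delete exactly those two characters
  del <- stream(list("deletion", 2, 2))
  relL <- blocks_to_relative(evolve_branch_blocks(5, del))
  leaf1 <- child_pointers_from_relative(ss, internal, relL)
  leaf2 <- child_pointers_from_relative(ss, internal, relL)
  flags <- mark_columns(ss, list(leaf1, leaf2))
  expect_identical(which(flags), c(1L, 2L, 3L))  # fresh 4,5 unflagged
  aln <- assemble_alignment(ss, list(L1 = leaf1, L2 = leaf2))
  expect_identical(ncol(aln), 3L)
  expect_true(all(unclass(aln) != "-"))          # no gap-only columns
  # with the internal row emitted, its insertion is a real column
  aln2 <- assemble_alignment(ss, list(N = internal, L1 = leaf1, L2 = leaf2))
  expect_identical(ncol(aln2), 5L)
  expect_identical(sum(aln2["L1", ] == "-"), 2L)
})

test_that("degapping any emitted row recovers its simulated sequence", {
  p <- indel_params(0.05, 0.08, length_distribution("zipf", 1.8, 30))
  for (i in 1:20) {
    set.seed(1500 + i)
    tr <- random_test_tree(sample(3:8, 1))
    n0 <- sample(20:80, 1)
    cfg <- sim_config(n0, insertion_rate = 0.05, deletion_rate = 0.08,
                      length_dist = p$length_dist, seed = 1500 + i,
                      ancestors = TRUE)
    sim <- simulate_alignment(tr, cfg)
    naive <- evolve_tree_naive(tr, n0, p, seed = 1500 + i)
    labels <- rownames(sim$alignment)
    for (nm in labels) {
      expect_identical(length(degap_row(sim$alignment, nm)),
                       unname(sim$lengths[nm]))
    }
    # leaf rows match the naive engine's per-node sequence lengths
    for (leaf in seq_along(tr$tip.label)) {
      expect_identical(unname(sim$lengths[tr$tip.label[leaf]]),
                       length(naive$sequences[[leaf]]))
    }
    m <- unclass(sim$alignment)
    expect_true(all(colSums(m != "-") > 0))
    expect_gte(ncol(m), max(sim$lengths))
  }
})

test_that("homology columns mirror naive token identity", {
  p <- default_params()
  for (i in 1:10) {
    set.seed(1700 + i)
    tr <- random_test_tree(sample(3:6, 1))
    n0 <- sample(20:60, 1)
    sim <- simulate_alignment(tr, sim_config(n0, seed = 1700 + i))
    naive <- evolve_tree_naive(tr, n0, p, seed = 1700 + i)
    # two leaves share a column for a root-derived element exactly when
    # the same ancestral label survives in both naive sequences
    tips <- seq_along(tr$tip.label)
    for (a in tips) for (b in tips) if (a < b) {
      pa <- sim$pointers[[tr$tip.label[a]]]
      pb <- sim$pointers[[tr$tip.label[b]]]
      shared_root <- intersect(pa[pa <= n0], pb[pb <= n0])
      sa <- naive$sequences[[a]]; sb <- naive$sequences[[b]]
      expect_identical(sort(shared_root),
                       sort(intersect(sa[sa > 0], sb[sb > 0])))
    }
  }
})

test_that("alignment writing is stable 60-column FASTA", {
  init <- init_super_sequence(4)
  aln <- assemble_alignment(init$super,
                            list(X = init$root_pointers,
                                 Y = init$root_pointers[c(1, 3, 4)]))
  path <- tempfile(fileext = ".fasta")
  on.exit(unlink(path))
  write_fasta_alignment(aln, path)
  lines <- readLines(path)
  expect_identical(lines, c(">X", "NNNN", ">Y", "N-NN"))
})
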