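test_that("the single-block start state describes the parent sequence", {
  expect_identical(initial_block_sequence(100), list(c(0L, 101L, 0L)))
  expect_identical(initial_block_sequence(0), list(c(0L, 1L, 0L)))
  expect_identical(current_length(initial_block_sequence(100)), 100L)
  expect_identical(current_length(list(c(0L, 30L, 5L), c(30L, 50L, 0L),
                                       c(85L, 16L, 0L))), 100L)
})

test_that("locate scans cumulative block totals", {
  f <- worked_blocks()
  expect_identical(locate_block(f, 45), list(index = 2L, offset = 10L))
  expect_identical(locate_block(f, 15), list(index = 1L, offset = 15L))
  expect_identical(locate_block(list(c(0L, 10L, 0L)), 0),
                   list(index = 1L, offset = 0L))
  expect_error(locate_block(f, 61), "beyond")
})

test_that("insertions split OPs and grow APs as in the worked examples", {
  f <- worked_blocks()
  expect_identical(apply_insertion_blocks(f, 15, 4),
                   list(c(0L, 16L, 4L), c(16L, 14L, 5L), c(30L, 25L, 0L)))
  expect_identical(apply_insertion_blocks(f, 32, 4),
                   list(c(0L, 30L, 9L), c(30L, 25L, 0L)))
  expect_identical(apply_insertion_blocks(f, 45, 4),
                   list(c(0L, 30L, 5L), c(30L, 10L, 4L), c(40L, 15L, 0L)))
  # insertion of 5 after position 29 on the post-deletion two-block state
  expect_identical(apply_insertion_blocks(list(c(0L, 80L, 0L),
                                               c(85L, 16L, 0L)), 29, 5),
                   list(c(0L, 30L, 5L), c(30L, 50L, 0L), c(85L, 16L, 0L)))
  # insertion before the first character lives in the anchor block
  expect_identical(apply_insertion_blocks(list(c(0L, 11L, 0L)), 0, 2),
                   list(c(0L, 1L, 2L), c(1L, 10L, 0L)))
})

test_that("deletions split, shrink and merge blocks as in the worked examples", {
  expect_identical(apply_deletion_blocks(initial_block_sequence(100), 80, 5),
                   list(c(0L, 80L, 0L), c(85L, 16L, 0L)))
  expect_identical(apply_deletion_blocks(worked_blocks(), 10, 4),
                   list(c(0L, 10L, 0L), c(14L, 16L, 5L), c(30L, 25L, 0L)))
  # deletion wholly inside an AP shrinks it
  expect_identical(apply_deletion_blocks(worked_blocks(), 31, 3),
                   list(c(0L, 30L, 2L), c(30L, 25L, 0L)))
  # spanning deletion: OP tail + AP + next block's OP head
  expect_identical(apply_deletion_blocks(worked_blocks(), 28, 9),
                   list(c(0L, 28L, 0L), c(32L, 23L, 0L)))
  # a fully deleted OP leaves its AP on the nearest preceding block
  expect_identical(apply_deletion_blocks(list(c(0L, 3L, 1L), c(10L, 2L, 4L),
                                              c(20L, 5L, 0L)), 4, 2),
                   list(c(0L, 3L, 5L), c(20L, 5L, 0L)))
  expect_error(apply_deletion_blocks(worked_blocks(), 0, 2), "position >= 1")
  expect_error(apply_deletion_blocks(worked_blocks(), 59, 5), "beyond")
})

test_that("hand-built streams match the naive engine exactly", {
  cases <- list(
    list(10, stream(list("insertion", 3, 2), list("deletion", 4, 3))),
    list(10, stream(list("insertion", 0, 4), list("deletion", 1, 6))),
    list(5, stream(list("insertion", 2, 3), list("deletion", 1, 8))),
    list(8, stream(list("insertion", 8, 2), list("insertion", 10, 1),
                   list("deletion", 7, 4))),
    list(12, stream(list("deletion", 1, 5), list("insertion", 7, 3),
                    list("deletion", 2, 8))),
    list(6, stream(list("insertion", 3, 2), list("insertion", 5, 2),
                   list("deletion", 4, 5)))
  )
  for (cs in cases) {
    r <- engines_on_stream(cs[[1]], cs[[2]])
    expect_identical(r$list, r$naive)
    expect_identical(r$avl, r$naive)
  }
})

test_that("random streams match the naive engine and obey the block bound", {
  p <- indel_params(0.06, 0.1, length_distribution("zipf", 1.5, 25))
  for (i in 1:200) {
    set.seed(700 + i)
    n0 <- sample(10:200, 1)
    sim <- simulate_branch_events(n0, runif(1, 0.02, 0.8), p)
    r <- engines_on_stream(n0, sim$events)
    expect_identical(r$list, r$naive)
    expect_identical(current_length(r$blocks), length(r$naive))
    # b <= min(k + 1, n + 1) after every event
    st <- attr(evolve_branch_blocks(n0, sim$events, instrument = TRUE),
               "stats")
    if (nrow(st))
      expect_true(all(st$b <= pmin(seq_len(nrow(st)) + 1L, n0 + 1L)))
  }
})

test_that("block invariants hold along random histories", {
  p <- indel_params(0.08, 0.08, length_distribution("geometric", 0.35, 12))
  for (i in 1:60) {
    set.seed(900 + i)
    n0 <- sample(5:80, 1)
    sim <- simulate_branch_events(n0, runif(1, 0.1, 1.2), p)
    blocks <- evolve_branch_blocks(n0, sim$events)
    m <- blocks_df(blocks)
    expect_identical(m$start[1], 0L)         # anchor block first
    expect_true(all(m$length >= 1L))         # OP size positive
    expect_true(all(m$insertion >= 0L))
    if (nrow(m) > 1)                         # OPs disjoint and increasing
      expect_true(all(m$start[-1] >= (m$start + m$length)[-nrow(m)]))
    # surviving ancestral positions equal the naive engine's
    naive <- relative_child_naive(
      seq_len(n0), evolve_branch_naive(seq_len(n0), sim$events)$seq)
    expect_identical(blocks_to_relative(blocks), naive)
  }
})

test_that("per-event scan work is bounded by the block count", {
  p <- indel_params(0.06, 0.1, length_distribution("zipf", 1.6, 20))
  set.seed(77)
  sim <- simulate_branch_events(150, 1.0, p)
  blocks <- evolve_branch_blocks(150, sim$events, instrument = TRUE)
  st <- attr(blocks, "stats")
  if (nrow(st) > 1)
    expect_true(all(st$visits[-1] <= st$b[-nrow(st)] + 1L))
})
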