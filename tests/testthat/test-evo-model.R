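test_that("sequence-wise rates follow the slot counts", {
  p <- default_params()
  r <- sequence_rates(100, p, 1)
  expect_equal(unname(r["R_ins"]), 101 * 0.03)  # (n+1) r_ins = 3.03
  expect_equal(unname(r["R_del"]), 0.09 * 100)  # S = 1: r_del * n
  r5 <- sequence_rates(100, p, 5)
  expect_equal(unname(r5["R_del"]), 0.09 * 104)
  expect_equal(unname(r5["lambda"]), unname(r5["R_ins"] + r5["R_del"]))
  expect_error(sequence_rates(-1, p, 1), "n_cur")
})

test_that("waiting times are exponential with rate lambda", {
  set.seed(11)
  x <- sample_waiting_time(2, 1e5)
  expect_lt(abs(mean(x) - 0.5), 3 * 0.5 / sqrt(1e5))
  set.seed(3); a <- sample_waiting_time(1.7)
  set.seed(3); b <- sample_waiting_time(1.7)
  expect_identical(a, b)
  # inverse-transform scaling: rexp shares the uniform stream
  set.seed(9); x1 <- sample_waiting_time(1, 100)
  set.seed(9); x2 <- sample_waiting_time(4, 100)
  expect_equal(x1, 4 * x2)
  expect_error(sample_waiting_time(0), "lambda")
})

test_that("event classification splits by relative rate", {
  set.seed(21)
  expect_identical(classify_event(0, 1), "deletion")
  expect_identical(classify_event(1, 0), "insertion")
  n <- 1e5
  draws <- vapply(seq_len(n), function(i) classify_event(2, 2), "")
  frac <- mean(draws == "insertion")
  expect_lt(abs(frac - 0.5), 3 * 0.5 / sqrt(n))
  expect_error(classify_event(0, 0), "R_ins")
})

test_that("insertion positions are uniform over the n + 1 slots", {
  expect_identical(sample_insertion_position(0, 5), rep(0L, 5))
  set.seed(13)
  q <- sample_insertion_position(100, 1e5)
  expect_true(all(q >= 0 & q <= 100))
  p <- 1 / 101
  freq <- tabulate(q + 1L, 101) / 1e5
  expect_true(all(abs(freq - p) < 4 * sqrt(p * (1 - p) / 1e5)))
})

test_that("deletion placement is edge-corrected and clipped", {
  # S = 1: every position deleted with probability exactly 1/n
  set.seed(17)
  ev <- sample_deletion_event(50, 1, n = 2e5)
  expect_true(all(ev$length == 1L))
  freq <- tabulate(ev$start, 50) / 2e5
  expect_true(all(abs(freq - 1 / 50) < 4 * sqrt((1 / 50) / 2e5)))
  # maximal left overhang clips to the first position only
  ev5 <- sample_deletion_event(100, 5, n = 2e4)
  expect_true(all(ev5$start >= 1 & ev5$start + ev5$length - 1 <= 100))
  expect_true(all(ev5$length >= 1))
  left_clipped <- ev5[ev5$start == 1 & ev5$length == 1, ]
  expect_gt(nrow(left_clipped), 0)  # raw start 2 - S occurs
  expect_error(sample_deletion_event(0, 3), "empty")
})

test_that("per-position deletion probability equals S/(n+S-1)", {
  set.seed(19)
  n_cur <- 40L; S <- 4L; trials <- 2e5
  ev <- sample_deletion_event(n_cur, S, n = trials)
  hits <- tabulate(ev$start, n_cur + 1L)
  ends <- tabulate(pmin(ev$start + ev$length, n_cur + 1L), n_cur + 1L)
  cover <- cumsum(hits - ends)[seq_len(n_cur)]  # coverage per position
  p <- S / (n_cur + S - 1)
  expect_true(all(abs(cover / trials - p) < 3.5 * sqrt(p * (1 - p) / trials)))
})

test_that("branch streams respect trivial boundary conditions", {
  p <- default_params()
  set.seed(1)
  s0 <- simulate_branch_events(500, 0, p)
  expect_identical(nrow(s0$events), 0L)
  expect_identical(s0$final_length, 500L)
  quiet <- indel_params(0, 0.0, length_distribution("zipf", 2, 50))
  expect_error(indel_params(-1, 0, length_distribution("zipf", 2, 50)),
               "nonnegative")
  s1 <- simulate_branch_events(100, 5, quiet)
  expect_identical(nrow(s1$events), 0L)
})

test_that("monotonicity: one-sided processes only shrink or grow", {
  dist <- length_distribution("zipf", 2, 50)
  ins_only <- indel_params(0.1, 0, dist)
  del_only <- indel_params(0, 0.1, dist)
  for (i in 1:20) {
    set.seed(100 + i)
    expect_gte(simulate_branch_events(50, 0.5, ins_only)$final_length, 50)
    set.seed(200 + i)
    expect_lte(simulate_branch_events(50, 0.5, del_only)$final_length, 50)
  }
})

test_that("event coordinates are valid for the evolving sequence", {
  p <- indel_params(0.06, 0.1, length_distribution("zipf", 1.5, 30))
  for (i in 1:30) {
    set.seed(300 + i)
    sim <- simulate_branch_events(60, 0.4, p)
    n <- 60L
    ev <- sim$events
    if (nrow(ev)) for (j in seq_len(nrow(ev))) {
      if (ev$kind[j] == "insertion") {
        expect_true(ev$pos[j] >= 0 && ev$pos[j] <= n)
        n <- n + ev$eff_length[j]
      } else {
        expect_true(ev$pos[j] >= 1 &&
                      ev$pos[j] + ev$eff_length[j] - 1L <= n)
        n <- n - ev$eff_length[j]
      }
    }
    expect_identical(n, sim$final_length)
    # bit-reproducible given the seed
    set.seed(300 + i)
    again <- simulate_branch_events(60, 0.4, p)
    expect_identical(sim, again)
  }
})

test_that("event counts agree with an independent brute-force oracle", {
  p <- default_params()
  pmf <- length_pmf(p$length_dist)
  reps <- 400
  set.seed(42)
  k_oracle <- vapply(seq_len(reps), function(i)
    oracle_branch_count(1000, 0.05, 0.03, 0.09, pmf), 0L)
  set.seed(4242)
  k_pkg <- vapply(seq_len(reps), function(i)
    nrow(simulate_branch_events(1000, 0.05, p)$events), 0L)
  se <- sqrt(var(k_pkg) / reps + var(k_oracle) / reps)
  expect_lt(abs(mean(k_pkg) - mean(k_oracle)), 3 * se)
})
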