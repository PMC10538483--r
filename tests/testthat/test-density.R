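test_that("window_minimizer returns the leftmost order-minimal offset", {
  olex <- minimizer_order("lex", 2)
  expect_identical(window_minimizer("AAA", olex), 0L)  # identical k-mers tie
  expect_error(window_minimizer("AAA", olex, w = 5), "w \\+ k - 1")
  expect_error(window_minimizer("ANA", olex), "position 2")
  # a window holding exactly one decycling-set member selects it for any seed
  set.seed(14)
  d5 <- enumerate_decycling_set(5)
  found <- 0
  while (found < 5) {
    win <- paste(sample(ORACLE_BASES, 12, replace = TRUE), collapse = "")
    km <- substring(win, 1:8, 5:12)
    inD <- km %in% d5
    if (sum(inD) != 1) next
    found <- found + 1
    for (s in c(0, 3, 77, 1234)) {
      o <- minimizer_order("decycling", 5, seed = s)
      expect_identical(window_minimizer(win, o), which(inD) - 1L)
    }
  }
})

test_that("selection satisfies the window guarantee and forward property", {
  olex <- minimizer_order("lex", 2)
  expect_identical(select_minimizers("AAAA", olex, w = 2)$positions, c(0L, 1L))
  # a sequence of exactly one window selects exactly one position
  o <- minimizer_order("random", 5, seed = 3)
  one <- select_minimizers(generate_iid_sequence(12, 9), o, w = 8)
  expect_identical(one$n_windows, 1L)
  expect_length(one$positions, 1)
  expect_warning(short <- select_minimizers("ACGTACG", o, w = 8), "no window")
  expect_identical(short$positions, integer(0))
  expect_error(select_minimizers("ACGTN", o, w = 1), "non-ACGT")
  # homopolymer: leftmost ties select every window start
  oh <- minimizer_order("random", 5, seed = 8)
  hp <- select_minimizers(strrep("A", 500), oh, w = 10)
  expect_identical(hp$positions, 0:(hp$n_windows - 1L))
  set.seed(4)
  for (i in 1:20) {
    k <- sample(c(3, 5, 11), 1); w <- sample(c(2, 5, 20), 1)
    s <- generate_iid_sequence(sample(80:200, 1), 100 + i)
    o <- minimizer_order("random", k, seed = i)
    res <- select_minimizers(s, o, w = w)
    n <- nchar(s) - k + 1
    expect_true(covers_all_windows(res$positions, n, w))
    expect_false(is.unsorted(res$positions, strictly = TRUE))
  }
})

test_that("streaming selection equals the naive per-window argmin", {
  set.seed(6)
  for (i in 1:40) {
    k <- sample(c(3, 5, 11), 1); w <- sample(c(2, 5, 20), 1)
    s <- generate_iid_sequence(sample(60:160, 1), 500 + i)
    kind <- sample(c("random", "decycling", "double_decycling"), 1)
    o <- minimizer_order(kind, k, seed = i)
    want <- o_select(s, k, w, o$mask, o_ranks(s, k, kind))
    got <- select_minimizers(s, o, w = w)$positions
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("particular density splits on non-ACGT and is additive over runs", {
  o <- minimizer_order("random", 5, seed = 7)
  s1 <- generate_iid_sequence(300, 1)
  s2 <- generate_iid_sequence(250, 2)
  pd1 <- particular_density(s1, o, w = 10)
  expect_equal(pd1$density * pd1$n_positions, pd1$n_selected)
  expect_equal(pd1$density_factor, pd1$density * 11)
  joint <- particular_density(paste0(s1, "N", s2), o, w = 10)
  pd2 <- particular_density(s2, o, w = 10)
  expect_equal(joint$n_selected, pd1$n_selected + pd2$n_selected)
  expect_equal(joint$n_positions, pd1$n_positions + pd2$n_positions)
  expect_identical(joint$n_runs_used, 2L)
  # runs shorter than L are excluded entirely, and counted
  with_frag <- particular_density(paste0(s1, "NN", "ACGTACG"), o, w = 10)
  expect_equal(with_frag$n_positions, pd1$n_positions)
  expect_identical(with_frag$n_runs_skipped, 1L)
  expect_error(particular_density("ACGNNACG", o, w = 10), "no ACGT run")
  # multiple records aggregate like concatenation with separators
  two_rec <- particular_density(c(a = s1, b = s2), o, w = 10)
  expect_equal(two_rec$n_selected, joint$n_selected)
})

test_that("the i.i.d. generator is seeded, uniform and independent", {
  expect_identical(generate_iid_sequence(1000, 5), generate_iid_sequence(1000, 5))
  a <- generate_iid_sequence(1e5, 1)
  b <- generate_iid_sequence(1e5, 2)
  expect_false(identical(a, b))
  freq <- table(strsplit(generate_iid_sequence(1e6, 3), "")[[1]]) / 1e6
  expect_true(all(abs(freq - 0.25) < 0.005))
  mism <- mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_lt(abs(mism - 0.75), 3 * sqrt(0.75 * 0.25 / 1e5) + 1e-3)
  # generation must not disturb the caller's RNG stream
  set.seed(9); x <- runif(1)
  set.seed(9); invisible(generate_iid_sequence(10, 4)); y <- runif(1)
  expect_identical(x, y)
})

test_that("the forward-scheme lower bound has the published shape", {
  expect_equal(lower_bound_density_factor(1, 1), 2)
  expect_lt(abs(lower_bound_density_factor(11, 10 * 11) - 1.5), 0.15)  # within 10%
  # monotone approach to the asymptote for fixed k
  f <- lower_bound_density_factor(11, c(100, 1000, 10000))
  expect_true(all(diff(abs(f - 1.5)) < 0))
  # any scheme's measured factor respects the bound
  e <- expected_density("random", k = 7, w = 12, n_reps = 3, seq_len = 5e4,
                        base_seed = 2)
  expect_gt(e$mean_density_factor, lower_bound_density_factor(7, 12))
})

test_that("expected density aggregates seeded replicates reproducibly", {
  e1 <- expected_density("decycling", k = 7, w = 15, n_reps = 3, seq_len = 3e4,
                         base_seed = 11)
  e2 <- expected_density("decycling", k = 7, w = 15, n_reps = 3, seq_len = 3e4,
                         base_seed = 11)
  expect_identical(e1, e2)
  reps <- attr(e1, "replicates")
  expect_identical(nrow(reps), 3L)
  expect_equal(e1$mean_density_factor, mean(reps$density_factor))
  # a single replicate is just particular density of that seeded sequence
  e3 <- expected_density("random", k = 5, w = 10, n_reps = 1, seq_len = 2e4,
                         base_seed = 4)
  r3 <- attr(e3, "replicates")
  o <- minimizer_order("random", 5, seed = r3$order_seed[1])
  pd <- particular_density(generate_iid_sequence(2e4, r3$seq_seed[1]), o, w = 10)
  expect_equal(e3$mean_density_factor, pd$density_factor)
  expect_true(is.na(e3$stderr_density_factor))
  # w/L consistency handling
  expect_error(expected_density("random", k = 5, w = 10, L = 13), "w \\+ k - 1")
  expect_error(expected_density("random", k = 5), "provide w or L")
})

test_that("density sweeps cover the grid deterministically", {
  sw <- density_sweep(7, c(20, 40), c("random", "decycling"), n_reps = 2,
                      seq_len = 2e4, base_seed = 3)
  expect_identical(nrow(sw), 4L)
  expect_true(all(c("mean_density_factor", "stderr_density_factor",
                    "lower_bound_factor") %in% names(sw)))
  sw2 <- density_sweep(7, c(20, 40), c("random", "decycling"), n_reps = 2,
                       seq_len = 2e4, base_seed = 3)
  expect_identical(sw, sw2)
  expect_identical(nrow(density_sweep(7, 20, character(0))), 0L)
  expect_error(density_sweep(7, 7, "random"), "exceed")
})
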