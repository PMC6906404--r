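test_that("p_misrejoin closed forms and validation", {
  expect_equal(p_misrejoin(0, 0.7), 1)
  expect_equal(p_misrejoin(0.7, 0.7), exp(-1), tolerance = 1e-12)
  expect_equal(p_misrejoin(1.4, 0.7), exp(-2), tolerance = 1e-12)
  expect_error(p_misrejoin(-1, 0.7), ">= 0")
  expect_error(p_misrejoin(1, 0), "positive")
  expect_error(p_misrejoin(1, -2), "positive")
})

test_that("survival probability is the counted-misrejoining power law", {
  expect_equal(survival_probability(0), 1)
  expect_equal(survival_probability(2, 0.5), 0.25)
  expect_equal(survival_probability(3, 0.25), 0.015625)
  expect_error(survival_probability(-1), "non-negative")
  expect_error(survival_probability(1, 0), "p_nlmr")
  expect_error(survival_probability(1, 1.5), "p_nlmr")
})

test_that("counting rules reproduce the worked cases", {
  # a single explicit join counts once
  o1 <- make_outcome(2, data.frame(i = 1, end_i = 1, j = 2, end_j = 1))
  expect_equal(count_misrejoinings(o1), 1)
  # both ends of the same pair joined explicitly: second join not counted
  o2 <- make_outcome(2, data.frame(i = c(1, 1), end_i = c(1, 2),
                                   j = c(2, 2), end_j = c(1, 2)))
  expect_equal(count_misrejoinings(o2), 1)
  # closed triangle over 3 cDSBs with 3 explicit joins: 3 by default,
  # N - 1 = 2 with the corrected chain rule
  tri <- data.frame(i = c(1, 1, 2), end_i = c(1, 2, 2),
                    j = c(2, 3, 3), end_j = c(1, 1, 2))
  o3 <- make_outcome(3, tri)
  expect_equal(count_misrejoinings(o3), 3)
  expect_equal(count_misrejoinings(o3, corrected_chains = TRUE), 2)
  # an open chain of 3 (2 joins) is not corrected
  o4 <- make_outcome(3, tri[1:2, ])
  expect_equal(count_misrejoinings(o4), 2)
  expect_equal(count_misrejoinings(o4, corrected_chains = TRUE), 2)
  # inconsistent graph: an end used twice
  bad <- make_outcome(3, data.frame(i = c(1, 1), end_i = c(1, 1),
                                    j = c(2, 3), end_j = c(1, 1)))
  expect_error(count_misrejoinings(bad), "inconsistent")
})

test_that("N <= 1 yields no trials and far-apart cDSBs never pair", {
  o <- simulate_misrejoining(matrix(0, 1, 3), 0.7, seed = 1)
  expect_equal(o$n_explicit, 0)
  pos <- rbind(c(0, 0, 0), c(50, 0, 0))
  hits <- vapply(1:10000, function(s) {
    simulate_misrejoining(pos, 0.7, seed = s)$n_explicit
  }, 0)
  expect_true(all(hits == 0))
})

test_that("Monte Carlo matches the exact enumeration oracle (N = 2, 3)", {
  # N = 2 at moderate separation
  pos2 <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  ex2 <- enum_misrejoining(pos2, 0.7)
  nm <- ne <- numeric(2e4)
  for (s in seq_len(2e4)) {
    o <- simulate_misrejoining(pos2, 0.7, seed = 5e5 + s)
    nm[s] <- count_misrejoinings(o)
    ne[s] <- o$n_explicit
  }
  expect_lt(abs(mean(nm) - ex2["n_mr"]), 4 * sd(nm) / sqrt(2e4))
  expect_lt(abs(mean(ne) - ex2["n_explicit"]), 4 * sd(ne) / sqrt(2e4))

  # N = 3, non-degenerate triangle
  pos3 <- rbind(c(0, 0, 0), c(0.8, 0, 0), c(0.3, 0.9, 0.2))
  ex3 <- enum_misrejoining(pos3, 0.7)
  nm3 <- sv3 <- numeric(2e4)
  for (s in seq_len(2e4)) {
    o <- simulate_misrejoining(pos3, 0.7, seed = 7e5 + s)
    k <- count_misrejoinings(o)
    nm3[s] <- k
    sv3[s] <- 0.5^k
  }
  expect_lt(abs(mean(nm3) - ex3["n_mr"]), 4 * sd(nm3) / sqrt(2e4))
  expect_lt(abs(mean(sv3) - ex3["surv"]), 4 * sd(sv3) / sqrt(2e4))
})

test_that("structural invariants: join bounds and monotonicity in r0 and N", {
  set.seed(9)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    pos <- matrix(runif(3 * n, -3, 3), ncol = 3)
    o <- simulate_misrejoining(pos, 0.7, seed = 1000 + rep)
    expect_lte(o$n_explicit, n)
    expect_lte(count_misrejoinings(o), o$n_explicit)
    expect_gte(count_misrejoinings(o), 0)
    # symmetry of pairing bookkeeping: each end at most once
    ends <- with(o$pairings, c(paste(i, end_i), paste(j, end_j)))
    expect_false(anyDuplicated(ends) > 0)
  }
  # mean N_mr non-decreasing in r0 (coupled seeds), and in N
  pos <- matrix(runif(3 * 6, -3, 3), ncol = 3)
  means <- vapply(c(0.35, 0.7, 1.4), function(r0) {
    mean(vapply(1:400, function(s) {
      count_misrejoinings(simulate_misrejoining(pos, r0, seed = s))
    }, 0))
  }, 0)
  expect_true(all(diff(means) >= 0))
  means_n <- vapply(c(2, 4, 6), function(n) {
    mean(vapply(1:400, function(s) {
      count_misrejoinings(simulate_misrejoining(pos[seq_len(n), ], 0.7,
                                                seed = s))
    }, 0))
  }, 0)
  expect_true(all(diff(means_n) >= 0))
})

test_that("misrejoin_cells aggregates per cell with zero-count defaults", {
  cdsb <- data.frame(cell_id = c(2L, 2L, 5L),
                     x_um = c(0, 0.3, 1), y_um = 0, z_um = 0,
                     track_ids = "0")
  out <- misrejoin_cells(cdsb, cell_ids = 1:5, r0 = 0.7, p_nlmr = 0.5,
                         seed = 42)
  expect_equal(out$cell_id, 1:5)
  expect_equal(out$n_cdsb, c(0L, 2L, 0L, 0L, 1L))
  expect_true(all(out$n_mr[c(1, 3, 4, 5)] == 0))
  expect_equal(out$p_surv, 0.5^out$n_mr)
  # deterministic under the same master seed
  expect_identical(out, misrejoin_cells(cdsb, 1:5, 0.7, 0.5, seed = 42))
})
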