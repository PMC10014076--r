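test_that("bin_output builds the indexed rectangular grid", {
  ds <- dose_response_dataset(0, list(as.numeric(1:10)))
  b <- bin_output(ds, 2, "equal_frequency")
  expect_equal(unname(b$counts[1, ]), c(5, 5))

  ds <- dose_response_dataset(c(0, 1),
                              list(seq(0, 0.9, by = 0.1), seq(1.1, 2, by = 0.1)))
  b <- bin_output(ds, 2, "equal_width")
  expect_equal(unname(b$counts), diag(c(10, 10)))

  # degenerate: all outputs identical collapses to one effective bin
  ds <- dose_response_dataset(c(0, 1), list(rep(5, 10), rep(5, 10)))
  b <- bin_output(ds, 4, "equal_frequency")
  expect_equal(b$effective_bins, 1L)

  expect_error(bin_output(ds, 1), "domain error")

  # row sums always equal per-dose cell counts
  ds <- make_normal_dataset(c(0, 1, 3), n = 157, seed = 8)
  for (k in c(2, 7, 20)) {
    b <- bin_output(ds, k)
    expect_equal(unname(rowSums(b$counts)), rep(157, 3))
  }
})

test_that("estimate_joint weights empirical conditionals into a joint", {
  j <- estimate_joint(matrix(c(5, 5), 1), 1)
  expect_equal(unname(j$joint_p), matrix(c(0.5, 0.5), 1))
  j <- estimate_joint(matrix(c(10, 0, 0, 10), 2, byrow = TRUE), c(0.5, 0.5))
  expect_equal(unname(j$joint_p), matrix(c(0.5, 0, 0, 0.5), 2, byrow = TRUE))
  j <- estimate_joint(matrix(c(1, 3), 1), 1)
  expect_equal(unname(j$joint_p), matrix(c(0.25, 0.75), 1))
  expect_equal(sum(j$joint_p), 1, tolerance = 1e-12)
  expect_error(estimate_joint(matrix(c(0, 0, 1, 1), 2, byrow = TRUE),
                              c(0.5, 0.5)),
               "domain error")
})

test_that("info_summary computes entropies and mutual information in bits", {
  s <- info_summary(matrix(c(0.5, 0, 0, 0.5), 2, byrow = TRUE))
  expect_equal(s$H_x, 1); expect_equal(s$H_y, 1)
  expect_equal(s$H_xy, 1); expect_equal(s$I_xy, 1)

  s <- info_summary(matrix(0.25, 2, 2))
  expect_equal(s$H_xy, 2); expect_equal(s$I_xy, 0)

  # four-term direct summation oracle
  p <- matrix(c(0.25, 0.25, 0, 0.5), 2, byrow = TRUE)
  s <- info_summary(p)
  direct <- 0
  px <- rowSums(p); py <- colSums(p)
  for (i in 1:2) for (j in 1:2) {
    if (p[i, j] > 0) {
      direct <- direct + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    }
  }
  expect_equal(s$I_xy, direct, tolerance = 1e-12)
  expect_equal(s$I_xy, 0.311278, tolerance = 1e-6)
  expect_equal(s$I_xy, s$H_x + s$H_y - s$H_xy, tolerance = 1e-9)
})

test_that("blahut_arimoto solves canonical channels", {
  r <- blahut_arimoto(diag(4))
  expect_equal(r$bits, 2, tolerance = 1e-8)
  expect_equal(r$optimal_input, rep(0.25, 4), tolerance = 1e-6)

  r <- blahut_arimoto(bsc(0.11))
  expect_equal(r$bits, 1 - h2(0.11), tolerance = 1e-8)
  expect_equal(r$optimal_input, c(0.5, 0.5), tolerance = 1e-6)

  r <- blahut_arimoto(matrix(c(0.2, 0.8, 0.2, 0.8), 2, byrow = TRUE))
  expect_equal(r$bits, 0, tolerance = 1e-9)

  expect_error(blahut_arimoto(matrix(c(0.5, 0.4, 0.4, 0.4), 2, 2)),
               "domain error")
})

test_that("blahut_arimoto matches exhaustive grid search on random channels", {
  set.seed(42)
  for (rep in 1:20) {
    Q <- random_stochastic(3, 3)
    ba <- blahut_arimoto(Q, tol = 1e-10)$bits
    gs <- grid_search_capacity(Q, step = 0.01)
    expect_lt(abs(ba - gs), 0.002)
    expect_gte(ba, gs - 1e-9)  # grid search can only undershoot
  }
})

test_that("coarsening output bins never increases mutual information", {
  set.seed(7)
  for (rep in 1:25) {
    m <- sample(2:4, 1); k <- sample(3:6, 1)
    p <- matrix(rexp(m * k), m, k); p <- p / sum(p)
    i_full <- info_summary(p)$I_xy
    j <- sample(k - 1, 1)  # merge adjacent columns j, j+1
    merged <- cbind(p[, seq_len(j - 1), drop = FALSE],
                    p[, j] + p[, j + 1],
                    p[, seq(j + 2, length.out = k - j - 1), drop = FALSE])
    expect_lte(info_summary(merged)$I_xy, i_full + 1e-12)
    # permutation of output labels leaves information unchanged
    perm <- sample(k)
    expect_equal(info_summary(p[, perm])$I_xy, i_full, tolerance = 1e-12)
  }
})

test_that("estimate_capacity enforces its preconditions", {
  ds <- make_normal_dataset(c(0, 2), n = 30)
  expect_error(estimate_capacity(ds, n_bins = 8), "sample-size error")
  est <- estimate_capacity(ds, n_bins = 8, min_cells = 10,
                           bias_correction = FALSE)
  expect_s3_class(est, "capacity_estimate")
  one <- dose_response_dataset(0, list(rnorm(100)))
  expect_error(estimate_capacity(one, n_bins = 8), ">= 2 doses")
  flat <- dose_response_dataset(c(0, 1), list(rep(1, 60), rep(1, 60)))
  expect_error(estimate_capacity(flat, n_bins = 8), "degeneracy error")
})

test_that("capacity estimates respect the input-alphabet ceiling", {
  set.seed(31)
  for (rep in 1:5) {
    m <- sample(2:4, 1)
    ds <- make_normal_dataset(seq_len(m) * 0.5, n = 200, seed = rep)
    est <- estimate_capacity(ds, n_bins = 8, bias_correction = FALSE)
    expect_lte(est$bits, log2(m) + 1e-9)
    expect_equal(sum(est$optimal_input), 1, tolerance = 1e-6)
    expect_true(all(est$optimal_input >= 0))
  }
})

test_that("finite-sample bias is positive on independence data", {
  # uncorrected capacity exceeds the bias-corrected extrapolation
  wins <- 0
  for (s in 1:6) {
    ds <- make_normal_dataset(rep(0, 6), n = 300, seed = 100 + s)
    est <- estimate_capacity(ds, n_bins = 10, bias_correction = TRUE,
                             n_bootstrap = 0, seed = s)
    wins <- wins + (est$bits_uncorrected > est$bits)
  }
  expect_gte(wins, 5)
})

test_that("capacity estimation is deterministic given a seed", {
  ds <- simulate_mixture_reporter(mixture_reporter_config(
    n_cells_per_dose = 200, seed = 19))
  a <- estimate_capacity(ds, n_bins = 10, n_bootstrap = 10, seed = 99,
                         min_cells = 50)
  b <- estimate_capacity(ds, n_bins = 10, n_bootstrap = 10, seed = 99,
                         min_cells = 50)
  expect_identical(a$bits, b$bits)
  expect_identical(a$ci_low, b$ci_low)
  expect_true(a$ci_low <= a$bits && a$bits <= a$ci_high || a$ci_flag)
})

test_that("bootstrap CI brackets the estimate on informative data", {
  ds <- simulate_known_channel(known_channel_config(bsc(0.2), 1000, seed = 4))
  est <- estimate_capacity(ds, n_bins = 8, bias_correction = TRUE,
                           n_bootstrap = 30, seed = 5)
  expect_false(est$ci_flag)
  expect_lt(est$ci_low, est$ci_high)
})

test_that("capacity_vs_max_dose runs nested dose prefixes", {
  ds <- make_normal_dataset(c(0, 0.5, 1.5, 3), n = 200, seed = 2,
                            doses = c(0, 1, 10, 100))
  curve <- capacity_vs_max_dose(ds, n_bins = 8, bias_correction = FALSE)
  expect_equal(nrow(curve), 3)
  expect_equal(curve$max_dose, c(1, 10, 100))
  expect_equal(curve$n_doses, 2:4)

  two <- make_normal_dataset(c(0, 1), n = 120, seed = 3)
  expect_equal(nrow(capacity_vs_max_dose(two, n_bins = 8,
                                         bias_correction = FALSE)), 1)
})

test_that("true capacities of nested input prefixes are non-decreasing", {
  # only the top input distinguishable: capacity ~0 until it enters
  m <- 5
  Q <- rbind(matrix(rep(c(0.5, 0.5, 0), each = 1), m - 1, 3, byrow = TRUE),
             c(0, 0, 1))
  caps <- vapply(2:m, function(k) true_capacity(Q[1:k, , drop = FALSE]),
                 numeric(1))
  expect_true(all(diff(caps) >= -1e-12))
  expect_lt(caps[1], 1e-9)
  expect_gt(caps[m - 1], 0.9)
})

test_that("select_bin_count finds the discretization plateau", {
  ds <- simulate_known_channel(known_channel_config(diag(4), 2000, seed = 3))
  sel <- select_bin_count(ds, candidates = c(8, 16, 32), seed = 5)
  expect_equal(as.integer(sel), 8L)
  prof <- attr(sel, "profile")
  expect_true(all(abs(prof$bits - 2) < 0.05))

  # independence data: all estimates near zero, smallest candidate returned
  ds0 <- make_normal_dataset(rep(0, 4), n = 400, seed = 12)
  sel0 <- select_bin_count(ds0, candidates = c(8, 16, 32), seed = 5)
  expect_equal(as.integer(sel0), 8L)

  expect_error(select_bin_count(ds, candidates = 8), "domain error")
})
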