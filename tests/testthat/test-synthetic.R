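test_that("mixture simulator reproduces its configured populations", {
  cfg <- mixture_reporter_config(p_min = 0, p_max = 0,
                                 n_cells_per_dose = 2000, seed = 5)
  ds <- simulate_mixture_reporter(cfg)
  pooled <- unlist(ds$outputs)
  se <- cfg$basal_log_sd / sqrt(length(pooled))
  expect_lt(abs(mean(pooled) - cfg$basal_log_mean), 4 * se)

  # identical seeds give identical datasets; different seeds do not
  a <- simulate_mixture_reporter(mixture_reporter_config(seed = 11,
                                                         n_cells_per_dose = 100))
  b <- simulate_mixture_reporter(mixture_reporter_config(seed = 11,
                                                         n_cells_per_dose = 100))
  c <- simulate_mixture_reporter(mixture_reporter_config(seed = 12,
                                                         n_cells_per_dose = 100))
  expect_identical(a$outputs, b$outputs)
  expect_false(identical(a$outputs, c$outputs))
})

test_that("activation fraction at the half-max dose is near 0.5", {
  n <- 10000
  cfg <- mixture_reporter_config(doses = c(0, 0.1, 1, 10),
                                 n_cells_per_dose = n,
                                 basal_log_mean = 0, basal_log_sd = 1e-6,
                                 active_log_mean = 10, active_log_sd = 1e-6,
                                 p_min = 0.05, p_max = 0.95,
                                 ec50 = 1, seed = 3)
  ds <- simulate_mixture_reporter(cfg)
  frac <- mean(ds$outputs[[3]] > 5)  # populations made separable on purpose
  ci <- qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("known-channel simulator emits the configured conditional", {
  # identity channel without jitter: outputs equal their input's center
  cfg <- known_channel_config(diag(2), n_cells_per_dose = 50,
                              output_jitter_sd = 0, seed = 2)
  ds <- simulate_known_channel(cfg)
  expect_true(all(ds$outputs[[1]] == 1))
  expect_true(all(ds$outputs[[2]] == 2))

  # identical rows: empirical output distribution independent of dose
  Q <- matrix(c(0.3, 0.7, 0.3, 0.7), 2, 2, byrow = TRUE)
  ds <- simulate_known_channel(known_channel_config(Q, 5000,
                                                    output_jitter_sd = 0,
                                                    seed = 6))
  tab <- rbind(table(factor(ds$outputs[[1]], levels = 1:2)),
               table(factor(ds$outputs[[2]], levels = 1:2)))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.001)

  # law of large numbers: empirical conditional within 0.01 entrywise
  Q <- matrix(c(0.6, 0.3, 0.1, 0.2, 0.2, 0.6), 2, 3, byrow = TRUE)
  ds <- simulate_known_channel(known_channel_config(Q, 100000,
                                                    output_jitter_sd = 0,
                                                    seed = 9))
  emp <- t(vapply(ds$outputs, function(v) {
    tabulate(round(v), nbins = 3) / length(v)
  }, numeric(3)))
  expect_lt(max(abs(emp - Q)), 0.01)
})

test_that("known-channel config validates its invariants", {
  expect_error(known_channel_config(matrix(c(0.5, 0.4, 0.4, 0.4), 2, 2)),
               "config error")
  expect_error(known_channel_config(diag(2), output_centers = c(2, 1)),
               "strictly increasing")
  expect_error(known_channel_config(diag(2), output_centers = c(1, 1.05),
                                    output_jitter_sd = 0.02),
               "6 x jitter")
  expect_error(mixture_reporter_config(p_min = 0.9, p_max = 0.1),
               "config error")
  expect_error(mixture_reporter_config(basal_log_mean = 3,
                                       active_log_mean = 2),
               "brighter")
})

test_that("true_capacity matches closed forms", {
  for (n in c(2, 4, 8)) {
    expect_equal(true_capacity(diag(n)), log2(n), tolerance = 1e-9)
  }
  expect_equal(true_capacity(bsc(0.11)), 1 - h2(0.11), tolerance = 1e-9)
  expect_equal(true_capacity(matrix(0.25, 3, 4)), 0, tolerance = 1e-9)
  expect_error(true_capacity(matrix(c(0.5, 0.4, 0.4, 0.4), 2, 2)),
               "domain error")
})

test_that("estimates on known-channel data converge to the true capacity", {
  # parameter recovery at n = 5000 cells per input, small jitter
  Q <- matrix(c(0.9, 0.1, 0, 0.1, 0.8, 0.1, 0, 0.2, 0.8), 3, 3, byrow = TRUE)
  ds <- simulate_known_channel(known_channel_config(Q, 5000, seed = 17))
  est <- estimate_capacity(ds, n_bins = "auto", bias_correction = TRUE,
                           n_bootstrap = 0, seed = 17)
  expect_lt(abs(est$bits - true_capacity(Q)), 0.05)
})

test_that("shuffling dose labels destroys the transmitted information", {
  ds <- simulate_mixture_reporter(mixture_reporter_config(
    n_cells_per_dose = 1000, seed = 23))
  est0 <- estimate_capacity(ds, n_bins = 10, bias_correction = TRUE,
                            n_bootstrap = 0, seed = 1)
  sh <- shuffle_dose_labels(ds, seed = 2)
  est <- estimate_capacity(sh, n_bins = 10, bias_correction = TRUE,
                           n_bootstrap = 0, seed = 1)
  expect_gt(est0$bits, 0.3)   # the intact channel carries information
  expect_lt(est$bits, 0.05)   # the shuffled one does not
})
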