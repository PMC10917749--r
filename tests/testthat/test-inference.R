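test_that("BH step-up reproduces the hand-computed rejection set", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.2)
  expect_equal(fdr_significant(p, 0.05), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # rejections form a prefix of the sorted p-values; raising q keeps them
  set.seed(1)
  for (rep in 1:20) {
    pv <- runif(30)^2
    sig5 <- fdr_significant(pv, 0.05)
    sig10 <- fdr_significant(pv, 0.10)
    ord <- order(pv)
    expect_true(all(diff(sig5[ord]) <= 0))        # prefix property
    expect_true(all(sig10[sig5]))                 # monotone in q
  }
})

test_that("timepoint_tests flags injected windows and not null data", {
  times <- seq(0, 0.99, 0.01)
  # all-zero curves: nothing significant
  zero <- matrix(0, 6, 100)
  expect_warning(s0 <- timepoint_tests(zero, times), "zero variance")
  expect_false(any(s0$significant))

  # embedded effect window
  set.seed(2)
  eff <- matrix(rnorm(16 * 100, sd = 0.1), 16, 100)
  eff[, 41:50] <- eff[, 41:50] + 1
  s <- timepoint_tests(eff, times)
  expect_true(all(s$significant[41:50]))
  expect_lte(mean(s$significant[-(41:50)]), 0.05)

  # null_mean shifts the tested reference
  bias <- matrix(rnorm(16 * 100, mean = 0.05, sd = 0.02), 16, 100)
  s_raw <- timepoint_tests(bias, times)
  s_deb <- timepoint_tests(bias, times, null_mean = 0.05)
  expect_gt(mean(s_raw$significant), 0.9)
  expect_lt(mean(s_deb$significant), 0.2)

  expect_error(timepoint_tests(matrix(0, 1, 100), times), "2 participants")
})

test_that("null_unique_mean matches the simulated OLS null expectation", {
  set.seed(3)
  n <- 300
  X <- matrix(rnorm(n * 5), n)
  uniq <- replicate(300, {
    y <- rnorm(n)
    fit_r2(y, X) - fit_r2(y, X[, 1:3])
  })
  expect_lt(abs(mean(uniq) - null_unique_mean(n, 2)), 0.002)
})

test_that("peak_latency finds maxima and breaks ties toward earlier times", {
  times <- seq(0, 0.5, 0.01)
  spike <- numeric(51); spike[times == 0.13] <- 1
  expect_equal(peak_latency(spike, times), 0.13)
  expect_equal(peak_latency(rep(1, 51), times), 0)          # flat -> earliest
  expect_equal(peak_latency(rep(1, 51), times, c(0.2, 0.4)), 0.2)
  expect_error(peak_latency(spike, times, c(0.9, 1)), "no time points")

  # noisy Gaussian bump centered at 0.30 s
  set.seed(4)
  curve <- exp(-0.5 * ((times - 0.3) / 0.03)^2) + rnorm(51, sd = 0.1)
  expect_lte(abs(peak_latency(curve, times) - 0.3), 0.02)
})

test_that("bootstrap_peaks is deterministic with degenerate-width CI on identical curves", {
  times <- seq(0, 0.5, 0.01)
  curves <- bump_curves(8, times, 0.25, seed = 5)
  a <- bootstrap_peaks(curves, times, n_boot = 300, seed = 9)
  b <- bootstrap_peaks(curves, times, n_boot = 300, seed = 9)
  expect_identical(a$bootstrap_latencies, b$bootstrap_latencies)

  same <- matrix(rep(exp(-0.5 * ((times - 0.2) / 0.05)^2), 4), 4,
                 byrow = TRUE)
  d <- bootstrap_peaks(same, times, n_boot = 200, seed = 1)
  expect_equal(d$ci95[1], d$ci95[2])
  expect_equal(d$peak_latency, 0.2)
  expect_warning(bootstrap_peaks(curves, times, n_boot = 50, seed = 1),
                 "unstable")
})

test_that("bootstrap CI covers an injected latency and narrows with cohort size", {
  times <- seq(0, 0.5, 0.01)
  cover <- 0
  for (s in 1:20) {
    curves <- bump_curves(16, times, 0.30, snr = 5, seed = 100 + s)
    pk <- bootstrap_peaks(curves, times, n_boot = 300, seed = s)
    cover <- cover + (pk$ci95[1] <= 0.30 && 0.30 <= pk$ci95[2])
  }
  expect_gte(cover, 18)    # >= 90% empirical coverage

  widths <- vapply(c(8, 32), function(np) {
    median(vapply(1:8, function(s) {
      curves <- bump_curves(np, times, 0.25, snr = 3, seed = 200 + s)
      diff(bootstrap_peaks(curves, times, n_boot = 200, seed = s)$ci95)
    }, numeric(1)))
  }, numeric(1))
  expect_lte(widths[2], widths[1])
})

test_that("the two peak-latency modes agree on high-SNR cohorts", {
  times <- seq(0, 0.5, 0.01)
  curves <- bump_curves(16, times, 0.22, snr = 20, seed = 31)
  pa <- bootstrap_peaks(curves, times, n_boot = 300, seed = 2,
                        mode = "peak_of_average")
  ap <- bootstrap_peaks(curves, times, n_boot = 300, seed = 2,
                        mode = "average_of_peaks")
  expect_true(ap$peak_latency >= pa$ci95[1] - 0.01 &&
                ap$peak_latency <= pa$ci95[2] + 0.01)
})

test_that("compare_peaks is paired, calibrated, and detects latency gaps", {
  times <- seq(0, 0.5, 0.01)
  curves <- bump_curves(16, times, 0.2, seed = 7)
  a <- bootstrap_peaks(curves, times, n_boot = 400, seed = 3)
  b <- bootstrap_peaks(curves, times, n_boot = 400, seed = 3)
  expect_gte(compare_peaks(a, b), 0.99)   # identical curves: p ~ 1

  other <- bootstrap_peaks(curves, times, n_boot = 400, seed = 4)
  expect_error(compare_peaks(a, other), "not paired")

  # separated latencies: strongly significant
  early <- bootstrap_peaks(bump_curves(16, times, 0.13, snr = 8, seed = 8),
                           times, n_boot = 400, seed = 5)
  late <- bootstrap_peaks(bump_curves(16, times, 0.30, snr = 8, seed = 9),
                          times, n_boot = 400, seed = 5)
  expect_lt(compare_peaks(early, late), 0.01)

  # equal latencies: type-I rate at alpha = 0.05 stays near nominal
  rejections <- vapply(1:40, function(s) {
    x <- bootstrap_peaks(bump_curves(8, times, 0.25, snr = 4,
                                     seed = 1000 + s),
                         times, n_boot = 200, seed = s)
    y <- bootstrap_peaks(bump_curves(8, times, 0.25, snr = 4,
                                     seed = 2000 + s),
                         times, n_boot = 200, seed = s)
    compare_peaks(x, y) < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.075)
})

test_that("compare_all_peaks corrects across the model pairs", {
  times <- seq(0, 0.5, 0.01)
  peaks <- lapply(c(0.13, 0.17, 0.16, 0.30), function(lat)
    bootstrap_peaks(bump_curves(12, times, lat, snr = 10, seed = round(lat * 1000)),
                    times, n_boot = 300, seed = 77,
                    group_name = sprintf("m%.2f", lat)))
  tab <- compare_all_peaks(peaks)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$p_adjusted >= tab$p))
  expect_equal(tab$p_adjusted, p.adjust(tab$p, "BH"))
})
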