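test_that("fit_r2 handles exact, orthogonal, and noisy targets", {
  set.seed(1)
  x1 <- rnorm(200)
  expect_equal(fit_r2(x1, list(x1)), 1, tolerance = 1e-12)
  expect_equal(fit_r2(rnorm(200), list()), 0)

  # sample-orthogonal predictor: R^2 = 0 to numerical precision
  y <- rnorm(100)
  x <- rnorm(100)
  x_orth <- resid(lm(x ~ y))
  expect_lt(fit_r2(y, list(x_orth)), 1e-10)

  # noisy linear combination matches the independent normal-equations oracle
  set.seed(42)
  n <- 1225
  x1 <- rnorm(n); x2 <- rnorm(n)
  yy <- 0.6 * x1 + 0.8 * x2 + rnorm(n, sd = 0.1)
  expect_equal(fit_r2(yy, list(x1, x2)), oracle_r2(yy, cbind(x1, x2)),
               tolerance = 1e-10)
})

test_that("fit_r2 warns on collinear predictors instead of failing", {
  set.seed(2)
  x <- rnorm(50)
  y <- x + rnorm(50, sd = 0.5)
  expect_warning(r2 <- fit_r2(y, list(x, 2 * x)), "collinear")
  expect_equal(r2, fit_r2(y, list(x)), tolerance = 1e-10)
})

test_that("unique variance matches the all-subsets brute-force oracle", {
  # random 3- and 4-group instances at n = 1225 pairs (50 conditions)
  for (k in 3:4) {
    set.seed(100 + k)
    n_cond <- 50
    n <- n_cond * (n_cond - 1) / 2
    shared <- rnorm(n)
    members <- lapply(seq_len(k), function(g) {
      p_g <- sample(1:2, 1)
      lapply(seq_len(p_g), function(j) 0.5 * shared + rnorm(n))
    })
    y <- rowSums(do.call(cbind, lapply(members, function(m)
      Reduce(`+`, m)))) + rnorm(n, sd = 2)
    groups <- lapply(seq_len(k), function(g)
      model_group(paste0("g", g), lapply(members[[g]], devectorize_lower)))
    eeg <- rdm_series(array(unclass(devectorize_lower(y)), c(n_cond, n_cond, 1)), 0)
    vp <- unique_variance_timecourse(eeg, groups)

    Xall <- do.call(cbind, lapply(unlist(members, recursive = FALSE), scale))
    sizes <- vapply(members, length, integer(1))
    col_group <- rep(seq_len(k), sizes)
    ys <- as.numeric(scale(y))
    r2_full <- oracle_r2(ys, Xall)
    expect_equal(vp$r2_all[1], r2_full, tolerance = 1e-10)
    for (g in seq_len(k)) {
      r2_wo <- oracle_r2(ys, Xall[, col_group != g, drop = FALSE])
      expect_equal(unname(vp$unique[g, 1]), r2_full - r2_wo,
                   tolerance = 1e-10)
    }
    # the full commonality decomposition is consistent: all-subset R^2 are
    # monotone and unique components sum to at most R2_full
    subs <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    r2_sub <- apply(subs, 1, function(inc)
      oracle_r2(ys, Xall[, col_group %in% which(inc), drop = FALSE]))
    expect_true(all(r2_sub <= r2_full + 1e-12))
    expect_lte(sum(vp$unique[, 1]), vp$r2_all[1] + 1e-12)
  }
})

test_that("exact-match and orthogonal groups give unique variance 1 and 0", {
  target <- random_rdm(12, seed = 5)
  n_t <- 3
  vals <- array(unclass(target), c(12, 12, n_t))
  eeg <- rdm_series(vals, seq(0, by = 0.01, length.out = n_t),
                    condition_ids(target))
  set.seed(6)
  other <- devectorize_lower(rnorm(66), condition_ids = condition_ids(target))
  vp <- unique_variance_timecourse(eeg, list(
    model_group("A", target), model_group("B", other)))
  expect_true(all(vp$unique["A", ] > 0.95))
  expect_true(all(vp$unique["B", ] < 0.05))
})

test_that("nestedness holds exactly across random instances", {
  set.seed(9)
  for (rep in 1:5) {
    eeg <- rdm_series(array(unclass(random_rdm(10, rep)), c(10, 10, 2)),
                      c(0, 0.01))
    groups <- lapply(1:3, function(g)
      model_group(paste0("g", g),
                  devectorize_lower(rnorm(45),
                                    condition_ids = eeg$condition_ids)))
    vp <- unique_variance_timecourse(eeg, groups)
    expect_true(all(vp$r2_all >= 0 & vp$r2_all <= 1))
    expect_true(all(sweep(vp$r2_reduced, 2, vp$r2_all, `-`) <= 1e-12))
    expect_true(all(vp$unique >= -1e-12))
  }
})

test_that("shuffling the neural RDM drives unique variance to the null floor", {
  set.seed(11)
  n_cond <- 50
  n <- n_cond * (n_cond - 1) / 2
  groups <- lapply(1:3, function(g)
    model_group(paste0("g", g), devectorize_lower(rnorm(n))))
  base <- vectorize_lower(average_rdms(groups[[1]]))
  uniq <- replicate(100, {
    y <- sample(base)
    eeg <- rdm_series(array(unclass(devectorize_lower(y)),
                            c(n_cond, n_cond, 1)), 0)
    unique_variance_timecourse(eeg, groups)$unique[, 1]
  })
  expect_lt(mean(uniq), 0.01)
})

test_that("unique-variance curves peak at well-separated injected latencies", {
  # moderate amplitude keeps decoding in its sensitive range, where the
  # group-mean unique-variance curve tracks the injected envelope center
  cfg <- run_config(seed = 17, n_participants = 8,
                    model_names = c("A", "B"),
                    latencies = c(0.10, 0.20, 0.32),
                    amplitude = 2, n_boot = 100, peak_window = c(0, 0.5))
  res <- run_pipeline(cfg)
  injected <- c(A = 0.10, B = 0.20, NAM = 0.32)
  for (g in names(injected)) {
    curve <- colMeans(res$unique[[g]])
    pk <- peak_latency(curve, res$varpart[[1]]$times, c(0, 0.5))
    expect_lte(abs(pk - injected[[g]]), 0.03 + 1e-9)
  }
})

test_that("varpart_table emits the long format", {
  eeg <- rdm_series(array(unclass(random_rdm(6, 1)), c(6, 6, 2)), c(0, 0.01))
  vp <- unique_variance_timecourse(
    eeg, model_group("A", random_rdm(6, 2)), participant_id = "P01")
  tab <- varpart_table(vp)
  expect_setequal(unique(tab$quantity), c("r2_all", "r2_reduced:A", "unique:A"))
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$participant == "P01"))
})
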