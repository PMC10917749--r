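test_that("aggregate_heatmaps normalizes to max 1 and is scale invariant", {
  m <- matrix(0, 6, 6); m[2, 3] <- 4
  one <- aggregate_heatmaps(list(m))
  expect_equal(max(one), 1)
  expect_equal(which(one > 0), which(m > 0))
  # two identical maps aggregate to the same normalized result as one
  expect_equal(aggregate_heatmaps(list(m, m)), one)
  # disjoint single-pixel maps end up with equal weight
  m2 <- matrix(0, 6, 6); m2[4, 5] <- 4
  both <- aggregate_heatmaps(list(m, m2))
  expect_equal(both[2, 3], 1)
  expect_equal(both[4, 5], 1)
  expect_error(aggregate_heatmaps(list(m, matrix(0, 5, 5))), "dimensions")
})

test_that("angular_histogram bins axis and diagonal offsets correctly", {
  # 9x9 grid, origin at bottom row, column floor(9/2)+1 = 5
  g <- matrix(0, 9, 9)
  g[8, 5] <- 1    # straight above origin -> 90 deg
  h <- angular_histogram(g)
  expect_equal(which(h$counts > 0) - 1L, 90)

  g <- matrix(0, 9, 9); g[9, 6] <- 1   # right along origin row -> bin 0
  expect_equal(which(angular_histogram(g)$counts > 0) - 1L, 0)
  g <- matrix(0, 9, 9); g[9, 4] <- 1   # left -> 180 deg -> closed top bin 179
  expect_equal(which(angular_histogram(g)$counts > 0) - 1L, 179)

  # offsets (dx, dy) = (1,1), (-1,1), (0,2) -> bins 45, 135, 90
  g <- matrix(0, 9, 9)
  g[8, 6] <- 1; g[8, 4] <- 1; g[7, 5] <- 1
  h <- angular_histogram(g)
  expect_equal(which(h$counts > 0) - 1L, c(45, 90, 135))
  expect_equal(sum(h$counts), 3)
})

test_that("angular_histogram ignores sub-origin pixels and respects threshold", {
  g <- matrix(0, 6, 8)
  g[6, 7] <- 0.9      # below-origin-row? origin row = 6; same row, right: bin 0
  g[6, 2] <- 0.9      # left on origin row: bin 179
  g[3, 4] <- 0.05     # faint pixel
  h <- angular_histogram(g, weight_threshold = 0.5)
  expect_equal(sum(h$counts), 2)       # faint pixel excluded
  # weighted mode accumulates intensities rather than counts
  hw <- angular_histogram(g, weight_threshold = 0, weighted = TRUE)
  expect_equal(sum(hw$counts), 0.9 + 0.9 + 0.05)
  # all-zero heatmap is an all-zero histogram, not an error
  expect_equal(sum(angular_histogram(matrix(0, 8, 8))$counts), 0)
  expect_error(angular_histogram(matrix(0, 8, 8), origin = c(20, 1)),
               "inside")
})

test_that("histogram total equals above-threshold pixels in the upper half-plane", {
  set.seed(4)
  for (s in 1:5) {
    maps <- generate_heatmaps(1, paths_per_image = c(2, 4),
                              image_size = c(24, 20), seed = s)
    g <- aggregate_heatmaps(maps)
    h <- angular_histogram(g)
    origin <- c(nrow(g), floor(ncol(g) / 2) + 1L)
    hit <- which(g > 0, arr.ind = TRUE)
    upper <- sum(hit[, 1] <= origin[1] &
                   !(hit[, 1] == origin[1] & hit[, 2] == origin[2]))
    expect_equal(sum(h$counts), upper)
  }
})

test_that("mirror-reflected heatmaps map bin b to 179 - b", {
  # integer angles (0/45/90/135/180 deg, i.e. axis or exact-diagonal pixels)
  # sit on bin edges where floor binning is not mirror-symmetric; generic
  # pixels avoid them
  set.seed(5)
  origin <- c(15, 8)
  g <- matrix(0, 15, 15)
  pix <- cbind(sample(1:13, 8, replace = TRUE), sample(c(1:6, 10:15), 8))
  dxy <- cbind(pix[, 2] - origin[2], origin[1] - pix[, 1])
  pix <- pix[abs(dxy[, 1]) != abs(dxy[, 2]) & dxy[, 1] != 0 & dxy[, 2] != 0, ,
             drop = FALSE]
  g[pix] <- 1
  h <- angular_histogram(g, origin = origin)
  gm <- g[, rev(seq_len(15))]          # reflect about the origin column
  hm <- angular_histogram(gm, origin = origin)
  expect_equal(hm$counts, rev(h$counts))
})

test_that("nam_rdm reproduces hand-computed Euclidean distances", {
  e90 <- numeric(180); e90[91] <- 1
  e0 <- numeric(180); e0[1] <- 1
  r <- nam_rdm(list(e90, e0))
  expect_equal(r[1, 2], sqrt(2), ignore_attr = TRUE)
  expect_equal(unclass(nam_rdm(list(e90, e90)))[1, 2], 0)

  set.seed(10)
  h3 <- lapply(1:3, function(i) rpois(180, 2))
  r3 <- nam_rdm(h3)
  for (i in 1:3) for (j in 1:3)
    expect_equal(unclass(r3)[i, j], sqrt(sum((h3[[i]] - h3[[j]])^2)))
  expect_error(nam_rdm(list(numeric(10), numeric(10))), "180")
})

test_that("nam_rdm satisfies the metric axioms on random histograms", {
  set.seed(11)
  hs <- lapply(1:6, function(i) runif(180, 0, 5))
  r <- unclass(nam_rdm(hs))
  expect_equal(r, t(r))
  expect_equal(diag(r), rep(0, 6), ignore_attr = TRUE)
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(r[i, k], r[i, j] + r[j, k] + 1e-12)
})

test_that("a single straight-up path concentrates mass at 90 degrees", {
  maps <- generate_heatmaps(1, paths_per_image = c(1, 1),
                            image_size = c(21, 21),
                            angle_range = c(90, 90), angle_jitter = 0,
                            seed = 3)
  h <- angular_histogram(aggregate_heatmaps(maps))
  expect_equal(sum(h$counts[91]), sum(h$counts))
  expect_gt(sum(h$counts), 0)
})

test_that("heatmap generation is deterministic, connected, and validated", {
  a <- generate_heatmaps(3, seed = 42)
  b <- generate_heatmaps(3, seed = 42)
  expect_identical(a, b)
  expect_identical(generate_heatmaps(0, seed = 1), list())
  expect_error(generate_heatmaps(2, paths_per_image = c(0, 2)), "paths")
  expect_error(generate_heatmaps(2, image_size = c(4, 4)), "image_size")
  # every path starts at the bottom-center pixel
  for (g in a) expect_gt(g[nrow(g), floor(ncol(g) / 2) + 1L], 0)
  # non-negative grids
  expect_true(all(vapply(a, function(g) all(g >= 0), logical(1))))
})
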