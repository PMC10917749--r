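#' Latency profile for synthetic epochs
#'
#' Describes when each model's representational geometry becomes decodable:
#' one entry per model with the Gaussian envelope's center (onset latency),
#' its width (SD, seconds) and a non-negative pattern amplitude relative to
#' the noise SD.
#'
#' @param model_names character vector of unique model names.
#' @param onset_latency numeric vector of envelope centers in seconds.
#' @param envelope_width numeric vector (or scalar) of envelope SDs, > 0.
#' @param amplitude numeric vector (or scalar) of amplitudes, >= 0.
#' @return object of class `latency_profile` (a data.frame).
#' @export
latency_profile <- function(model_names, onset_latency,
                            envelope_width = 0.04, amplitude = 1) {
  if (anyDuplicated(model_names)) stop("model names must be unique")
  n <- length(model_names)
  prof <- data.frame(model = as.character(model_names),
                     onset_latency = rep_len(onset_latency, n),
                     envelope_width = rep_len(envelope_width, n),
                     amplitude = rep_len(amplitude, n),
                     stringsAsFactors = FALSE)
  if (any(prof$envelope_width <= 0)) stop("envelope widths must be > 0")
  if (any(prof$amplitude < 0)) stop("amplitudes must be >= 0")
  class(prof) <- c("latency_profile", "data.frame")
  prof
}

#' Synthetic per-condition feature matrices with controlled RDM similarity
#'
#' Stand-in for network activations: one `n_conditions x latent_dim` matrix
#' per model, constructed so that the RDMs derived from any two models (via
#' [rdm_from_features()]) have lower-triangle vectors whose Pearson
#' correlation is close to `cross_model_similarity`.
#'
#' Each model places the conditions at latent positions in a low-dimensional
#' geometry space (`geometry_rank` dimensions), mixing a shared configuration
#' with a private one: `Z_k = a * Z_shared + b * Z_k_private` with
#' `a^2 + b^2 = 1`. Features are a random linear readout of the latent
#' positions plus independent feature noise, so correlation-distance RDMs
#' inherit the latent geometry: structured, with dissimilarities spanning a
#' wide range (as for real network activations) rather than clustering near
#' 1. Because the shared latent component enters every model's pairwise
#' structure quadratically, the RDM-vector correlation between two models is
#' approximately `a^4`, so `a = similarity^(1/4)` targets it. Negative
#' targets use a deflation construction (subtracting a multiple of the mean
#' private configuration), feasible down to `-1/(n_models - 1)`.
#'
#' @param n_conditions number of conditions (>= 3).
#' @param model_names character vector of model names.
#' @param latent_dim feature dimensionality (>= 2; larger values tighten the
#'   match to the target similarity).
#' @param cross_model_similarity target pairwise RDM correlation in
#'   (-1/(K-1), 0.99\].
#' @param geometry_rank dimensionality of the latent condition geometry.
#' @param feature_noise_sd SD of the independent per-feature noise added on
#'   top of the latent readout.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return named list of `n_conditions x latent_dim` matrices with condition
#'   row names.
#' @export
generate_features <- function(n_conditions, model_names, latent_dim = 128,
                              cross_model_similarity = 0,
                              geometry_rank = 4L, feature_noise_sd = 0.5,
                              seed = 1L) {
  stopifnot(n_conditions >= 3, latent_dim >= 2, geometry_rank >= 1)
  rho <- cross_model_similarity
  if (!is.finite(rho)) stop("cross_model_similarity must be finite")
  if (rho > 0.99) stop("cross_model_similarity > 0.99 is infeasible")
  k <- length(model_names)
  if (anyDuplicated(model_names)) stop("model names must be unique")
  if (k > 1 && rho < 0 && rho <= -1 / (k - 1) + 1e-9)
    stop("pairwise similarity below -1/(n_models - 1) is infeasible")
  ids <- default_condition_ids(n_conditions)
  set.seed(as.integer(seed))
  r <- as.integer(geometry_rank)
  shared <- matrix(rnorm(n_conditions * r), n_conditions)
  private <- lapply(seq_len(k), function(i)
    matrix(rnorm(n_conditions * r), n_conditions))
  lat <- vector("list", k)
  if (rho >= 0) {
    a <- rho^0.25
    b <- sqrt(1 - sqrt(rho))
    for (i in seq_len(k)) lat[[i]] <- a * shared + b * private[[i]]
  } else {
    # a negative RDM correlation cannot be inherited from latent positions
    # (pairwise structure is an even function of them), so it is built in
    # the dissimilarity domain: each model's cosine-similarity structure is
    # mixed with shared perturbations weighted by simplex-vertex coordinates
    # (pairwise inner product -1/(k-1)), then realized via a Cholesky readout
    return(negative_similarity_features(n_conditions, model_names,
                                        latent_dim, rho, private, ids))
  }
  out <- lapply(seq_len(k), function(i) {
    readout <- matrix(rnorm(r * latent_dim), r, latent_dim)
    m <- lat[[i]] %*% readout +
      feature_noise_sd * matrix(rnorm(n_conditions * latent_dim), n_conditions)
    rownames(m) <- ids
    m
  })
  names(out) <- model_names
  out
}

cosine_matrix <- function(z) {
  zn <- z / sqrt(rowSums(z^2))
  tcrossprod(zn)
}

# clip eigenvalues to keep a perturbed correlation matrix positive definite,
# then restore the unit diagonal
psd_correlation <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, 1e-4)
  m2 <- e$vectors %*% (vals * t(e$vectors))
  stats::cov2cor(m2)
}

# k unit vectors in (k-1) dims with pairwise inner product -1/(k-1)
simplex_vertices <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  v <- diag(k) - 1 / k
  e <- eigen(v, symmetric = TRUE)
  e$vectors[, seq_len(k - 1), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k - 1)]), k - 1) * sqrt(k / (k - 1))
}

negative_similarity_features <- function(n_conditions, model_names,
                                         latent_dim, rho, private, ids) {
  k <- length(model_names)
  n <- n_conditions
  own <- lapply(private, cosine_matrix)
  n_dirs <- max(k - 1, 1)
  # full-rank symmetric perturbations: their spectral radius (~2 sd sqrt(n))
  # bounds how much anti-shared structure fits in a positive-definite
  # correlation matrix, so the overall structure scale is set to that limit
  shared <- lapply(seq_len(n_dirs), function(j) {
    m <- matrix(rnorm(n * n), n)
    m <- (m + t(m)) / sqrt(2)
    diag(m) <- 0
    m
  })
  vmat <- simplex_vertices(k)
  frac <- min(1, -rho * (k - 1))        # anti-shared share of the variance
  v_own <- mean(vectorize_lower(own[[1]])^2)
  # total off-diagonal structure sd x, split (1-frac) own / frac shared,
  # sized so the shared part's spectral radius stays below 0.85
  x <- 0.85 / (2 * sqrt(n) * max(sqrt(frac), 0.3))
  build <- function(xx) {
    b <- xx * sqrt((1 - frac) / max(v_own, 1e-12))
    cc <- xx * sqrt(frac)
    lapply(seq_len(k), function(i) {
      pert <- Reduce(`+`, lapply(seq_len(n_dirs), function(j)
        vmat[i, j] * shared[[j]]))
      psd_correlation(diag(n) + b * (own[[i]] - diag(n)) + cc * pert)
    })
  }
  realized <- function(cs) {
    vs <- lapply(cs, vectorize_lower)
    pr <- utils::combn(k, 2)
    mean(apply(pr, 2, function(ij) stats::cor(vs[[ij[1]]], vs[[ij[2]]])))
  }
  cs <- build(x)
  # compensate the attenuation from realizing the structure with latent_dim
  # feature samples: observed corr ~ structure corr * V/(V + 1/latent_dim)
  v_emp <- mean(vapply(cs, function(m) stats::var(vectorize_lower(m)),
                       numeric(1)))
  atten <- v_emp / (v_emp + 1 / latent_dim)
  r1 <- realized(cs) * atten
  if (k > 1 && r1 < -1e-6 && abs(r1 - rho) > 0.02) {
    # one deterministic recalibration of the shared fraction
    adj <- sqrt(max(0.2, min(5, rho / r1)))
    frac <- min(1, frac * adj^2)
    cs <- build(x)
  }
  out <- lapply(seq_len(k), function(i) {
    m <- t(chol(cs[[i]])) %*% matrix(rnorm(n * latent_dim), n)
    rownames(m) <- ids
    m
  })
  names(out) <- model_names
  out
}

gaussian_envelope <- function(times, center, width) {
  exp(-0.5 * ((times - center) / width)^2)
}

# embed an RDM's geometry as per-condition channel patterns:
# classical MDS of the dissimilarities, mixed to channels by a seeded random
# linear map, then scaled so the root-mean-square pairwise channel-pattern
# distance is 1 -- the profile amplitude is therefore the typical separation
# between two conditions' patterns in noise-SD units at the envelope peak
rdm_to_patterns <- function(r, n_channels, max_dim = 10L) {
  m <- unclass(as.matrix(r))
  diag(m) <- 0
  n <- nrow(m)
  q <- min(n - 1L, max_dim)
  emb <- suppressWarnings(stats::cmdscale(m, k = q))
  emb <- as.matrix(emb)
  keep <- apply(emb, 2, function(col) sd(col) > 1e-12)
  emb <- emb[, keep, drop = FALSE]
  if (ncol(emb) == 0) emb <- matrix(0, n, 1)
  mix <- matrix(rnorm(ncol(emb) * n_channels), ncol(emb), n_channels)
  pat <- emb %*% mix
  pd <- stats::dist(pat)
  rms_sep <- sqrt(mean(pd^2))
  if (rms_sep > 0) pat <- pat / rms_sep
  pat
}

#' Synthetic epochs with representational structure injected at latencies
#'
#' Builds an [epoch_set] in which each model's RDM geometry appears as
#' per-condition channel patterns (classical multidimensional-scaling
#' embedding of the RDM, mapped to channels by a seed-fixed random mixing),
#' modulated by a Gaussian temporal envelope centered at the model's onset
#' latency, and added to independent Gaussian sensor noise. Trials of the
#' same condition share the pattern and differ only in noise.
#'
#' @param model_rdms named list of `rdm` objects over one condition set.
#' @param profile a [latency_profile()]; its model names must be a subset of
#'   `names(model_rdms)` and its latencies must lie inside `range(times)`.
#' @param n_trials_per_condition trials per condition (>= 2).
#' @param n_channels number of channels.
#' @param times strictly increasing, uniformly spaced time axis (seconds).
#' @param noise_sd SD of the additive Gaussian noise.
#' @param ar1 lag-1 autocorrelation of the noise along time (0 = white,
#'   the default).
#' @param channel_names optional channel names (default `ch01`, ...).
#' @param seed integer seed.
#' @return an `epoch_set` with trials ordered by condition.
#' @export
generate_epochs <- function(model_rdms, profile, n_trials_per_condition,
                            n_channels, times, noise_sd = 1, ar1 = 0,
                            channel_names = NULL, seed = 1L) {
  if (inherits(model_rdms, "rdm")) model_rdms <- list(model = model_rdms)
  stopifnot(inherits(profile, "latency_profile"))
  if (n_trials_per_condition < 2)
    stop("n_trials_per_condition must be at least 2")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(profile$model %in% names(model_rdms)))
    stop("profile names must be a subset of model_rdms names")
  if (any(profile$onset_latency < min(times) | profile$onset_latency > max(times)))
    stop("onset latencies must lie within the epoch window")
  ids <- condition_ids(model_rdms[[1]])
  for (r in model_rdms) {
    if (!identical(condition_ids(r), ids))
      stop("all model RDMs must share one condition set")
  }
  n_cond <- length(ids)
  nt <- length(times)
  n_trials <- n_cond * n_trials_per_condition
  set.seed(as.integer(seed))
  patterns <- lapply(profile$model, function(nm)
    rdm_to_patterns(model_rdms[[nm]], n_channels))
  # signal[cond, ch, t] = sum_m amp_m * env_m(t) * P_m[cond, ch]
  signal <- array(0, dim = c(n_cond, n_channels, nt))
  for (i in seq_len(nrow(profile))) {
    env <- profile$amplitude[i] *
      gaussian_envelope(times, profile$onset_latency[i],
                        profile$envelope_width[i])
    signal <- signal + outer(patterns[[i]], env)
  }
  noise <- array(rnorm(n_trials * n_channels * nt, sd = noise_sd),
                 dim = c(n_trials, n_channels, nt))
  if (ar1 > 0) {
    scale <- sqrt(1 - ar1^2)
    for (tt in 2:nt)
      noise[, , tt] <- ar1 * noise[, , tt - 1] + scale * noise[, , tt]
  }
  cond_of_trial <- rep(seq_len(n_cond), each = n_trials_per_condition)
  data <- noise + signal[cond_of_trial, , , drop = FALSE]
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(n_channels))
  epoch_set(data, ids[cond_of_trial], channel_names, times)
}

#' Synthetic path-drawing heatmaps
#'
#' Emulates aggregated exit-path drawings: for each condition, a grid in
#' which each path is a connected pixel trace starting at the bottom-center
#' pixel and heading outward at a random angle (with small angular jitter
#' along the way). Pixel values count how many paths covered the pixel.
#'
#' @param n_conditions number of images; 0 gives an empty list.
#' @param paths_per_image length-2 integer range `(min, max)`, min >= 1.
#' @param image_size `(width, height)` in pixels, both >= 8.
#' @param angle_range `(low, high)` degrees from which each path's heading is
#'   drawn (0 = rightward, 90 = straight up).
#' @param angle_jitter SD (radians) of the per-step heading jitter; 0 gives
#'   perfectly straight paths.
#' @param seed integer seed.
#' @return list of `height x width` non-negative matrices.
#' @export
generate_heatmaps <- function(n_conditions, paths_per_image = c(2L, 5L),
                              image_size = c(64L, 48L),
                              angle_range = c(25, 155), angle_jitter = 0.02,
                              seed = 1L) {
  if (any(image_size < 8)) stop("image_size must be at least (8, 8)")
  if (min(paths_per_image) < 1) stop("paths_per_image minimum must be >= 1")
  if (n_conditions == 0) return(list())
  w <- as.integer(image_size[1]); h <- as.integer(image_size[2])
  origin <- c(row = h, col = floor(w / 2) + 1L)  # bottom-center pixel
  set.seed(as.integer(seed))
  lapply(seq_len(n_conditions), function(i) {
    grid <- matrix(0, h, w)
    n_paths <- if (paths_per_image[1] == paths_per_image[2]) paths_per_image[1]
               else sample(paths_per_image[1]:paths_per_image[2], 1)
    for (p in seq_len(n_paths)) {
      theta <- runif(1, angle_range[1], angle_range[2]) * pi / 180
      len <- runif(1, 0.4, 0.95) * (h - 1)
      covered <- matrix(FALSE, h, w)
      pos <- unname(c(origin["row"], origin["col"]))
      travelled <- 0
      while (travelled < len) {
        ri <- round(pos[1]); ci <- round(pos[2])
        if (ri < 1 || ci < 1 || ci > w) break
        covered[ri, ci] <- TRUE
        if (angle_jitter > 0) theta <- theta + rnorm(1, 0, angle_jitter)
        pos <- pos + 0.5 * c(-sin(theta), cos(theta))
        travelled <- travelled + 0.5
      }
      grid <- grid + covered
    }
    grid
  })
}

#' Block/run trial schedule
#'
#' Generates the presentation schedule: each run presents a fixed multiset of
#' block lengths in random order, blocks are separated by catch-trial
#' markers, and condition assignments are balanced so every condition is
#' repeated equally often across the experiment (required when the total
#' trial count is divisible by `n_conditions`).
#'
#' @param block_composition named integer vector mapping block length to
#'   block count, e.g. `c("5" = 24, "4" = 15, "3" = 15, "2" = 10, "1" = 5)`;
#'   see [default_block_composition].
#' @param n_runs number of runs.
#' @param n_conditions number of conditions (>= 1).
#' @param seed integer seed.
#' @param balance require equal repetitions per condition (default `TRUE`).
#' @return object of class `trial_schedule`: list of runs, each a list with
#'   `blocks` (list of condition-index vectors) and `catch_after` (logical
#'   per block).
#' @export
generate_schedule <- function(block_composition = default_block_composition,
                              n_runs = 15L, n_conditions = 50L, seed = 1L,
                              balance = TRUE) {
  stopifnot(n_conditions >= 1)
  lens <- as.integer(names(block_composition))
  counts <- as.integer(block_composition)
  if (any(lens < 1) || any(counts < 0)) stop("invalid block composition")
  per_run <- sum(lens * counts)
  total <- per_run * n_runs
  if (balance && total %% n_conditions != 0)
    stop("total trial count (", total, ") is not divisible by n_conditions (",
         n_conditions, "); balanced assignment is impossible")
  set.seed(as.integer(seed))
  pool <- if (balance) {
    sample(rep(seq_len(n_conditions), each = total %/% n_conditions))
  } else {
    sample(seq_len(n_conditions), total, replace = TRUE)
  }
  pos <- 0L
  runs <- lapply(seq_len(n_runs), function(r) {
    order_lens <- sample(rep(lens, counts))
    blocks <- lapply(order_lens, function(L) {
      idx <- (pos + 1L):(pos + L)
      pos <<- pos + L
      pool[idx]
    })
    list(blocks = blocks, catch_after = rep(TRUE, length(blocks)))
  })
  structure(list(runs = runs, n_conditions = as.integer(n_conditions),
                 block_composition = stats::setNames(counts, lens)),
            class = "trial_schedule")
}

#' Run/block composition of the reference paradigm
#'
#' 69 blocks per run: 24 blocks of 5 trials, 15 of 4, 15 of 3, 10 of 2 and
#' 5 of 1 (250 trials per run; 15 runs over 50 conditions give 75
#' repetitions per condition).
#' @export
default_block_composition <- c("5" = 24L, "4" = 15L, "3" = 15L, "2" = 10L,
                               "1" = 5L)

#' Summarize a trial schedule
#'
#' @param schedule a `trial_schedule`.
#' @return list with `blocks_per_run`, `trials_per_run`, and
#'   `repetitions_per_condition` (a table).
#' @export
schedule_summary <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  bpr <- vapply(schedule$runs, function(r) length(r$blocks), integer(1))
  trials <- unlist(lapply(schedule$runs, function(r) unlist(r$blocks)))
  list(blocks_per_run = bpr,
       trials_per_run = vapply(schedule$runs,
                               function(r) length(unlist(r$blocks)), integer(1)),
       repetitions_per_condition = table(factor(trials,
                                                levels = seq_len(schedule$n_conditions))))
}

#' @export
print.trial_schedule <- function(x, ...) {
  s <- schedule_summary(x)
  cat(sprintf("<trial_schedule> %d runs, %d blocks/run, %d trials/run, %d conditions\n",
              length(x$runs), s$blocks_per_run[1], s$trials_per_run[1],
              x$n_conditions))
  invisible(x)
}
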