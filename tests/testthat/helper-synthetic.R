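# shared fixtures built in code

# small epoch set with raw Gaussian noise (no structure)
noise_epochs <- function(n_cond = 2, n_trials = 10, n_ch = 4, n_t = 20,
                         seed = 1, rate = 100) {
  set.seed(seed)
  n <- n_cond * n_trials
  epoch_set(array(rnorm(n * n_ch * n_t), c(n, n_ch, n_t)),
            rep(sprintf("c%02d", seq_len(n_cond)), each = n_trials),
            sprintf("ch%02d", seq_len(n_ch)),
            seq(0, by = 1 / rate, length.out = n_t))
}

# random valid distance RDM (symmetric, zero diagonal, positive off-diagonal)
random_rdm <- function(n, seed = 1) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 3), n)
  rdm(unname(as.matrix(dist(pts))))
}

# participant x time curves: Gaussian bump at a given latency plus noise
bump_curves <- function(n_part, times, latency, width = 0.04, snr = 10,
                        seed = 1) {
  set.seed(seed)
  bump <- exp(-0.5 * ((times - latency) / width)^2)
  t(replicate(n_part, bump + rnorm(length(times), sd = 1 / snr)))
}

# independent all-subsets R^2 oracle: plain normal equations on centered data
oracle_r2 <- function(y, X) {
  y <- y - mean(y)
  if (NCOL(X) == 0 || is.null(X)) return(0)
  X <- scale(X, center = TRUE, scale = FALSE)
  b <- solve(crossprod(X), crossprod(X, y))
  1 - sum((y - X %*% b)^2) / sum(y^2)
}
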