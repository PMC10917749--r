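#' Time-resolved pairwise decoding
#'
#' For every unordered condition pair and every time point, trains a Fisher
#' linear discriminant on the channel vectors at that single time point and
#' estimates cross-validated accuracy, yielding one decoding RDM per time
#' point. The diagonal of each RDM is `NA` (self-decoding is undefined) and
#' is excluded from all downstream vectorization.
#'
#' Cross-validation is leave-one-trial-out by default (`n_folds = "loo"`):
#' each fold trains on all-but-one trials of the pair and tests the left-out
#' trial, which makes the result invariant to trial ordering. `"paired"`
#' leaves one trial of *each* condition out per fold (class-balanced folds,
#' but tied to the within-condition trial order), and an integer `n_folds`
#' requests stratified k-fold (trial-to-fold assignment drawn from `seed`).
#' The pooled within-class covariance can be shrunk
#' toward a scaled identity; `"auto"` selects the analytic
#' (Ledoit-Wolf) intensity per fold, which keeps the discriminant stable when
#' trials are few relative to channels. Decision-boundary ties are broken
#' toward the lower condition index.
#'
#' @param epochs an [epoch_set]; every condition needs >= 2 trials.
#' @param n_folds `"loo"` (default), `"paired"`, or an integer number of
#'   folds >= 2.
#' @param regularization shrinkage in \[0, 1\], or `"auto"`.
#' @param seed integer seed (used only for k-fold assignment).
#' @return an [rdm_series] of decoding-accuracy RDMs (values in \[0, 1\]).
#' @export
pairwise_decode <- function(epochs, n_folds = "loo", regularization = "auto",
                            seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  conds <- sort(unique(epochs$conditions))
  if (length(conds) < 2) stop("pairwise decoding needs at least 2 conditions")
  cond_idx <- match(epochs$conditions, conds) - 1L
  n_trials <- dim(epochs$data)[1]
  if (identical(n_folds, "loo")) {
    fold_id <- seq_len(n_trials)
  } else if (identical(n_folds, "paired")) {
    fold_id <- integer(n_trials)
    for (ci in unique(cond_idx)) {
      idx <- which(cond_idx == ci)
      fold_id[idx] <- seq_along(idx)
    }
  } else {
    n_folds <- suppressWarnings(as.integer(n_folds))
    if (is.na(n_folds) || n_folds < 2)
      stop("n_folds must be \"loo\", \"paired\", or an integer >= 2")
    set.seed(as.integer(seed))
    fold_id <- integer(n_trials)
    for (ci in unique(cond_idx)) {
      idx <- which(cond_idx == ci)
      fold_id[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  }
  gamma <- if (identical(regularization, "auto")) -1 else {
    g <- as.numeric(regularization)
    if (is.na(g) || g < 0 || g > 1)
      stop("regularization must be in [0, 1] or \"auto\"")
    g
  }
  acc <- pairwise_decode_cpp(epochs$data, as.integer(cond_idx),
                             as.integer(fold_id), length(conds), gamma)
  rdm_series(acc, epochs$times, conds)
}

#' Grand-average decoding timecourse
#'
#' Mean of the off-diagonal upper-triangle accuracies at each time point.
#'
#' @param series an [rdm_series] of decoding RDMs.
#' @return data.frame with columns `time` and `accuracy`.
#' @export
grand_average <- function(series) {
  stopifnot(inherits(series, "rdm_series"))
  if (length(series$times) == 0) stop("empty RDM series")
  ut <- upper.tri(series$values[, , 1])
  acc <- apply(series$values, 3, function(m) mean(m[ut]))
  data.frame(time = series$times, accuracy = acc)
}
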