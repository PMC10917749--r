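#' Coefficient of determination of an OLS fit
#'
#' R-squared of ordinary least squares with intercept, with target and
#' predictors z-scored internally (R-squared is invariant to this; it aids
#' conditioning). An empty predictor list gives 0. Collinear predictors are
#' handled by pivoted least squares (the projection onto the column space is
#' unique, so R-squared is well defined) with a warning.
#'
#' @param target numeric vector (e.g. a vectorized RDM).
#' @param predictors list of numeric vectors of the same length, possibly
#'   empty; a matrix is taken column-wise.
#' @return R-squared in \[0, 1\].
#' @export
fit_r2 <- function(target, predictors = list()) {
  if (is.matrix(predictors))
    predictors <- lapply(seq_len(ncol(predictors)), function(j) predictors[, j])
  if (length(predictors) == 0) return(0)
  n <- length(target)
  if (any(vapply(predictors, length, 1L) != n))
    stop("all vectors must have the same length")
  if (n < length(predictors) + 2)
    stop("need at least n_predictors + 2 observations")
  X <- vapply(predictors, zscore, numeric(n))
  y <- zscore(target)
  qr_r2(qr(cbind(1, X)), y, warn_collinear = TRUE)
}

zscore <- function(v) {
  s <- sd(v)
  if (s == 0) return(v - mean(v))
  (v - mean(v)) / s
}

# R^2 from a precomputed QR of the design (first column = intercept)
qr_r2 <- function(qx, y, warn_collinear = FALSE) {
  if (warn_collinear && qx$rank < ncol(qx$qr))
    warning("collinear predictors; using pivoted least squares")
  res <- qr.resid(qx, y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  max(0, min(1, 1 - sum(res^2) / tss))
}

#' Unique-variance timecourses by nested regression
#'
#' At every time point the neural RDM's lower-triangle vector is regressed
#' on the member RDM vectors of all model groups jointly (R2_all), then on
#' all-but-one group for each group (R2_reduced). The unique variance of a
#' group is the difference `R2_all - R2_reduced`, which is non-negative by
#' the nestedness of ordinary least squares. Each group contributes its
#' member RDMs as separate regressors (not their average).
#'
#' @param eeg an [rdm_series] of neural (decoding) RDMs.
#' @param groups list of [model_group]s with unique names, all sharing the
#'   neural condition set.
#' @param participant_id optional label stored with the result.
#' @return object of class `varpart_result`: list with `times`, `r2_all`
#'   (vector), `r2_reduced` and `unique` (matrices `group x time`), and
#'   `participant_id`.
#' @export
unique_variance_timecourse <- function(eeg, groups, participant_id = NA_character_) {
  stopifnot(inherits(eeg, "rdm_series"))
  if (inherits(groups, "model_group")) groups <- list(groups)
  g_names <- vapply(groups, function(g) g$name, character(1))
  if (anyDuplicated(g_names)) stop("group names must be unique")
  for (g in groups) {
    if (!identical(g$condition_ids, eeg$condition_ids))
      stop("group '", g$name, "' does not share the neural condition set")
  }
  preds <- lapply(groups, function(g)
    vapply(g$rdms, function(r) zscore(vectorize_lower(r)),
           numeric(length(vectorize_lower(g$rdms[[1]])))))
  X_all <- do.call(cbind, preds)
  n <- nrow(X_all)
  if (n < ncol(X_all) + 2)
    stop("too few condition pairs for the number of predictors")
  memb <- rep(seq_along(groups), vapply(preds, ncol, 1L))
  qr_all <- qr(cbind(1, X_all))
  qr_red <- lapply(seq_along(groups), function(k)
    qr(cbind(1, X_all[, memb != k, drop = FALSE])))
  nt <- length(eeg$times)
  r2_all <- numeric(nt)
  r2_reduced <- matrix(0, length(groups), nt,
                       dimnames = list(g_names, NULL))
  for (t in seq_len(nt)) {
    y <- zscore(vectorize_lower(eeg$values[, , t]))
    r2_all[t] <- qr_r2(qr_all, y)
    for (k in seq_along(groups)) r2_reduced[k, t] <- qr_r2(qr_red[[k]], y)
  }
  uniq <- sweep(-r2_reduced, 2, r2_all, `+`)
  if (any(uniq < -1e-10))
    stop("negative unique variance encountered; nested OLS violated")
  structure(list(times = eeg$times, r2_all = r2_all,
                 r2_reduced = r2_reduced, unique = uniq,
                 participant_id = participant_id),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat(sprintf("<varpart_result> %s: %d groups x %d time points, max R2_all = %.4f\n",
              x$participant_id, nrow(x$unique), length(x$times), max(x$r2_all)))
  for (g in rownames(x$unique)) {
    i <- which.max(x$unique[g, ])
    cat(sprintf("  %-10s peak unique R2 %.4f at %.3f s\n",
                g, x$unique[g, i], x$times[i]))
  }
  invisible(x)
}

#' Long-format table of a variance-partitioning result
#'
#' @param x a `varpart_result`.
#' @return data.frame with columns `participant`, `time`, `quantity`, `value`
#'   where quantity is `r2_all`, `r2_reduced:<group>` or `unique:<group>`.
#' @export
varpart_table <- function(x) {
  stopifnot(inherits(x, "varpart_result"))
  g <- rownames(x$unique)
  rows <- list(data.frame(participant = x$participant_id, time = x$times,
                          quantity = "r2_all", value = x$r2_all))
  for (k in seq_along(g)) {
    rows[[length(rows) + 1]] <- data.frame(
      participant = x$participant_id, time = x$times,
      quantity = paste0("r2_reduced:", g[k]), value = x$r2_reduced[k, ])
    rows[[length(rows) + 1]] <- data.frame(
      participant = x$participant_id, time = x$times,
      quantity = paste0("unique:", g[k]), value = x$unique[k, ])
  }
  do.call(rbind, rows)
}
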