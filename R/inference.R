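#' Per-timepoint one-sample tests with FDR correction
#'
#' Tests, at every time point, whether the participant curves (e.g. unique
#' variance) exceed zero with a one-sample t-test, then controls the false
#' discovery rate across time points with the Benjamini-Hochberg step-up
#' procedure at level `q`.
#'
#' @param per_participant numeric matrix `participants x timepoints` (>= 2
#'   rows).
#' @param times time axis in seconds.
#' @param tail `"greater"` (default) or `"two.sided"`.
#' @param q FDR level (default 0.05).
#' @param null_mean value tested against (default 0, matching the published
#'   convention). For unique-variance curves from nested OLS the exact null
#'   expectation is `p_group / (n_pairs - 1)` -- non-zero because an R-squared
#'   difference over nested models is non-negative by construction -- and
#'   passing that value tests for structure beyond the regression's
#'   chance-level gain. See [null_unique_mean()].
#' @return object of class `timecourse_stats`: list with `times`, `p_values`,
#'   `p_adjusted`, `significant`.
#' @export
timepoint_tests <- function(per_participant, times, tail = "greater",
                            q = 0.05, null_mean = 0) {
  tail <- match.arg(tail, c("greater", "two.sided"))
  per_participant <- as.matrix(per_participant)
  n <- nrow(per_participant)
  if (n < 2) stop("at least 2 participants are required")
  if (ncol(per_participant) != length(times)) stop("time axis mismatch")
  mu <- colMeans(per_participant) - null_mean
  s <- apply(per_participant, 2, sd)
  p <- numeric(length(times))
  degenerate <- s == 0
  if (any(degenerate)) {
    warning("zero variance across participants at ", sum(degenerate),
            " time point(s); p set to 0 (mean > 0) or 1")
    p[degenerate] <- ifelse(mu[degenerate] > 0, 0, 1)
  }
  ok <- !degenerate
  tstat <- mu[ok] / (s[ok] / sqrt(n))
  p[ok] <- if (tail == "greater") stats::pt(tstat, n - 1, lower.tail = FALSE)
           else 2 * stats::pt(abs(tstat), n - 1, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  structure(list(times = times, p_values = p, p_adjusted = padj,
                 significant = fdr_significant(p, q), q = q),
            class = "timecourse_stats")
}

#' Benjamini-Hochberg rejection mask
#'
#' Step-up FDR control: with `m` p-values sorted ascending, reject all
#' hypotheses up to the largest `i` with `p_(i) <= i q / m`.
#'
#' @param p vector of p-values.
#' @param q FDR level.
#' @return logical vector, `TRUE` for rejected (significant) entries.
#' @export
fdr_significant <- function(p, q = 0.05) {
  stats::p.adjust(p, method = "BH") <= q
}

#' @export
print.timecourse_stats <- function(x, ...) {
  sig <- which(x$significant)
  cat(sprintf("<timecourse_stats> %d/%d time points significant (BH, q = %g)%s\n",
              length(sig), length(x$times), x$q,
              if (length(sig)) sprintf(", %.3f..%.3f s",
                                       min(x$times[sig]), max(x$times[sig]))
              else ""))
  invisible(x)
}

#' Null expectation of a group's unique variance
#'
#' For a target independent of the predictors, OLS R-squared with `p`
#' regressors and an intercept on `n` observations follows a
#' Beta(p/2, (n-1-p)/2) distribution with mean `p/(n-1)`; the expected
#' R-squared difference from adding a group's `p_group` regressors is
#' therefore `p_group/(n-1)` regardless of the other predictors. Useful as
#' the `null_mean` of [timepoint_tests()] when screening unique-variance
#' curves for structure beyond this chance-level gain.
#'
#' @param n_pairs number of condition pairs (regression observations).
#' @param p_group number of member RDMs the group contributes.
#' @return expected null unique variance.
#' @export
null_unique_mean <- function(n_pairs, p_group) {
  p_group / (n_pairs - 1)
}

#' Peak latency of a timecourse
#'
#' Time of the maximum within a search window; ties are broken toward the
#' earliest time.
#'
#' @param curve numeric vector.
#' @param times time axis in seconds.
#' @param search_window `(t0, t1)` in seconds, half-open like all windows;
#'   default covers the whole axis.
#' @return latency in seconds.
#' @export
peak_latency <- function(curve, times, search_window = NULL) {
  stopifnot(length(curve) == length(times))
  if (is.null(search_window))
    idx <- seq_along(times)
  else
    idx <- window_index(times, search_window)
  if (length(idx) == 0) stop("search window contains no time points")
  times[idx][which.max(curve[idx])]
}

#' Bootstrap peak latency with confidence interval
#'
#' Resamples participants with replacement `n_boot` times; each iteration
#' recomputes the peak latency, either of the resampled participants' average
#' curve (`"peak_of_average"`, default) or as the average of the resampled
#' participants' own peaks (`"average_of_peaks"`). The 95% interval is the
#' 2.5/97.5 percentile of the bootstrap latencies. The resample indices are
#' derived from `seed` alone, so results built from the same seed and cohort
#' size are paired and comparable with [compare_peaks()].
#'
#' @param per_participant matrix `participants x timepoints` (>= 2 rows).
#' @param times time axis in seconds.
#' @param n_boot bootstrap iterations (default 1000; < 100 warns).
#' @param seed integer seed.
#' @param mode `"peak_of_average"` or `"average_of_peaks"`.
#' @param search_window optional `(t0, t1)` restriction for the peak.
#' @param group_name label stored with the result.
#' @return object of class `peak_latency_result`: `peak_latency` (of the full
#'   cohort's average curve), `ci95`, `bootstrap_latencies`, `boot_sd`,
#'   `mean_participant_peak`, `mode`, `n_boot`, `seed`.
#' @export
bootstrap_peaks <- function(per_participant, times, n_boot = 1000L,
                            seed = 1L, mode = "peak_of_average",
                            search_window = NULL, group_name = NA_character_) {
  mode <- match.arg(mode, c("peak_of_average", "average_of_peaks"))
  per_participant <- as.matrix(per_participant)
  n <- nrow(per_participant)
  if (n < 2) stop("at least 2 participants are required")
  if (n_boot < 100) warning("n_boot < 100 gives unstable confidence intervals")
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  part_peaks <- apply(per_participant, 1, peak_latency, times = times,
                      search_window = search_window)
  lat <- if (mode == "peak_of_average") {
    apply(idx, 1, function(i)
      peak_latency(colMeans(per_participant[i, , drop = FALSE]), times,
                   search_window))
  } else {
    rowMeans(matrix(part_peaks[t(idx)], ncol = n, byrow = TRUE))
  }
  est <- if (mode == "peak_of_average")
    peak_latency(colMeans(per_participant), times, search_window)
  else mean(part_peaks)
  ci <- unname(stats::quantile(lat, c(0.025, 0.975)))
  structure(list(group_name = group_name, peak_latency = est, ci95 = ci,
                 bootstrap_latencies = lat, boot_sd = sd(lat),
                 mean_participant_peak = mean(part_peaks), mode = mode,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 n_participants = n, resample_idx = idx),
            class = "peak_latency_result")
}

#' @export
print.peak_latency_result <- function(x, ...) {
  cat(sprintf("<peak_latency_result> %s: peak %.2f ms, 95%% CI [%.2f, %.2f] ms (%s, %d boots)\n",
              x$group_name, 1000 * x$peak_latency, 1000 * x$ci95[1],
              1000 * x$ci95[2], x$mode, x$n_boot))
  invisible(x)
}

#' Paired bootstrap comparison of two peak latencies
#'
#' Requires both results to be built from the same participant resamples
#' (same seed, cohort size and iteration count). The two-sided p-value uses
#' the per-iteration latency differences with a +1 continuity correction:
#' `p = 2 * min(P(diff <= 0), P(diff >= 0))`, capped at 1.
#'
#' @param a,b `peak_latency_result`s from the same cohort and seed.
#' @return p-value.
#' @export
compare_peaks <- function(a, b) {
  stopifnot(inherits(a, "peak_latency_result"),
            inherits(b, "peak_latency_result"))
  if (!identical(a$resample_idx, b$resample_idx))
    stop("peak results are not paired: build both with the same seed, ",
         "n_boot and participant cohort")
  d <- a$bootstrap_latencies - b$bootstrap_latencies
  B <- length(d)
  p <- 2 * min((1 + sum(d <= 0)) / (B + 1), (1 + sum(d >= 0)) / (B + 1))
  min(1, p)
}

#' All pairwise peak comparisons with FDR correction
#'
#' Applies [compare_peaks()] to every unordered pair of results and corrects
#' the p-values across pairs with Benjamini-Hochberg.
#'
#' @param results named list of paired `peak_latency_result`s.
#' @return data.frame with columns `a`, `b`, `p`, `p_adjusted`.
#' @export
compare_all_peaks <- function(results) {
  stopifnot(length(results) >= 2)
  nms <- vapply(results, function(r) r$group_name, character(1))
  pairs <- utils::combn(seq_along(results), 2)
  p <- apply(pairs, 2, function(ij)
    compare_peaks(results[[ij[1]]], results[[ij[2]]]))
  data.frame(a = nms[pairs[1, ]], b = nms[pairs[2, ]], p = p,
             p_adjusted = stats::p.adjust(p, method = "BH"))
}
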