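#' Epoched multi-channel recording
#'
#' Container for per-trial peri-stimulus segments: a numeric array
#' `trials x channels x timepoints` with a condition label per trial, unique
#' channel names, and a strictly increasing, uniformly spaced time axis in
#' seconds relative to stimulus onset.
#'
#' @param data numeric array `trials x channels x timepoints`.
#' @param conditions character/factor vector, one label per trial; every
#'   condition must have at least 2 trials.
#' @param channels character vector of unique channel names.
#' @param times numeric vector of sample times in seconds.
#' @param sampling_rate sampling rate in Hz; inferred from `times` if `NULL`.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, conditions, channels, times, sampling_rate = NULL) {
  stopifnot(length(dim(data)) == 3L)
  conditions <- as.character(conditions)
  if (dim(data)[1] != length(conditions))
    stop("one condition label per trial is required")
  if (dim(data)[2] != length(channels)) stop("channel count mismatch")
  if (dim(data)[3] != length(times)) stop("time axis length mismatch")
  if (anyDuplicated(channels)) stop("channel names must be unique")
  dt <- diff(times)
  if (length(times) > 1) {
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-9)
      stop("times must be uniformly spaced to within 1e-9 s")
  }
  tab <- table(conditions)
  if (any(tab < 2)) stop("every condition needs at least 2 trials")
  if (is.null(sampling_rate))
    sampling_rate <- if (length(times) > 1) 1 / stats::median(dt) else NA_real_
  structure(list(data = data, conditions = conditions,
                 channels = as.character(channels),
                 times = as.numeric(times),
                 sampling_rate = sampling_rate),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d trials (%d conditions) x %d channels x %d samples @ %g Hz, %.3f..%.3f s\n",
    dim(x$data)[1], length(unique(x$conditions)), dim(x$data)[2],
    dim(x$data)[3], x$sampling_rate, min(x$times), max(x$times)))
  invisible(x)
}

#' The 17 posterior/occipital channels of the 10-10 system
#'
#' Default channel selection for visually driven analyses.
#' @export
posterior_channels <- c("O1", "Oz", "O2", "PO7", "PO3", "POz", "PO4", "PO8",
                        "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8")

# indices of samples with t0 <= t < t1 (half-open window convention)
window_index <- function(times, window) {
  stopifnot(length(window) == 2)
  if (!(window[1] < window[2])) stop("window must satisfy t0 < t1")
  which(times >= window[1] - 1e-12 & times < window[2] - 1e-12)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean signal over the baseline window
#' (half-open `[t0, t1)`). The default window is the full pre-stimulus
#' interval.
#'
#' @param epochs an `epoch_set`.
#' @param baseline_window length-2 numeric `(t0, t1)` in seconds; must contain
#'   at least one sample.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs,
                             baseline_window = c(min(epochs$times), 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- window_index(epochs$times, baseline_window)
  if (length(idx) == 0) stop("baseline window contains no samples")
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(bl, dim = dim(epochs$data))
  epochs
}

#' Downsample epochs with anti-alias filtering
#'
#' Integer decimation: a zero-phase low-pass Butterworth filter (order 6,
#' cutoff 0.8 of the target Nyquist, applied forward-backward with
#' reflection padding) precedes taking every q-th sample, so the time axis is
#' preserved at the retained samples.
#'
#' @param epochs an `epoch_set`.
#' @param target_rate new sampling rate in Hz; must divide the current rate.
#' @return the downsampled `epoch_set`.
#' @export
downsample <- function(epochs, target_rate) {
  stopifnot(inherits(epochs, "epoch_set"))
  sr <- epochs$sampling_rate
  if (target_rate > sr * (1 + 1e-9))
    stop("target_rate exceeds the sampling rate")
  q <- sr / target_rate
  if (abs(q - round(q)) > 1e-6)
    stop("target_rate must divide the sampling rate (integer decimation)")
  q <- as.integer(round(q))
  if (q == 1L) return(epochs)
  keep <- seq(1L, dim(epochs$data)[3], by = q)
  bf <- signal::butter(6, 0.8 / q, type = "low")
  nt <- dim(epochs$data)[3]
  out <- array(0, dim = c(dim(epochs$data)[1:2], length(keep)))
  for (tr in seq_len(dim(epochs$data)[1])) {
    for (ch in seq_len(dim(epochs$data)[2])) {
      out[tr, ch, ] <- filtfilt_padded(bf, epochs$data[tr, ch, ])[keep]
    }
  }
  epoch_set(out, epochs$conditions, epochs$channels, epochs$times[keep],
            sampling_rate = target_rate)
}

# forward-backward filtering with odd-reflection padding at both ends
# (suppresses the startup transient of plain filtfilt on short epochs)
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * (max(length(bf$a), length(bf$b)) - 1L) * 4L)
  if (pad < 1L) return(signal::filtfilt(bf, x))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(pad + 1):(pad + n)]
}

#' Select and reorder channels
#'
#' @param epochs an `epoch_set`.
#' @param names channel names to retain, in the requested order. The exported
#'   [posterior_channels] constant gives the default posterior/occipital set.
#' @return the reduced `epoch_set`.
#' @export
select_channels <- function(epochs, names = posterior_channels) {
  stopifnot(inherits(epochs, "epoch_set"))
  unknown <- setdiff(names, epochs$channels)
  if (length(unknown) > 0)
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  idx <- match(names, epochs$channels)
  epochs$data <- epochs$data[, idx, , drop = FALSE]
  epochs$channels <- epochs$channels[idx]
  epochs
}

#' Crop epochs to a time window
#'
#' Retains samples with `t0 <= t < t1` (half-open), so a (-0.2, 0.8) window
#' at 100 Hz yields exactly 100 samples.
#'
#' @param epochs an `epoch_set`.
#' @param window length-2 numeric `(t0, t1)` in seconds.
#' @return the cropped `epoch_set`.
#' @export
crop <- function(epochs, window) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- window_index(epochs$times, window)
  if (length(idx) == 0) stop("crop window retains no samples")
  epochs$data <- epochs$data[, , idx, drop = FALSE]
  epochs$times <- epochs$times[idx]
  epochs
}
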