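#' Representational dissimilarity matrix (RDM)
#'
#' An RDM is a symmetric `n_conditions x n_conditions` matrix of pairwise
#' dissimilarities between condition-specific responses. Distance RDMs carry a
#' zero diagonal; decoding RDMs store `NA` on the diagonal because
#' self-decoding is undefined. Off-diagonal entries must be finite.
#'
#' @param values square numeric matrix, symmetric to within `1e-12`.
#' @param condition_ids character vector of condition labels (defaults to
#'   dimnames or `cond01`, `cond02`, ...).
#' @return an object of class `rdm`: the matrix with a `condition_ids`
#'   attribute.
#' @export
rdm <- function(values, condition_ids = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("RDM must be square")
  offdiag <- values[row(values) != col(values)]
  if (any(!is.finite(offdiag))) stop("off-diagonal RDM entries must be finite")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-12)
    stop("RDM must be symmetric to within 1e-12")
  if (is.null(condition_ids)) {
    condition_ids <- rownames(values)
    if (is.null(condition_ids)) condition_ids <- default_condition_ids(n)
  }
  if (length(condition_ids) != n) stop("condition_ids length must match RDM size")
  dimnames(values) <- list(condition_ids, condition_ids)
  structure(values, condition_ids = condition_ids, class = c("rdm", "matrix"))
}

default_condition_ids <- function(n) sprintf("cond%02d", seq_len(n))

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d conditions\n", nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

#' Condition labels of an RDM
#' @param x an `rdm`.
#' @return character vector of condition ids.
#' @export
condition_ids <- function(x) attr(x, "condition_ids")

#' Time-resolved RDM series
#'
#' One RDM per time point, sharing a single condition set. Stored as a
#' 3-dimensional array `n_conditions x n_conditions x n_times`.
#'
#' @param values array `n x n x n_times`, each slice a valid RDM.
#' @param times numeric vector of time points in seconds.
#' @param condition_ids condition labels shared by all slices.
#' @return object of class `rdm_series` with elements `values`, `times`,
#'   `condition_ids`.
#' @export
rdm_series <- function(values, times, condition_ids = NULL) {
  stopifnot(length(dim(values)) == 3L, dim(values)[1] == dim(values)[2])
  if (dim(values)[3] != length(times))
    stop("number of RDMs must equal length(times)")
  if (is.null(condition_ids)) condition_ids <- default_condition_ids(dim(values)[1])
  structure(list(values = values, times = as.numeric(times),
                 condition_ids = condition_ids),
            class = "rdm_series")
}

#' @export
print.rdm_series <- function(x, ...) {
  cat(sprintf("<rdm_series> %d conditions x %d time points (%.3f to %.3f s)\n",
              length(x$condition_ids), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Extract one RDM from a series
#' @param series an `rdm_series`.
#' @param i time index.
#' @return an `rdm`.
#' @export
rdm_at <- function(series, i) {
  stopifnot(inherits(series, "rdm_series"))
  rdm(series$values[, , i], series$condition_ids)
}

#' Model RDM from a feature matrix
#'
#' Each condition is a row of features (e.g. one layer's activations to that
#' stimulus); the dissimilarity of two conditions is 1 minus the Pearson
#' correlation of their feature vectors, giving values in \[0, 2\] with a zero
#' diagonal.
#'
#' @param features numeric matrix `n_conditions x d`, `d >= 2`. Row names, if
#'   present, become condition ids.
#' @param metric only `"one_minus_pearson"` is implemented.
#' @return an `rdm`.
#' @export
rdm_from_features <- function(features, metric = "one_minus_pearson") {
  metric <- match.arg(metric)
  features <- as.matrix(features)
  if (ncol(features) < 2) stop("feature matrices need at least 2 columns")
  ids <- rownames(features)
  if (is.null(ids)) ids <- default_condition_ids(nrow(features))
  vars <- apply(features, 1, stats::var)
  if (any(vars == 0))
    stop("zero-variance feature rows for condition(s): ",
         paste(ids[vars == 0], collapse = ", "))
  d <- 1 - stats::cor(t(features))
  d <- (d + t(d)) / 2          # kill rounding asymmetry
  diag(d) <- 0
  rdm(d, ids)
}

#' Named group of model RDMs
#'
#' A predictor family for variance partitioning: one named model (e.g. "2D")
#' contributing one or more member RDMs (e.g. a mid and an output layer).
#'
#' @param name group label.
#' @param rdms list of `rdm` objects sharing one condition set.
#' @return object of class `model_group`.
#' @export
model_group <- function(name, rdms) {
  if (inherits(rdms, "rdm")) rdms <- list(rdms)
  stopifnot(length(rdms) >= 1, all(vapply(rdms, inherits, TRUE, "rdm")))
  ids <- condition_ids(rdms[[1]])
  for (r in rdms) {
    if (!identical(condition_ids(r), ids))
      stop("all RDMs in group '", name, "' must share condition ids")
  }
  structure(list(name = name, rdms = rdms, condition_ids = ids),
            class = "model_group")
}

#' Elementwise mean of a group's RDMs
#'
#' Used for group-level summaries and as the pattern source when injecting a
#' group's geometry into synthetic epochs. Note that variance partitioning
#' consumes the member RDMs, not this average.
#'
#' @param group a `model_group`.
#' @return an `rdm`.
#' @export
average_rdms <- function(group) {
  stopifnot(inherits(group, "model_group"))
  acc <- Reduce(`+`, lapply(group$rdms, unclass))
  rdm(acc / length(group$rdms), group$condition_ids)
}

#' Vectorize the strictly lower triangle of an RDM
#'
#' Row-major traversal of the strictly-lower-triangle entries, i.e. (2,1),
#' (3,1), (3,2), (4,1), ... The diagonal is excluded, so decoding RDMs with an
#' `NA` diagonal vectorize cleanly. [devectorize_lower()] inverts the
#' operation exactly.
#'
#' @param x an `rdm` or square matrix.
#' @return numeric vector of length `n(n-1)/2`.
#' @export
vectorize_lower <- function(x) {
  m <- unclass(as.matrix(x))
  t(m)[upper.tri(m)]
}

#' Rebuild a symmetric RDM from its lower-triangle vector
#'
#' @param v vector as produced by [vectorize_lower()].
#' @param diagonal value placed on the diagonal (default 0).
#' @param condition_ids optional labels.
#' @return an `rdm`.
#' @export
devectorize_lower <- function(v, diagonal = 0, condition_ids = NULL) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-9) stop("length is not n(n-1)/2 for integer n")
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  tm <- t(m)
  tm[upper.tri(tm)] <- v        # row-major lower triangle of m
  m <- t(tm)
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  diag(m) <- diagonal
  rdm(m, condition_ids)
}
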