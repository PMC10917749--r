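#' Aggregate per-participant path heatmaps
#'
#' Sums the participants' drawing grids elementwise and rescales to a maximum
#' of 1, yielding a probabilistic heatmap whose support is the union of all
#' drawn paths.
#'
#' @param per_participant_maps list of non-negative matrices with identical
#'   dimensions.
#' @return a matrix with values in \[0, 1\] (all-zero input stays all-zero).
#' @export
aggregate_heatmaps <- function(per_participant_maps) {
  stopifnot(length(per_participant_maps) >= 1)
  dims <- dim(per_participant_maps[[1]])
  for (m in per_participant_maps) {
    if (!identical(dim(m), dims))
      stop("all heatmaps must share the same dimensions")
  }
  acc <- Reduce(`+`, per_participant_maps)
  mx <- max(acc)
  if (mx > 0) acc <- acc / mx
  acc
}

#' Angular histogram of navigable-path pixels
#'
#' Bins every above-threshold pixel of a heatmap into one-degree angular bins
#' spanning 0 to 180 degrees, measured at the origin pixel (bottom-center by
#' default): 0 deg points rightward along the origin row, 90 deg straight up,
#' 180 deg leftward. Pixels below the origin row and the origin pixel itself
#' (undefined angle) are ignored. The closed top edge maps an exact 180 deg
#' angle to bin 179 (bins are otherwise `[b, b+1)` degrees).
#'
#' @param heatmap non-negative numeric matrix (rows = image rows, row 1 at
#'   the top).
#' @param origin `(row, col)` pixel; defaults to the bottom row at column
#'   `floor(width/2) + 1`.
#' @param weight_threshold pixels contribute only if their weight exceeds
#'   this value (default 0).
#' @param weighted if `TRUE`, each pixel contributes its weight instead of a
#'   unit count.
#' @param image_id optional label.
#' @return object of class `affordance_histogram`: list with `counts`
#'   (length 180) and `image_id`.
#' @export
angular_histogram <- function(heatmap, origin = NULL, weight_threshold = 0,
                              weighted = FALSE, image_id = NA_character_) {
  stopifnot(is.matrix(heatmap))
  h <- nrow(heatmap); w <- ncol(heatmap)
  if (is.null(origin)) origin <- c(h, floor(w / 2) + 1L)
  if (origin[1] < 1 || origin[1] > h || origin[2] < 1 || origin[2] > w)
    stop("origin must lie inside the grid")
  counts <- numeric(180)
  hit <- which(heatmap > weight_threshold, arr.ind = TRUE)
  if (nrow(hit) > 0) {
    dy <- origin[1] - hit[, 1]          # upward offset
    dx <- hit[, 2] - origin[2]          # rightward offset
    keep <- dy >= 0 & !(dy == 0 & dx == 0)
    dy <- dy[keep]; dx <- dx[keep]
    wts <- if (weighted) heatmap[hit][keep] else rep(1, sum(keep))
    if (length(dy) > 0) {
      theta <- atan2(dy, dx) * 180 / pi
      bin <- pmin(floor(theta), 179) + 1L
      for (i in seq_along(bin)) counts[bin[i]] <- counts[bin[i]] + wts[i]
    }
  }
  structure(list(counts = counts, image_id = image_id),
            class = "affordance_histogram")
}

#' @export
print.affordance_histogram <- function(x, ...) {
  nz <- which(x$counts > 0)
  cat(sprintf("<affordance_histogram> %s: total %g over %d active bins (%s)\n",
              x$image_id, sum(x$counts), length(nz),
              if (length(nz)) sprintf("%d-%d deg", min(nz) - 1, max(nz) - 1)
              else "empty"))
  invisible(x)
}

#' Navigational-affordance RDM
#'
#' Pairwise Euclidean distance between 180-bin affordance histograms.
#'
#' @param histograms list of `affordance_histogram` objects (or bare
#'   length-180 numeric vectors), at least 2.
#' @param condition_ids optional labels; defaults to the histograms'
#'   `image_id`s when all are set.
#' @return an `rdm` with zero diagonal.
#' @export
nam_rdm <- function(histograms, condition_ids = NULL) {
  stopifnot(length(histograms) >= 2)
  vecs <- lapply(histograms, function(x) {
    v <- if (inherits(x, "affordance_histogram")) x$counts else as.numeric(x)
    if (length(v) != 180)
      stop("affordance histograms must have exactly 180 bins")
    v
  })
  if (is.null(condition_ids)) {
    ids <- vapply(histograms, function(x)
      if (inherits(x, "affordance_histogram")) x$image_id else NA_character_,
      character(1))
    condition_ids <- if (!anyNA(ids) && !anyDuplicated(ids)) ids else NULL
  }
  m <- as.matrix(stats::dist(do.call(rbind, vecs)))
  rdm(unname(m), condition_ids)
}
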