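#' Write an epoch set to disk
#'
#' Stores the signal as a flat little-endian double array (trials fastest,
#' then channels, then time — R's native array order) next to a JSON sidecar
#' holding the condition labels, channel names, time axis, sampling rate and
#' any extra provenance fields.
#'
#' @param epochs an [epoch_set].
#' @param path basename without extension; writes `<path>.dat` and
#'   `<path>.json`.
#' @param extra named list merged into the sidecar (e.g. seed, generator
#'   config).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path, extra = list()) {
  stopifnot(inherits(epochs, "epoch_set"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  side <- c(list(dim = dim(epochs$data), conditions = epochs$conditions,
                 channels = epochs$channels, times = epochs$times,
                 sampling_rate = epochs$sampling_rate), extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#' @param path basename without extension.
#' @return an [epoch_set].
#' @export
read_epochs <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dims <- as.integer(side$dim)
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(dims), size = 8, endian = "little")
  epoch_set(array(vals, dim = dims), side$conditions, side$channels,
            side$times, side$sampling_rate)
}

#' Export one channel's trial x time slice as CSV
#'
#' @param epochs an [epoch_set].
#' @param channel channel name.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
export_channel_csv <- function(epochs, channel, file) {
  stopifnot(inherits(epochs, "epoch_set"))
  ci <- match(channel, epochs$channels)
  if (is.na(ci)) stop("unknown channel: ", channel)
  m <- epochs$data[, ci, , drop = TRUE]
  df <- data.frame(trial = seq_len(nrow(m)), condition = epochs$conditions, m)
  names(df)[-(1:2)] <- sprintf("t%.4f", epochs$times)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write an RDM as CSV with a JSON sidecar
#'
#' Comma-separated values with a header row of condition ids and no index
#' quoting, so round trips are bit-exact on the text representation; the
#' sidecar records condition ids plus any provenance fields.
#'
#' @param x an `rdm`.
#' @param path basename without extension; writes `<path>.csv` and
#'   `<path>.json`.
#' @param extra named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_rdm <- function(x, path, extra = list()) {
  stopifnot(inherits(x, "rdm"))
  m <- unclass(as.matrix(x))
  utils::write.table(m, paste0(path, ".csv"), sep = ",", col.names = TRUE,
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(list(condition_ids = condition_ids(x)), extra),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an RDM written by [write_rdm()] (or any headed square CSV)
#' @param path basename without extension (sidecar optional).
#' @return an `rdm`.
#' @export
read_rdm <- function(path) {
  m <- as.matrix(utils::read.csv(paste0(path, ".csv"), check.names = FALSE))
  ids <- colnames(m)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$condition_ids)) ids <- side$condition_ids
  }
  rdm(unname(m), ids)
}

#' Read a feature matrix from CSV/TSV
#'
#' Expects a condition-id index column (first column) and one column per
#' feature dimension.
#'
#' @param file path; tab-separated if the extension is `.tsv`.
#' @return numeric matrix with condition row names.
#' @export
read_features <- function(file) {
  sep <- if (grepl("\\.tsv$", file)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a feature matrix as CSV
#' @param features numeric matrix with condition row names.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_features <- function(features, file) {
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  df <- data.frame(condition = rownames(features), features,
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a heatmap grid
#'
#' @param grid non-negative matrix.
#' @param file output path: `.png` writes an 8-bit grayscale image (values
#'   scaled to the grid maximum), anything else a plain-text numeric grid.
#' @return `file`, invisibly.
#' @export
write_heatmap <- function(grid, file) {
  if (grepl("\\.png$", file)) {
    mx <- max(grid)
    png::writePNG(if (mx > 0) grid / mx else grid, file)
  } else {
    utils::write.table(grid, file, sep = " ", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(file)
}

#' Read a heatmap grid written by [write_heatmap()]
#' @param file `.png` or plain-text grid path.
#' @return numeric matrix.
#' @export
read_heatmap <- function(file) {
  if (grepl("\\.png$", file)) {
    img <- png::readPNG(file)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  } else {
    as.matrix(utils::read.table(file, header = FALSE))
  }
}

#' Write an affordance histogram as CSV (bin, count)
#' @param hist an `affordance_histogram`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_histogram_csv <- function(hist, file) {
  stopifnot(inherits(hist, "affordance_histogram"))
  utils::write.csv(data.frame(bin = 0:179, count = hist$counts), file,
                   row.names = FALSE)
  invisible(file)
}

#' Write peak-latency results as JSON
#'
#' One record per group: `{group, peak_s, ci_low_s, ci_high_s, boot_sd_s,
#' mean_participant_peak_s, n_boot, seed}`.
#'
#' @param results list of `peak_latency_result`s.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_peaks_json <- function(results, file) {
  recs <- lapply(results, function(r) list(
    group = r$group_name, peak_s = r$peak_latency,
    ci_low_s = r$ci95[1], ci_high_s = r$ci95[2], boot_sd_s = r$boot_sd,
    mean_participant_peak_s = r$mean_participant_peak,
    n_boot = r$n_boot, seed = r$seed))
  jsonlite::write_json(unname(recs), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
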