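#' Configuration for an end-to-end synthetic run
#'
#' Collects every knob of the simulate -> preprocess -> decode -> model-RDM
#' -> variance-partitioning -> inference chain. All randomness flows from
#' `seed` through named per-stage substreams, so a config reproduces its run
#' bit-exactly.
#'
#' @param seed master seed.
#' @param n_conditions number of stimulus conditions.
#' @param n_participants synthetic cohort size.
#' @param n_trials_per_condition trials per condition and participant.
#' @param n_channels simulated channels.
#' @param sampling_rate simulation rate in Hz.
#' @param target_rate analysis rate in Hz (decimation target).
#' @param epoch_window `(t0, t1)` seconds, half-open.
#' @param baseline_window `(t0, t1)` seconds.
#' @param model_names names of the feature-based model groups.
#' @param latencies onset latencies (s), one per group in
#'   `c(model_names, "NAM")` order.
#' @param envelope_width Gaussian envelope SD (s).
#' @param amplitude pattern amplitude relative to `noise_sd`.
#' @param noise_sd trial noise SD.
#' @param cross_model_similarity target RDM correlation between groups.
#' @param within_group_similarity target RDM correlation between the two
#'   layer RDMs of one group.
#' @param latent_dim feature dimensionality.
#' @param n_heatmap_participants simulated path-drawers for the NAM.
#' @param heatmap_size `(width, height)` pixels.
#' @param n_folds,regularization decoding settings (see [pairwise_decode()]).
#' @param n_boot bootstrap iterations.
#' @param peak_window latency search window (s).
#' @param model_files optional named list mapping a model group name to a
#'   feature CSV/TSV (see [read_features()]); listed groups use the file
#'   instead of generated features.
#' @param out_dir run directory (`NULL` = results kept in memory only).
#' @return object of class `run_config` (a list).
#' @export
run_config <- function(seed = 1L,
                       n_conditions = 14L,
                       n_participants = 16L,
                       n_trials_per_condition = 5L,
                       n_channels = 16L,
                       sampling_rate = 100,
                       target_rate = 100,
                       epoch_window = c(-0.2, 0.8),
                       baseline_window = c(-0.2, 0),
                       model_names = c("2D", "3D", "semantic"),
                       latencies = c(0.13, 0.17, 0.16, 0.30),
                       envelope_width = 0.04,
                       amplitude = 5,
                       noise_sd = 1,
                       cross_model_similarity = 0.2,
                       within_group_similarity = 0.7,
                       latent_dim = 128L,
                       n_heatmap_participants = 3L,
                       heatmap_size = c(64L, 48L),
                       n_folds = "loo",
                       regularization = "auto",
                       n_boot = 1000L,
                       peak_window = c(0, 0.8),
                       model_files = NULL,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  if (length(cfg$latencies) != length(cfg$model_names) + 1)
    stop("latencies must have one entry per model group plus one for NAM")
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML or JSON
#' @param file path to a `.yaml`/`.yml` or `.json` config file; fields
#'   override the [run_config()] defaults.
#' @return a `run_config`.
#' @export
read_config <- function(file) {
  vals <- if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
          else jsonlite::read_json(file, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

# deterministic per-stage substream seed (kept below 2^31)
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) %% 65011 * 33013 + h * 257) %% 2147483629)
}

# second-layer variant of a feature matrix whose RDM correlates ~similarity
# with the original's (shared/private mixing on the sampling-covariance scale)
layer_variant <- function(features, similarity, seed) {
  set.seed(seed)
  a <- sqrt(similarity)
  b <- sqrt(1 - similarity)
  a * features + b * matrix(rnorm(length(features)), nrow(features))
}

epoch_times <- function(window, rate) {
  n <- round((window[2] - window[1]) * rate)
  window[1] + (seq_len(n) - 1) / rate
}

#' Build the model groups of a synthetic run
#'
#' Feature-based groups (two layer RDMs each, from [generate_features()] and
#' a correlated layer variant) plus the NAM group (one RDM from synthetic
#' path heatmaps aggregated across drawers).
#'
#' @param config a [run_config()].
#' @return list with `groups` (list of [model_group]s, NAM last), `features`,
#'   `heatmaps`, `histograms`.
#' @export
build_model_groups <- function(config) {
  feats <- generate_features(config$n_conditions, config$model_names,
                             latent_dim = config$latent_dim,
                             cross_model_similarity = config$cross_model_similarity,
                             seed = stage_seed(config$seed, "features"))
  if (!is.null(config$model_files)) {
    for (nm in names(config$model_files)) {
      f <- config$model_files[[nm]]
      if (!file.exists(f))
        stop("model feature file not found for group '", nm, "': ", f)
      feats[[nm]] <- read_features(f)
    }
  }
  groups <- lapply(config$model_names, function(nm) {
    f1 <- feats[[nm]]
    f2 <- layer_variant(f1, config$within_group_similarity,
                        stage_seed(config$seed, paste0("layer2_", nm)))
    rownames(f2) <- rownames(f1)
    model_group(nm, list(rdm_from_features(f1), rdm_from_features(f2)))
  })
  ids <- default_condition_ids(config$n_conditions)
  maps <- lapply(seq_len(config$n_heatmap_participants), function(p)
    generate_heatmaps(config$n_conditions, image_size = config$heatmap_size,
                      seed = stage_seed(config$seed, paste0("heatmaps_", p))))
  agg <- lapply(seq_len(config$n_conditions), function(i)
    aggregate_heatmaps(lapply(maps, `[[`, i)))
  hists <- lapply(seq_len(config$n_conditions), function(i)
    angular_histogram(agg[[i]], image_id = ids[i]))
  nam <- model_group("NAM", nam_rdm(hists, condition_ids = ids))
  list(groups = c(groups, list(nam)), features = feats,
       heatmaps = agg, histograms = hists)
}

#' Simulate and preprocess one participant's epochs
#'
#' Injects each group's average RDM geometry at its configured latency,
#' baseline-corrects, downsamples to the target rate if needed, and crops to
#' the epoch window.
#'
#' @param config a [run_config()].
#' @param groups list of [model_group]s (NAM last), as from
#'   [build_model_groups()].
#' @param participant participant index (seeds the noise and channel mixing).
#' @return a preprocessed [epoch_set].
#' @export
simulate_participant <- function(config, groups, participant) {
  inj <- lapply(groups, average_rdms)
  names(inj) <- vapply(groups, function(g) g$name, character(1))
  prof <- latency_profile(names(inj), config$latencies,
                          envelope_width = config$envelope_width,
                          amplitude = config$amplitude * config$noise_sd)
  times <- epoch_times(config$epoch_window, config$sampling_rate)
  ep <- generate_epochs(inj, prof, config$n_trials_per_condition,
                        config$n_channels, times,
                        noise_sd = config$noise_sd,
                        seed = stage_seed(config$seed,
                                          paste0("epochs_", participant)))
  ep <- baseline_correct(ep, config$baseline_window)
  if (config$target_rate < config$sampling_rate)
    ep <- downsample(ep, config$target_rate)
  crop(ep, config$epoch_window)
}

#' Run the full synthetic pipeline
#'
#' Chains simulate -> preprocess -> decode -> model RDMs -> variance
#' partitioning -> group statistics for a whole synthetic cohort. When
#' `config$out_dir` is set, every artifact is written there along with a
#' manifest listing each file's producing stage, md5 checksum and upstream
#' dependencies; a rerun with the same config reproduces the deterministic
#' stages bit-exactly.
#'
#' @param config a [run_config()], or a path accepted by [read_config()].
#' @return (invisibly) list with `config`, `groups`, `varpart` (one
#'   `varpart_result` per participant), `unique` (per group, matrices
#'   `participants x time`), `stats` (per-group `timecourse_stats`), `peaks`
#'   (per-group `peak_latency_result`), `comparisons` (pairwise peak table),
#'   `grand_accuracy`, and `dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  built <- build_model_groups(config)
  groups <- built$groups
  g_names <- vapply(groups, function(g) g$name, character(1))

  vp <- vector("list", config$n_participants)
  ga <- NULL
  for (p in seq_len(config$n_participants)) {
    ep <- simulate_participant(config, groups, p)
    series <- pairwise_decode(ep, n_folds = config$n_folds,
                              regularization = config$regularization,
                              seed = stage_seed(config$seed,
                                                paste0("folds_", p)))
    vp[[p]] <- unique_variance_timecourse(series, groups,
                                          participant_id = sprintf("P%02d", p))
    acc <- grand_average(series)$accuracy
    ga <- if (is.null(ga)) acc / config$n_participants
          else ga + acc / config$n_participants
  }
  times <- vp[[1]]$times
  uniq <- lapply(g_names, function(g)
    do.call(rbind, lapply(vp, function(x) x$unique[g, ])))
  names(uniq) <- g_names

  stats <- lapply(uniq, function(m) timepoint_tests(m, times))
  peaks <- lapply(g_names, function(g)
    bootstrap_peaks(uniq[[g]], times, n_boot = config$n_boot,
                    seed = stage_seed(config$seed, "bootstrap"),
                    search_window = config$peak_window, group_name = g))
  names(peaks) <- g_names
  comparisons <- compare_all_peaks(peaks)

  out <- list(config = config, groups = groups, varpart = vp, unique = uniq,
              stats = stats, peaks = peaks, comparisons = comparisons,
              grand_accuracy = data.frame(time = times, accuracy = ga),
              dir = config$out_dir)
  if (!is.null(config$out_dir)) write_run_artifacts(out, built)
  invisible(out)
}

write_run_artifacts <- function(out, built) {
  dir <- out$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- out$config
  cfg$out_dir <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list()
  note <- function(path, stage, deps = character(0)) {
    manifest[[length(manifest) + 1]] <<- list(
      path = basename(path), stage = stage,
      md5 = unname(tools::md5sum(path)), depends_on = deps)
  }
  note(file.path(dir, "config.json"), "config")

  for (nm in names(built$features)) {
    f <- file.path(dir, sprintf("features_%s.csv", nm))
    write_features(built$features[[nm]], f)
    note(f, "simulate", "config.json")
  }
  for (i in seq_along(built$heatmaps)) {
    f <- file.path(dir, sprintf("heatmap_%s.txt", out$groups[[1]]$condition_ids[i]))
    write_heatmap(built$heatmaps[[i]], f)
    note(f, "simulate", "config.json")
  }
  for (g in out$groups) {
    for (k in seq_along(g$rdms)) {
      f <- file.path(dir, sprintf("rdm_%s_%d", g$name, k))
      write_rdm(g$rdms[[k]], f, extra = list(stage = "modelrdm",
                                             group = g$name, member = k))
      note(paste0(f, ".csv"), "modelrdm", "config.json")
    }
  }
  f <- file.path(dir, "grand_average_decoding.csv")
  utils::write.csv(out$grand_accuracy, f, row.names = FALSE)
  note(f, "decode", "config.json")

  f <- file.path(dir, "varpart.csv")
  utils::write.csv(do.call(rbind, lapply(out$varpart, varpart_table)), f,
                   row.names = FALSE)
  note(f, "varpart", "grand_average_decoding.csv")

  stats_df <- do.call(rbind, lapply(names(out$stats), function(g) {
    s <- out$stats[[g]]
    data.frame(group = g, time = s$times, p = s$p_values,
               p_adjusted = s$p_adjusted, significant = s$significant)
  }))
  f <- file.path(dir, "timepoint_stats.csv")
  utils::write.csv(stats_df, f, row.names = FALSE)
  note(f, "stats", "varpart.csv")

  f <- file.path(dir, "peaks.json")
  write_peaks_json(out$peaks, f)
  note(f, "stats", "varpart.csv")

  f <- file.path(dir, "peak_comparisons.csv")
  utils::write.csv(out$comparisons, f, row.names = FALSE)
  note(f, "stats", "peaks.json")

  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
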