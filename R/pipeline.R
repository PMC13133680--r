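#' Experiment grid configuration
#'
#' Every combination of the listed bands, connectivity metrics, graph
#' modes, window lengths, channel configurations and feature policies
#' expands to one independent run with its own output directory.
#'
#' @param bands Subset of the five band names.
#' @param metrics Subset of `c("plv", "pcc")`.
#' @param graph_modes Character vector; `"full"` or `"tau0.3"`,
#'   `"tau0.5"`, `"tau0.8"`.
#' @param window_seconds Vector of window lengths in `[2, 8]`.
#' @param channel_configs Vector from `c(8, 16, 22, 24, 29)`.
#' @param feature_policies Subset of `c("fusion", "local_only",
#'   "higher_order_only")`.
#' @param model_cfg A [model_config()] (node count is adapted to the
#'   channel configuration per run).
#' @param train_cfg A [train_config()].
#' @param smote_mode `"global"` (reference protocol: one SMOTE pass over
#'   the whole cohort before splitting, synthetic subjects eligible for
#'   the fixed test set) or `"fold"` (leakage-free: oversampling inside
#'   each training partition only; see [cross_validate()]).
#' @param seed Master seed; all per-run randomness derives from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(bands = "gamma", metrics = "plv",
                              graph_modes = "tau0.3", window_seconds = 8,
                              channel_configs = 29,
                              feature_policies = "fusion",
                              model_cfg = model_config(),
                              train_cfg = train_config(),
                              smote_mode = c("global", "fold"), seed = 42) {
  smote_mode <- match.arg(smote_mode)
  stopifnot(all(bands %in% names(EEG_BANDS)),
            all(metrics %in% c("plv", "pcc")),
            all(window_seconds >= 2 & window_seconds <= 8),
            all(channel_configs %in% c(8, 16, 22, 24, 29)),
            all(feature_policies %in%
                  c("fusion", "local_only", "higher_order_only")))
  structure(list(bands = bands, metrics = metrics,
                 graph_modes = graph_modes,
                 window_seconds = window_seconds,
                 channel_configs = channel_configs,
                 feature_policies = feature_policies,
                 model_cfg = model_cfg, train_cfg = train_cfg,
                 smote_mode = smote_mode, seed = as.integer(seed)),
            class = "experiment_config")
}

policy_features <- function(policy) {
  switch(policy,
         local_only = c("mav", "sd", "band_power", "betweenness"),
         higher_order_only = setdiff(HIGHER_ORDER_NAMES,
                                     "PersistenceEntropy_1"),
         fusion = select_features(policy = "paper_fixed"),
         stop("unknown feature policy '", policy, "'", call. = FALSE))
}

parse_graph_mode <- function(mode) {
  if (mode == "full") return(list(mode = "full", tau = NA_real_))
  if (grepl("^tau", mode))
    return(list(mode = "thresholded",
                tau = as.numeric(sub("^tau", "", mode))))
  stop("unknown graph mode '", mode, "'", call. = FALSE)
}

#' Extract classifier samples from a cohort
#'
#' Channel selection, band-pass filtering, segmentation and per-segment
#' feature extraction for one band/metric/graph-mode combination,
#' restricted to the requested feature policy's columns.
#'
#' @param cohort List of [eeg_recording()]s.
#' @param band Band name.
#' @param metric `"plv"` or `"pcc"`.
#' @param window_seconds Window length (default 8).
#' @param channel_config 8, 16, 22, 24 or 29 (default 29).
#' @param graph_mode `"tau0.3"`, `"tau0.5"`, `"tau0.8"` or `"full"`.
#' @param feature_policy `"fusion"`, `"local_only"` or
#'   `"higher_order_only"`.
#' @return List of `graph_sample`s.
#' @export
cohort_samples <- function(cohort, band = "gamma", metric = "plv",
                           window_seconds = 8, channel_config = 29,
                           graph_mode = "tau0.3",
                           feature_policy = "fusion") {
  gm <- parse_graph_mode(graph_mode)
  cols <- policy_features(feature_policy)
  out <- list()
  for (rec in cohort) {
    rec <- select_channels(rec, channel_config)
    rec <- bandpass(rec, band)
    for (seg in segment(rec, window_seconds)) {
      s <- extract_features(seg, metric = metric, graph_mode = gm$mode,
                            tau = if (is.na(gm$tau)) 0.3 else gm$tau)
      s$features <- s$features[, cols, drop = FALSE]
      out[[length(out) + 1]] <- s
    }
  }
  out
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Run the experiment grid
#'
#' Expands the configuration into independent runs; for each, extracts
#' features, rebalances with SMOTE, cross-validates, and writes
#' `metrics.csv`, `roc.csv`, `loss.csv` and `run_info.json` into the
#' run's directory. Completed runs (existing `metrics.csv`) are
#' skipped, so an interrupted grid resumes; a failing run is recorded
#' in `failures.log` and does not abort the rest.
#'
#' @param config An [experiment_config()].
#' @param cohort List of [eeg_recording()]s, or `NULL` to read all
#'   `.csv`/`.edf` recordings in `data_dir`.
#' @param out_dir Output directory (created if needed).
#' @param data_dir Directory of recordings (used when `cohort` is NULL).
#' @return Data frame summarizing all runs (one row per combination).
#' @export
run_experiment <- function(config, cohort = NULL, out_dir, data_dir = NULL) {
  if (is.null(cohort)) {
    files <- list.files(data_dir, pattern = "\\.(csv|edf)$",
                        full.names = TRUE)
    cohort <- lapply(files, read_recording)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  grid <- expand.grid(band = config$bands, metric = config$metrics,
                      graph_mode = config$graph_modes,
                      window_seconds = config$window_seconds,
                      channel_config = config$channel_configs,
                      feature_policy = config$feature_policies,
                      stringsAsFactors = FALSE)
  fail_log <- file.path(out_dir, "failures.log")
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tag <- sprintf("%s_%s_%s_w%g_ch%d_%s", g$band, g$metric, g$graph_mode,
                   g$window_seconds, g$channel_config, g$feature_policy)
    run_dir <- file.path(out_dir, tag)
    metrics_file <- file.path(run_dir, "metrics.csv")
    if (file.exists(metrics_file)) {
      prev <- read.csv(metrics_file)
      rows[[i]] <- cbind(grid[i, ], accuracy = mean(prev$accuracy),
                         f1 = mean(prev$f1), status = "cached")
      next
    }
    res <- tryCatch({
      dir.create(run_dir, showWarnings = FALSE)
      samples <- cohort_samples(cohort, band = g$band, metric = g$metric,
                                window_seconds = g$window_seconds,
                                channel_config = g$channel_config,
                                graph_mode = g$graph_mode,
                                feature_policy = g$feature_policy)
      if (config$smote_mode == "global")
        samples <- smote_oversample(samples, seed = config$seed)
      mcfg <- config$model_cfg
      mcfg$n_nodes <- nrow(samples[[1]]$features)
      mcfg$n_features <- ncol(samples[[1]]$features)
      tcfg <- config$train_cfg
      tcfg$seed <- config$seed
      cv <- cross_validate(samples, mcfg, tcfg,
                           smote = if (config$smote_mode == "fold")
                             "fold" else "none")
      fm <- cv$fold_metrics
      fm$config_hash <- hash
      write.csv(fm, metrics_file, row.names = FALSE)
      # one model on all non-test subjects for loss and ROC curves
      ids <- vapply(samples, `[[`, "", "subject_id")
      tr <- samples[!ids %in% tcfg$test_ids]
      te <- samples[ids %in% tcfg$test_ids]
      if (config$smote_mode == "fold")
        tr <- smote_oversample(tr, seed = config$seed)
      fit <- train_gcn(normalize_features(tr), mcfg, tcfg,
                       validation = normalize_features(tr, te))
      hist <- fit$history
      hist$config_hash <- hash
      write.csv(hist, file.path(run_dir, "loss.csv"), row.names = FALSE)
      pr <- predict_gcn(fit$model, normalize_features(tr, te))
      roc <- roc_curve(pr$prob_moderate, pr$label,
                       tcfg$positive_class)$points
      roc$config_hash <- hash
      write.csv(roc, file.path(run_dir, "roc.csv"), row.names = FALSE)
      jsonlite::write_json(list(config_hash = hash, seed = config$seed,
                                tag = tag,
                                r_version = R.version.string,
                                mean = as.list(cv$mean),
                                sd = as.list(cv$sd)),
                           file.path(run_dir, "run_info.json"),
                           auto_unbox = TRUE, digits = NA)
      cbind(grid[i, ], accuracy = cv$mean[["accuracy"]],
            f1 = cv$mean[["f1"]], status = "ok")
    }, error = function(e) {
      cat(format(Sys.time()), tag, conditionMessage(e), "\n",
          file = fail_log, append = TRUE)
      cbind(grid[i, ], accuracy = NA_real_, f1 = NA_real_,
            status = "failed")
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
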