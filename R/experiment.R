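#' Stratified train/test split of a clip list
#'
#' Splits by label (seeded shuffle within class) at the given training
#' fraction; the canonical design is a 3:1 split.
#'
#' @param clips list of labeled [vog_clip]s.
#' @param train_fraction fraction of each class assigned to training.
#' @param seed shuffle seed.
#' @return list with `train` and `test` clip lists.
#' @export
split_clips <- function(clips, train_fraction = 0.75, seed = 1) {
  labs <- vapply(clips, function(c) c$label, character(1))
  idx_tr <- with_seed(seed, {
    unlist(lapply(unique(labs), function(l) {
      i <- which(labs == l)
      i <- i[sample.int(length(i))]
      i[seq_len(round(train_fraction * length(i)))]
    }))
  })
  list(train = clips[idx_tr], test = clips[-idx_tr])
}

#' Train and evaluate one pipeline configuration
#'
#' Runs filter -> classifier -> voting on a train/test split and reports
#' video-level metrics at the operating threshold (plus the Youden-J
#' optimal threshold for reference).
#'
#' @param train,test lists of labeled [vog_clip]s.
#' @param beta,window filtered-image parameters.
#' @param backbone a [backbone_spec].
#' @param voting a [voting_spec].
#' @return list with `fit` (the detector), `decisions` (test data.frame
#'   with truth attached), `auroc` (ranking quality of the aggregate
#'   scores), `metrics` (a `metrics_report` of the voting rule's own
#'   decisions, so temporal run criteria are honored) and
#'   `youden_threshold` (score cutoff maximizing Youden's J, reported for
#'   reference).
#' @export
evaluate_pipeline <- function(train, test, beta = 0.25, window = NULL,
                              backbone = backbone_spec(),
                              voting = voting_spec("soft")) {
  fit <- nystagmus_detector(train, beta = beta, window = window,
                            backbone = backbone, voting = voting)
  dec <- predict(fit, test)
  dec$truth <- vapply(test, function(c) c$label, character(1))
  auc <- roc_auc(dec$score, dec$truth)$auc
  met <- metrics_at_threshold(as.numeric(dec$label == "nystagmus"),
                              dec$truth, 0.5)
  met$operating_threshold <- switch(voting$method,
    temporal = voting$run_length, voting$video_threshold)
  list(fit = fit, decisions = dec, auroc = auc, metrics = met,
       youden_threshold = youden_threshold(dec$score, dec$truth))
}

#' Frame-rate / resolution degradation experiment
#'
#' Degrades a master dataset over a rate-by-resolution grid and re-runs the
#' full train/evaluate pipeline in each cell (shared split and seeds), the
#' robustness analysis for low-quality video.
#'
#' @param clips master dataset (top rate and resolution).
#' @param rates numeric vector of target rates (Hz).
#' @param resolutions list of `c(H, W)` targets.
#' @param beta,backbone,voting,train_fraction,seed pipeline configuration.
#' @return data.frame, one row per grid cell: rate, H, W, auroc,
#'   sensitivity, specificity, accuracy.
#' @export
run_degradation_experiment <- function(clips, rates, resolutions,
                                       beta = 0.25,
                                       backbone = backbone_spec(),
                                       voting = voting_spec("soft"),
                                       train_fraction = 0.75, seed = 1) {
  out <- NULL
  for (r in rates) {
    for (res in resolutions) {
      cell <- lapply(clips, function(cl) downscale(resample_rate(cl, r), res))
      sp <- split_clips(cell, train_fraction, seed)
      ev <- evaluate_pipeline(sp$train, sp$test, beta = beta,
                              backbone = backbone, voting = voting)
      out <- rbind(out, data.frame(
        rate = r, H = res[1], W = res[2], auroc = ev$auroc,
        sensitivity = ev$metrics$sensitivity,
        specificity = ev$metrics$specificity,
        accuracy = ev$metrics$accuracy))
    }
  }
  out
}

#' Default experiment configuration
#'
#' Desk-scale defaults for [run_experiment]: a separable synthetic
#' benchmark small enough to train on one CPU in minutes.
#'
#' @param ... overrides of any config field.
#' @return a named list of configuration values.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    n_videos = 36, class_ratio = 0.5, rate = 60, resolution = c(60, 80),
    duration = 10, eccentric_fraction = 0.25, patients = 6,
    # benchmark amplitudes: upper half of the waveform range, so beats stay
    # >= 1.5 px at the benchmark resolution (see the methods vignette)
    amplitude_range = c(1.5, 2.5),
    betas = 0.25, window = NULL,
    backbone = unclass(backbone_spec()),
    # temporal voting is the benchmark default: a >= 50-frame run of
    # positive images (~750 ms at 60 Hz) is the direct reading of the
    # consecutive-beat definition and proved the most seed-stable rule
    voting = list(method = "temporal", prob_threshold = 0.5,
                  video_threshold = 0.5, run_length = 50),
    rates = NULL, resolutions = NULL,
    train_fraction = 0.75, seed = 1, output_dir = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Degradation summary on the bundled synthetic benchmark
#'
#' Generates a fresh separable benchmark dataset per seed, evaluates the
#' pipeline at each sampling rate (matched resolution), and averages the
#' video-level accuracy over seeds. The expected pattern on a separable
#' set is non-increasing accuracy as the rate drops, the directional
#' analogue of real-world frame-rate robustness findings.
#'
#' @param seeds integer vector of dataset/training seeds.
#' @param rates sampling rates to compare (Hz); the first must be the
#'   generation rate.
#' @param n_videos,resolution,patients benchmark dataset size.
#' @param epochs backbone training epochs.
#' @return data.frame: one row per (seed, rate) with auroc and accuracy.
#' @export
benchmark_degradation <- function(seeds = 1:5, rates = c(60, 15),
                                  n_videos = 24, resolution = c(60, 80),
                                  patients = 6, epochs = 20) {
  out <- NULL
  for (s in seeds) {
    clips <- make_dataset(n_videos = n_videos, resolution = resolution,
                          duration = 10, patients = patients,
                          amplitude_range = c(1.5, 2.5), seed = s)
    tab <- run_degradation_experiment(
      clips, rates = rates, resolutions = list(resolution),
      backbone = backbone_spec(epochs = epochs, seed = s),
      voting = voting_spec("temporal", run_length = 50), seed = s)
    out <- rbind(out, cbind(seed = s, tab))
  }
  out
}

#' Run a full simulate-filter-train-vote-evaluate experiment
#'
#' Generates a synthetic dataset from the config, runs the pipeline once
#' per `beta`, and (optionally) writes decision and metric CSVs plus the
#' config itself to `output_dir`, so any results bundle can be regenerated
#' from its embedded config.
#'
#' @param config a list from [experiment_config], or a path to a YAML/JSON
#'   file holding one.
#' @return list with `config`, `metrics` (data.frame, one row per beta)
#'   and `decisions` (test-set decisions per beta).
#' @export
run_experiment <- function(config = experiment_config()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required to read YAML configs")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
    config <- do.call(experiment_config, config)
  }
  clips <- make_dataset(n_videos = config$n_videos,
                        class_ratio = config$class_ratio,
                        rate = config$rate,
                        resolution = unlist(config$resolution),
                        duration = config$duration,
                        eccentric_fraction = config$eccentric_fraction,
                        patients = config$patients,
                        amplitude_range = unlist(config$amplitude_range),
                        seed = config$seed)
  sp <- split_clips(clips, config$train_fraction, config$seed)
  bb <- do.call(backbone_spec, config$backbone)
  vt <- do.call(voting_spec, config$voting)
  metrics <- NULL
  decisions <- list()
  for (b in config$betas) {
    ev <- evaluate_pipeline(sp$train, sp$test, beta = b,
                            window = config$window, backbone = bb,
                            voting = vt)
    metrics <- rbind(metrics, data.frame(
      beta = b, auroc = ev$auroc,
      sensitivity = ev$metrics$sensitivity,
      specificity = ev$metrics$specificity,
      accuracy = ev$metrics$accuracy,
      youden_threshold = ev$youden_threshold))
    decisions[[as.character(b)]] <- ev$decisions
  }
  degradation <- NULL
  if (!is.null(config$rates) && !is.null(config$resolutions)) {
    res_list <- config$resolutions
    if (!is.list(res_list)) res_list <- list(res_list)
    res_list <- lapply(res_list, unlist)
    degradation <- run_degradation_experiment(
      clips, rates = unlist(config$rates), resolutions = res_list,
      beta = config$betas[1], backbone = bb, voting = vt,
      train_fraction = config$train_fraction, seed = config$seed)
  }
  out <- list(config = config, metrics = metrics, decisions = decisions,
              degradation = degradation)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(config$output_dir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(degradation)) {
      utils::write.csv(degradation,
                       file.path(config$output_dir, "degradation.csv"),
                       row.names = FALSE)
    }
    for (b in names(decisions)) {
      utils::write.csv(decisions[[b]],
                       file.path(config$output_dir,
                                 sprintf("decisions_beta%s.csv", b)),
                       row.names = FALSE)
    }
    jsonlite::write_json(config, file.path(config$output_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
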