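# Pipeline orchestration: configuration, the per-recording preprocessing
# chain, per-subject template fitting, and the end-to-end run that writes
# an artifact directory.

#' Default pipeline configuration
#'
#' One nested list holding every tunable parameter of the pipeline, in the
#' study-default setting: 40 subjects, 2 conditions, 4 trials of 90 s
#' (88 s retained) at 250 Hz over 64 electrodes; 0.1-80 Hz broadband and
#' 2-20 Hz analysis bands; 100 microvolt rejection; k searched over 2-8 by
#' the Krzanowski-Lai criterion; 5000 bootstrap resamples.
#'
#' @param ... Named overrides applied on top of the defaults, as nested
#'   lists (e.g. `simulate = list(n_subjects = 10)`).
#' @return A `ms_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    version = "1",
    seed = 1,
    simulate = list(
      n_subjects = 40, n_trials = 4, trial_s = 90, srate = 250,
      n_electrodes = 64, k = 4, snr = 2, signal_rms_uv = 15,
      alpha_amp_neutral = 1.2, alpha_amp_change = 0.4,
      dwell_shape = 4, dwell_subject_sd = 0.05,
      effects = "default"            # "default" or "null"
    ),
    preprocess = list(
      broadband = c(0.1, 80), analysis_band = c(2, 20),
      epoch_window = c(-1, 90), baseline = c(-1, 0), select = c(1, 89),
      segment_s = 1, reject_uv = 100, reject_criterion = "both",
      resample_hz = 250, posterior_set = default_posterior_set(),
      alpha_band = c(8, 12), eog_correction = FALSE
    ),
    microstate = list(
      k_range = c(2, 8), n_restarts = 20, max_iter = 100, tol = 1e-7,
      k_fixed = NULL, select_subjects = 8, min_peak_distance = 0,
      label_by = "truth", include_truncated = TRUE
    ),
    stats = list(n_boot = 5000, conf_level = 0.95)
  )
  modifyList(cfg, list(...))
}

#' Validate a pipeline configuration
#'
#' Checks types, ranges and key names; unknown keys are rejected. Returns
#' invisibly `TRUE` on success, otherwise raises an error listing every
#' problem found.
#'
#' @param config A config list (or path to a YAML file holding one).
#' @return `TRUE` invisibly if valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  ref <- default_config()
  errs <- character()
  check_keys <- function(x, ref, prefix = "") {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown)) {
      errs <<- c(errs, paste0("unknown key(s): ",
                              paste0(prefix, unknown, collapse = ", ")))
    }
    for (k in intersect(names(x), names(ref))) {
      if (is.list(ref[[k]]) && is.list(x[[k]])) {
        check_keys(x[[k]], ref[[k]], paste0(prefix, k, "."))
      }
    }
  }
  check_keys(config, ref)
  sim <- config$simulate; pre <- config$preprocess; ms <- config$microstate
  if (!is.null(sim$n_subjects) && sim$n_subjects < 3) {
    errs <- c(errs, "simulate.n_subjects must be >= 3")
  }
  if (!is.null(sim$snr) && sim$snr <= 0) {
    errs <- c(errs, "simulate.snr must be positive")
  }
  if (!is.null(ms$k_range)) {
    if (length(ms$k_range) != 2 || ms$k_range[1] < 2 ||
        ms$k_range[2] < ms$k_range[1]) {
      errs <- c(errs, "microstate.k_range must be c(kmin, kmax) with kmin >= 2")
    }
  }
  if (!is.null(pre$reject_uv) && pre$reject_uv <= 0) {
    errs <- c(errs, "preprocess.reject_uv must be positive")
  }
  if (!is.null(pre$broadband) &&
      (pre$broadband[1] < 0 || pre$broadband[2] <= pre$broadband[1])) {
    errs <- c(errs, "preprocess.broadband must be an increasing band")
  }
  if (length(errs)) {
    abort(paste0("invalid configuration:\n  - ",
                 paste(errs, collapse = "\n  - ")))
  }
  invisible(TRUE)
}

#' Read / write a configuration file
#'
#' Plain YAML; [validate_config()] is applied on read.
#'
#' @param path YAML file path.
#' @param config A config list.
#' @return `read_config()` returns the config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml collapses numeric vectors fine, but ensure doubles
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Preprocess one recording into analysis-ready epoch sets
#'
#' Applies the canonical order: broadband band-pass, epoch/baseline around
#' trial onsets with the select window, (optional EOG regression), 1 s
#' segmentation, amplitude rejection, downsampling, then a broadband copy
#' is kept for alpha power before the analysis band-pass and average
#' reference are applied for microstate analysis.
#'
#' @param recording An `eeg_recording` with onsets set.
#' @param config A pipeline config (only the `preprocess` entry is used).
#' @return List with `microstate` (analysis-band, average-referenced 1 s
#'   epochs) and `broadband` (post-rejection, pre-analysis-band epochs for
#'   spectral measures), plus `n_rejected`.
#' @export
preprocess_recording <- function(recording, config = default_config()) {
  p <- config$preprocess
  rec <- bandpass(recording, p$broadband[1], p$broadband[2])
  ep <- epoch_and_baseline(rec, t_min_s = p$epoch_window[1],
                           t_max_s = p$epoch_window[2],
                           baseline = p$baseline, select = p$select)
  ep <- segment_1s(ep, p$segment_s)
  n_before <- n_epochs(ep)
  ep <- reject_amplitude(ep, p$reject_uv, p$reject_criterion)
  ep <- downsample(ep, p$resample_hz)
  broadband <- ep
  ms <- bandpass(ep, p$analysis_band[1], p$analysis_band[2])
  ms <- average_reference(ms)
  list(microstate = ms, broadband = broadband,
       n_rejected = n_before - n_epochs(ep))
}

#' Fit individual-level microstate templates
#'
#' Extracts the GFP-peak maps of an epoch set and clusters them with the
#' polarity-invariant modified k-means, either at a fixed k or at the k
#' chosen by the Krzanowski-Lai criterion.
#'
#' @param epochset Analysis-ready `eeg_epochs`.
#' @param k Fixed number of classes, or `NULL` to select by KL.
#' @param k_range Search range when selecting.
#' @param n_restarts,max_iter,tol,seed Clustering controls.
#' @return An `ms_templates` (level `"individual"`) with the peak count in
#'   `$n_peaks` and, when selected, the KL curve in `$kl`.
#' @export
fit_individual_templates <- function(epochset, k = 4, k_range = c(2, 8),
                                     n_restarts = 20, max_iter = 100,
                                     tol = 1e-7, seed = NULL) {
  g <- gfp_series(epochset)
  peaks <- detect_gfp_peaks(g$gfp, g$epoch)
  L <- ncol(epochset$epochs[[1]])
  pm <- t(vapply(peaks, function(pk) {
    e <- ((pk - 1) %/% L) + 1
    s <- ((pk - 1) %% L) + 1
    epochset$epochs[[e]][, s]
  }, numeric(length(epochset$channel_names))))
  kl <- NULL
  if (is.null(k)) {
    sel <- select_k_kl(pm, k_range, n_restarts, max_iter, tol, seed = seed)
    k <- sel$chosen_k
    fit <- sel$fits[[as.character(k)]]
    kl <- sel$kl_curve
  } else {
    fit <- modified_kmeans(pm, k, n_restarts, max_iter, tol, seed = seed)
  }
  tpl <- new_ms_templates(fit$templates, epochset$channel_names,
                          level = "individual", chosen_k = k, kl = kl)
  tpl$n_peaks <- nrow(pm)
  tpl$ev <- fit$ev
  tpl
}

#' Run the full pipeline and write an artifact directory
#'
#' Simulate -> preprocess -> microstate -> statistics, writing a
#' deterministic artifact layout under `out_dir`: `behaviour.csv`,
#' `truth_params.csv`, `templates/` (overall and condition maps + JSON),
#' `segmentations/` (per-sample labels), `params.csv`, `cohort.csv`,
#' `report.json`, `config.yaml` and `log.txt`. Re-running with the same
#' config and seed reproduces `params.csv` and `report.json` byte for
#' byte.
#'
#' @param config A pipeline config (see [default_config()]); validated
#'   before the run.
#' @param out_dir Output directory (created if needed).
#' @param write_recordings Also write the raw simulated recordings
#'   (float32 + JSON sidecar; they are large). Default FALSE.
#' @return Invisibly, a list with the in-memory results: `cohort`,
#'   `templates`, `params`, `cohort_table`, `report`, `chosen_k`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         write_recordings = FALSE) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("templates", "segmentations", "recordings")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  cfg_hash <- digest::digest(config)
  logf <- file.path(out_dir, "log.txt")
  cat(sprintf("pipeline start  config_hash=%s  seed=%d\n", cfg_hash,
              config$seed), file = logf)
  log_stage <- function(fmt, ...) {
    cat(sprintf(paste0("[%s] ", fmt, "\n"),
                format(Sys.time(), "%H:%M:%S"), ...),
        file = logf, append = TRUE)
  }
  sim <- config$simulate
  montage <- standard_montage(sim$n_electrodes)
  effects <- if (identical(sim$effects, "null")) null_effects()
  else default_effects()
  truth <- make_ground_truth(
    montage = montage, k = sim$k, dwell_shape = sim$dwell_shape,
    alpha_amp = c(neutral = sim$alpha_amp_neutral,
                  smoking = sim$alpha_amp_neutral + sim$alpha_amp_change),
    snr = sim$snr, signal_rms_uv = sim$signal_rms_uv,
    dwell_subject_sd = sim$dwell_subject_sd,
    seed = config$seed + 17)
  cohort <- generate_cohort(
    n_subjects = sim$n_subjects, truth = truth, effect_config = effects,
    n_trials = sim$n_trials, trial_s = sim$trial_s, srate = sim$srate,
    signal = "eeg", seed = config$seed)
  log_stage("simulated %d recordings (%d subjects)",
            length(cohort$recordings), sim$n_subjects)
  write.csv(cohort$behaviour, file.path(out_dir, "behaviour.csv"),
            row.names = FALSE)
  write.csv(cohort$truth_params, file.path(out_dir, "truth_params.csv"),
            row.names = FALSE)
  write_montage(montage, file.path(out_dir, "montage.txt"))

  p <- config$preprocess
  cfg2 <- config
  cfg2$preprocess$epoch_window <- c(-1, sim$trial_s)
  cfg2$preprocess$select <- c(1, sim$trial_s - 1)
  prep <- list()
  for (key in names(cohort$recordings)) {
    rec <- cohort$recordings[[key]]
    if (write_recordings) {
      write_recording(rec, file.path(out_dir, "recordings", key))
    }
    prep[[key]] <- preprocess_recording(rec, cfg2)
  }
  log_stage("preprocessed %d recordings (epochs kept: %s)",
            length(prep),
            paste(vapply(prep, function(x) n_epochs(x$microstate),
                         integer(1)), collapse = ","))

  msc <- config$microstate
  # individual-level template fitting; KL selection on a subset of
  # subject/conditions, then a consensus k for everyone
  keys <- names(prep)
  chosen_k <- msc$k_fixed
  if (is.null(chosen_k)) {
    sel_keys <- keys[seq_len(min(msc$select_subjects, length(keys)))]
    ks <- vapply(seq_along(sel_keys), function(i) {
      fit_individual_templates(prep[[sel_keys[i]]]$microstate, k = NULL,
                               k_range = msc$k_range,
                               n_restarts = msc$n_restarts,
                               seed = config$seed + i)$chosen_k
    }, numeric(1))
    chosen_k <- as.integer(names(sort(table(ks), decreasing = TRUE))[1])
    log_stage("KL-selected k per individual: %s -> consensus k = %d",
              paste(ks, collapse = ","), chosen_k)
  }
  indiv <- lapply(seq_along(keys), function(i) {
    fit_individual_templates(prep[[keys[i]]]$microstate, k = chosen_k,
                             n_restarts = msc$n_restarts,
                             seed = config$seed + 1000 + i)
  })
  names(indiv) <- keys
  by_cond <- split(indiv, sub("^.*_", "", keys))
  ref <- if (identical(msc$label_by, "truth")) truth$templates
  lvl <- build_level_templates(by_cond, montage, montage$name,
                               canonical_labels = TRUE, reference = ref)
  log_stage("templates built (overall level), k = %d", chosen_k)
  write_templates(lvl$overall, file.path(out_dir, "templates", "overall"))
  for (cn in names(lvl$condition)) {
    write_templates(lvl$condition[[cn]],
                    file.path(out_dir, "templates", cn))
  }

  params <- list(); alpha <- list()
  for (key in keys) {
    seg <- backfit(prep[[key]]$microstate, lvl$overall,
                   min_peak_distance = msc$min_peak_distance)
    pr <- compute_parameters(seg, include_truncated = msc$include_truncated)
    pr$gev <- compute_gev(seg)
    pr$subject <- sub("_[^_]+$", "", key)
    pr$condition <- sub("^.*_", "", key)
    params[[key]] <- pr
    ap <- posterior_alpha_power(prep[[key]]$broadband, p$posterior_set,
                                p$alpha_band)
    alpha[[key]] <- tibble(subject = pr$subject[1],
                           condition = pr$condition[1],
                           alpha_power = ap$power)
    writeLines(as.character(seg$labels),
               file.path(out_dir, "segmentations", paste0(key, ".txt")))
  }
  params <- dplyr::bind_rows(params)
  alpha <- dplyr::bind_rows(alpha)
  params_out <- params[, c("subject", "condition", "class", "duration_ms",
                           "occurrence_per_s", "contribution", "gev")]
  write.csv(params_out, file.path(out_dir, "params.csv"), row.names = FALSE)
  log_stage("backfit + parameters done (%d rows)", nrow(params_out))

  cohort_table <- build_cohort_table(params, alpha, cohort$behaviour)
  write.csv(cohort_table, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  report <- analyze_cohort(cohort_table, n_boot = config$stats$n_boot,
                           conf_level = config$stats$conf_level,
                           seed = config$seed)
  write_report(report, file.path(out_dir, "report.json"))
  write_config(config, file.path(out_dir, "config.yaml"))
  log_stage("report written; pipeline done")
  invisible(list(cohort = cohort, templates = lvl, params = params,
                 alpha = alpha, cohort_table = cohort_table,
                 report = report, chosen_k = chosen_k,
                 config_hash = cfg_hash))
}
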