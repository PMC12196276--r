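# End-to-end orchestration: synthesize (or read) a cohort, preprocess,
# extract biomechanical and neurophysiological indicators, group by
# coherence median split, compare groups, classify, and write all reports
# with a content-hash manifest.

#' Pipeline configuration
#'
#' @param synthetic use the synthetic-cohort generator (`TRUE`, default) or
#'   read data from `data_dir` written in the package's on-disk formats.
#' @param data_dir input directory when `synthetic = FALSE`.
#' @param out_dir output directory for reports and artifacts.
#' @param synth a [synth_config()] for synthetic runs.
#' @param mains_hz mains frequency for the notch filter (default 60).
#' @param onset_threshold_deg,onset_hold_s movement-onset detector
#'   parameters (defaults 2 degrees, 0.1 s).
#' @param epoch_window epoch window in seconds (default `c(-3, 3)`).
#' @param beta_band coherence/power band in Hz (default `c(14, 20)`).
#' @param band_mode band summary statistic, `"mean"` or `"peak"`.
#' @param baseline_window wavelet baseline window (default `c(-3, -2.5)`).
#' @param power_mode `"absolute"` (default) or `"percent"` beta-power
#'   normalization.
#' @param cv_mode classifier cross-validation ordering (`"faithful"` or
#'   `"leakfree"`).
#' @param bootstrap_sizes classifier augmentation sweep sizes.
#' @param primary_size headline bootstrap size (default 1000).
#' @param run_classifier,run_gait stage toggles.
#' @param eog_regression enable EOG artifact regression (default TRUE).
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = TRUE, data_dir = NULL,
                            out_dir = tempfile("cmcgait_run_"),
                            synth = synth_config(),
                            mains_hz = 60,
                            onset_threshold_deg = 2, onset_hold_s = 0.1,
                            epoch_window = c(-3, 3),
                            beta_band = c(14, 20),
                            band_mode = "mean",
                            baseline_window = c(-3, -2.5),
                            power_mode = "absolute",
                            cv_mode = "faithful",
                            bootstrap_sizes = c(10, seq(100, 1000, by = 100)),
                            primary_size = 1000,
                            run_classifier = TRUE, run_gait = TRUE,
                            eog_regression = TRUE,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (!synthetic && is.null(data_dir))
    stop_cmc("data_dir required when synthetic = FALSE", class = "cmcgait_config_error")
  if (!is.numeric(seed) || length(seed) != 1L)
    stop_cmc("seed must be a single number", class = "cmcgait_config_error")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys are [pipeline_config()] arguments
#' (with a nested `synth` block passed to [synth_config()]).
#'
#' @param path YAML file path.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_yaml <- function(path) {
  if (!file.exists(path))
    stop_cmc("file not found: %s", path, class = "cmcgait_io_error")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synth)) raw$synth <- do.call(synth_config, raw$synth)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_cmc("unknown config key(s): %s", paste(unknown, collapse = ", "),
             class = "cmcgait_config_error")
  do.call(pipeline_config, raw)
}

# Preprocess one subject's raw record: notch, band-passes, EOG regression,
# EMG rectification. Returns the cleaned record.
preprocess_record <- function(record, mains_hz = 60, eog_regression = TRUE) {
  rec <- filter_signal(record, "notch60", mains_hz = mains_hz)
  emg_ch <- intersect(c("TA", "MG"), rec$channels)
  eeg_ch <- setdiff(rec$channels, c(emg_ch, "EOG_up", "EOG_down"))
  rec <- filter_signal(rec, "emg_band", channels = emg_ch)
  rec <- filter_signal(rec, "eeg_band", channels = eeg_ch)
  if (eog_regression && all(c("EOG_up", "EOG_down") %in% rec$channels))
    rec <- regress_eog(rec, eeg_channels = eeg_ch)
  rectify(rec, emg_ch)
}

# Movement-execution segments (0..movement_s after onset) for coherence.
movement_segments <- function(epochs, channel, movement_s = 3) {
  sel <- epochs$time >= 0 & epochs$time < movement_s
  epochs$data[, channel, sel, drop = TRUE]
}

# Cut an angle trace into per-trial segments with time relative to onset.
epoch_angle <- function(trace, onsets, window = c(-1, 4)) {
  lapply(onsets, function(t0) {
    sel <- trace$time >= t0 + window[1] - 1e-9 & trace$time <= t0 + window[2] + 1e-9
    angle_trace(trace$time[sel] - t0, trace$dorsiflexion[sel],
                trace$inversion[sel], trace$rate)
  })
}

# Analyse one subject's dorsiflexion-task data end to end.
analyze_subject <- function(record, angle, cfg, subject = NA_character_,
                            onsets = NULL) {
  rec <- preprocess_record(record, cfg$mains_hz, cfg$eog_regression)
  if (is.null(onsets))
    onsets <- detect_onset(angle, threshold_deg = cfg$onset_threshold_deg,
                           min_hold_s = cfg$onset_hold_s)
  if (length(onsets) == 0)
    stop_cmc("no movement onsets detected for subject %s", subject,
             class = "cmcgait_epoching_error")
  # epoch with a wavelet buffer margin; crop after convolution so no
  # analysis window touches a reflection-padded edge
  margin <- 0.35
  epochs <- epoch_trials(rec, onsets,
                         window = cfg$epoch_window + c(-margin, margin))
  spec <- estimate_msc(movement_segments(epochs, "Cz"),
                       movement_segments(epochs, "TA"), rate = rec$rate)
  cmc <- band_summary(spec, band = cfg$beta_band, mode = cfg$band_mode,
                      subject = subject)
  series <- morlet_power(epochs, channel = "Cz",
                         freqs = seq(cfg$beta_band[1], cfg$beta_band[2]))
  series <- crop_series(series, cfg$epoch_window)
  series <- baseline_normalize(series, mode = cfg$power_mode,
                               baseline_window = cfg$baseline_window)
  feats <- window_features(series)
  ang_trials <- epoch_angle(angle, onsets)
  biomech <- dorsiflexion_metrics(ang_trials)
  list(subject = subject, onsets = onsets, spectrum = spec, cmc = cmc,
       beta_series = series, features = feats, biomech = biomech)
}

#' Run the full pipeline
#'
#' Stages, in order: ingest or synthesize -> preprocess -> biomechanics ->
#' coherence -> median split -> time-frequency features -> group statistics
#' -> classifier. Each stage's outputs are written under `out_dir` before
#' the next starts, and a manifest lists every artifact with its MD5
#' content hash.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return list with `out_dir`, `truth` (synthetic runs), `cmc_values`,
#'   `groups`, `feature_table`, `group_stats`, `classifier`, `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  artifacts <- character(0)
  put <- function(path) { artifacts <<- c(artifacts, path); path }

  # --- stage: ingest / synthesize -----------------------------------------
  if (cfg$synthetic) {
    log_msg("stage synthesize: %d subjects", cfg$synth$n_high + cfg$synth$n_low)
    cohort <- synth_cohort_signals(cfg$synth)
    gait <- if (cfg$run_gait) synth_gait_trials(cfg$synth) else NULL
    truth <- cohort$truth
    utils::write.csv(truth, put(file.path(cfg$out_dir, "ground_truth.csv")),
                     row.names = FALSE)
  } else {
    cohort <- read_cohort_dir(cfg$data_dir)
    gait <- NULL
    truth <- NULL
  }
  subjects <- cohort$subjects

  # --- stage: per-subject analysis ----------------------------------------
  res <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    log_msg("stage analyze: subject %s", s$subject)
    res[[i]] <- tryCatch(
      analyze_subject(s$record, s$angle, cfg, subject = s$subject,
                      onsets = s$onsets),
      error = function(e) stop_cmc("stage analyze failed for subject %s: %s",
                                   s$subject, conditionMessage(e),
                                   class = "cmcgait_stage_error"))
  }
  names(res) <- vapply(res, `[[`, character(1), "subject")

  # --- stage: coherence summaries + median split --------------------------
  cmc_values <- vapply(res, function(r) r$cmc$value, numeric(1))
  groups <- median_split(cmc_values)
  split_df <- data.frame(subject = names(cmc_values), cmc = unname(cmc_values),
                         group = as.character(groups))
  utils::write.table(split_df, put(file.path(cfg$out_dir, "cmc_groups.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # --- stage: feature table -----------------------------------------------
  feature_table <- do.call(rbind, lapply(res, function(r)
    data.frame(subject = r$subject, window = r$features$window,
               value = r$features$value,
               group = as.character(groups[r$subject]))))
  rownames(feature_table) <- NULL
  write_feature_tsv(feature_table, put(file.path(cfg$out_dir, "features.tsv")))

  # --- stage: biomechanics + group statistics -----------------------------
  biomech_df <- do.call(rbind, lapply(res, function(r)
    data.frame(subject = r$subject, t(r$biomech$mean))))
  if (cfg$run_gait && !is.null(gait)) {
    gm <- lapply(gait$subjects, function(g) {
      cycles <- epoch_gait(g$angle, g$ic_times, g$to_times)
      gait_metrics(cycles, pass_length_m = g$pass_length_m,
                   pass_times_s = g$pass_times_s)
    })
    biomech_df <- cbind(biomech_df, do.call(rbind, lapply(gm, function(m)
      as.data.frame(t(m$mean)))))
  }
  rownames(biomech_df) <- NULL
  utils::write.csv(biomech_df, put(file.path(cfg$out_dir, "biomech.csv")),
                   row.names = FALSE)
  metrics <- setdiff(names(biomech_df), "subject")
  hi <- biomech_df$subject %in% split_df$subject[split_df$group == "high"]
  group_stats <- list()
  if (sum(hi) >= 3 && sum(!hi) >= 3) {
    group_stats <- lapply(metrics, function(mname) {
      v <- biomech_df[[mname]]
      compare_groups(v[hi], v[!hi], metric = mname)
    })
    names(group_stats) <- metrics
    # beta-power group comparison in the late preparation window
    prep <- feature_table[feature_table$window == "-500~0 ms", ]
    group_stats[["beta_power_-500~0ms"]] <-
      compare_groups(prep$value[prep$group == "high"],
                     prep$value[prep$group == "low"],
                     metric = "beta_power_-500~0ms")
  } else {
    log_msg("stage groupstats skipped: fewer than 3 subjects per group")
  }
  stats_report <- lapply(group_stats, function(g)
    list(metric = g$metric, test = g$test, statistic = g$statistic,
         p_value = g$p_value, effect_size_d = g$effect_size_d,
         significant = g$significant,
         mean_high = unname(g$means["high"]), sd_high = unname(g$sds["high"]),
         mean_low = unname(g$means["low"]), sd_low = unname(g$sds["low"])))
  write_report_json(list(kind = "group_statistics", results = stats_report),
                    put(file.path(cfg$out_dir, "group_stats.json")))

  # --- stage: classifier ---------------------------------------------------
  classifier <- NULL
  if (cfg$run_classifier) {
    log_msg("stage classify: %s CV, primary size %d", cfg$cv_mode, cfg$primary_size)
    classifier <- window_sweep(feature_table, sizes = cfg$bootstrap_sizes,
                               seed = cfg$seed, cv_mode = cfg$cv_mode,
                               primary_size = cfg$primary_size)
    write_report_json(list(kind = "classifier", cv_mode = classifier$cv_mode,
                           folds = classifier$folds, seed = classifier$seed,
                           primary_size = classifier$primary_size,
                           results = classifier$results),
                      put(file.path(cfg$out_dir, "classifier.json")))
  }

  # --- manifest ------------------------------------------------------------
  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)))
  write_report_json(list(kind = "manifest", files = manifest),
                    file.path(cfg$out_dir, "manifest.json"))
  list(out_dir = cfg$out_dir, truth = truth, cmc_values = cmc_values,
       groups = groups, feature_table = feature_table,
       biomech = biomech_df, group_stats = group_stats,
       classifier = classifier, manifest = manifest)
}

# Read a cohort from disk: one subdirectory per subject containing
# signals.csv, angles.csv and events.tsv (onset rows).
read_cohort_dir <- function(dir) {
  subdirs <- list.dirs(dir, recursive = FALSE)
  if (!length(subdirs))
    stop_cmc("no subject directories under %s", dir, class = "cmcgait_io_error")
  subjects <- lapply(subdirs, function(d) {
    rec <- read_signals(file.path(d, "signals.csv"))
    ang <- read_angle_csv(file.path(d, "angles.csv"))
    ev <- read_event_tsv(file.path(d, "events.tsv"))
    list(subject = basename(d), record = rec, angle = ang,
         onsets = ev$time[ev$label == "onset"])
  })
  names(subjects) <- basename(subdirs)
  list(subjects = subjects, truth = NULL)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Materializes a generated cohort as one directory per subject with
#' `signals.csv`, `angles.csv` and `events.tsv`, so a pipeline run on disk
#' input is indistinguishable from a synthetic in-memory run.
#'
#' @param cohort result of [synth_cohort_signals()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    d <- file.path(dir, s$subject)
    dir.create(d, showWarnings = FALSE)
    write_signal_csv(s$record, file.path(d, "signals.csv"))
    write_angle_csv(s$angle, file.path(d, "angles.csv"))
    write_event_tsv(event_table(rep("onset", length(s$onsets)), s$onsets,
                                seq_along(s$onsets)),
                    file.path(d, "events.tsv"))
  }
  invisible(dir)
}
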