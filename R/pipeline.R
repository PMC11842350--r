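# End-to-end pipeline and on-disk dataset format.
#
# A dataset directory holds, per trial, a motion CSV (t, box_height,
# box_velocity, angle, load_force), an EMG CSV (t + six channels) and a JSON
# sidecar (sampling rates, condition, subject, load mass, iMVC peaks), plus
# subjects.json and a manifest. Stage outputs (summaries.csv, rnle.csv,
# calibration.json, stats.json, clusters.json, manifest.json) are written to
# the output directory so every stage is independently re-runnable.

#' Pipeline configuration
#'
#' @param output_dir Directory for all stage outputs (created if missing).
#' @param seed Single global seed; per-stage seeds derive from it.
#' @param generator A [generator_config()] (its seed is overridden by
#'   `seed`).
#' @param calibration A [calibration_config()] template (its seed is derived
#'   per subject from `seed`).
#' @param k Number of clusters for the compression re-stratification.
#' @param write_dataset Also write the generated dataset under
#'   `output_dir/dataset`.
#' @param make_figures Write violin/scatter figures (requires ggplot2).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, seed = 1L,
                            generator = generator_config(),
                            calibration = calibration_config(),
                            k = 6L, write_dataset = TRUE,
                            make_figures = FALSE) {
  generator$seed <- as.integer(seed)
  list(output_dir = output_dir, seed = as.integer(seed),
       generator = generator, calibration = calibration, k = as.integer(k),
       write_dataset = isTRUE(write_dataset),
       make_figures = isTRUE(make_figures))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

#' Write a synthetic dataset to a directory
#'
#' @param dataset A `lift_dataset` from [generate_dataset()].
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subj_meta <- lapply(dataset$subjects, function(s)
    list(body_mass = s$body_mass, height = s$height))
  write_json_file(subj_meta, file.path(dir, "subjects.json"))
  write_json_file(dataset$true_params, file.path(dir, "ground_truth.json"))
  ids <- character(0)
  for (tr in dataset$trials) {
    id <- sprintf("%s_L%d_R%d", tr$subject_id, tr$li_level, tr$repetition)
    ids <- c(ids, id)
    motion <- data.frame(t = ts_time(tr$motion), tr$motion$values,
                         check.names = FALSE)
    write.csv(motion, file.path(dir, paste0(id, "_motion.csv")),
              row.names = FALSE)
    emg <- data.frame(t = ts_time(tr$emg), tr$emg$values,
                      check.names = FALSE)
    write.csv(emg, file.path(dir, paste0(id, "_emg.csv")),
              row.names = FALSE)
    sidecar <- list(subject_id = tr$subject_id, li_level = tr$li_level,
                    repetition = tr$repetition, load_mass = tr$load_mass,
                    fs_motion = tr$fs_motion, fs_emg = tr$fs_emg,
                    emg_is_envelope = tr$emg_is_envelope,
                    imvc_peaks = tr$imvc_peaks,
                    task = unclass(tr$task))
    write_json_file(sidecar, file.path(dir, paste0(id, ".json")))
  }
  write_json_file(list(trials = ids, seed = dataset$cfg$seed,
                       n_subjects = length(dataset$subjects)),
                  file.path(dir, "manifest.json"))
  invisible(dir)
}

read_trial <- function(dir, id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(id, ".json")),
                              simplifyVector = TRUE)
  motion <- read.csv(file.path(dir, paste0(id, "_motion.csv")))
  emg <- read.csv(file.path(dir, paste0(id, "_emg.csv")))
  task <- do.call(lifting_task, meta$task[c("load_mass", "H", "V", "D",
                                            "A", "F", "duration_class",
                                            "coupling")])
  structure(list(
    subject_id = meta$subject_id, li_level = meta$li_level,
    repetition = meta$repetition, task = task, load_mass = meta$load_mass,
    fs_motion = meta$fs_motion, fs_emg = meta$fs_emg,
    motion = lift_ts(as.matrix(motion[, -1L]), meta$fs_motion,
                     motion$t[1L]),
    emg = lift_ts(as.matrix(emg[, -1L]), meta$fs_emg, emg$t[1L]),
    emg_is_envelope = isTRUE(meta$emg_is_envelope),
    imvc_peaks = meta$imvc_peaks,
    ground_truth = NULL), class = "lift_trial")
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `lift_dataset` (without ground-truth series).
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  subj_meta <- jsonlite::read_json(file.path(dir, "subjects.json"),
                                   simplifyVector = TRUE)
  subjects <- lapply(subj_meta, function(s) subject(s$body_mass, s$height))
  trials <- lapply(manifest$trials, function(id) read_trial(dir, id))
  structure(list(subjects = subjects, models = NULL, true_params = NULL,
                 conditions = NULL, trials = trials,
                 cfg = list(seed = manifest$seed)),
            class = "lift_dataset")
}

#' Validate a dataset directory
#'
#' Schema check of every trial CSV/JSON triple; reports (rather than stops
#' on) missing files, malformed sidecars and missing channels.
#'
#' @param dir Dataset directory.
#' @return Data frame with columns `trial`, `issue` (zero rows when clean);
#'   an empty directory yields a single `empty-dataset` warning row.
#' @export
validate_dataset <- function(dir) {
  issues <- data.frame(trial = character(0), issue = character(0),
                       stringsAsFactors = FALSE)
  add <- function(trial, issue)
    rbind(issues, data.frame(trial = trial, issue = issue,
                             stringsAsFactors = FALSE))
  if (!file.exists(file.path(dir, "manifest.json")))
    return(add("-", "empty-dataset: no manifest.json found"))
  manifest <- tryCatch(
    jsonlite::read_json(file.path(dir, "manifest.json"),
                        simplifyVector = TRUE),
    error = function(e) NULL)
  if (is.null(manifest) || length(manifest$trials) == 0)
    return(add("-", "empty-dataset: manifest lists no trials"))
  motion_cols <- c("t", "box_height", "box_velocity", "angle", "load_force")
  for (id in manifest$trials) {
    for (suffix in c("_motion.csv", "_emg.csv", ".json")) {
      f <- file.path(dir, paste0(id, suffix))
      if (!file.exists(f)) issues <- add(id, paste0("missing file: ",
                                                    basename(f)))
    }
    mf <- file.path(dir, paste0(id, "_motion.csv"))
    if (file.exists(mf)) {
      cols <- names(read.csv(mf, nrows = 1L))
      missing <- setdiff(motion_cols, cols)
      if (length(missing))
        issues <- add(id, paste0("missing motion channels: ",
                                 paste(missing, collapse = ", ")))
    }
    jf <- file.path(dir, paste0(id, ".json"))
    if (file.exists(jf)) {
      meta <- tryCatch(jsonlite::read_json(jf, simplifyVector = TRUE),
                       error = function(e) NULL)
      if (is.null(meta)) {
        issues <- add(id, "malformed sidecar JSON")
      } else {
        need <- c("subject_id", "li_level", "fs_motion", "fs_emg",
                  "imvc_peaks")
        absent <- need[!need %in% names(meta)]
        if (length(absent))
          issues <- add(id, paste0("sidecar missing fields: ",
                                   paste(absent, collapse = ", ")))
      }
    }
  }
  issues
}

stage <- function(name, log, expr) {
  t0 <- Sys.time()
  message(sprintf("[liftload] stage %s ...", name))
  res <- tryCatch(force(expr), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  log[[name]] <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                       2)
  list(result = res, log = log)
}

#' Run the full analysis pipeline
#'
#' Generate -> segment/process -> RNLE -> calibrate (low + high risk trials)
#' -> estimate loads (all trials) -> summarize -> risk statistics ->
#' cluster re-stratification, with all stage outputs written to
#' `cfg$output_dir` and a manifest (config echo, per-stage timings, output
#' checksums).
#'
#' @param cfg A [pipeline_config()].
#' @return List with `summaries`, `stats`, `clusters`, `calibrations`,
#'   `rnle`, `manifest` (also written to disk).
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()

  st <- stage("generate", timings, generate_dataset(cfg$generator))
  dataset <- st$result; timings <- st$log
  if (cfg$write_dataset)
    write_dataset(dataset, file.path(cfg$output_dir, "dataset"))

  st <- stage("rnle", timings, {
    tab <- do.call(rbind, lapply(seq_along(dataset$conditions), function(i) {
      res <- rnle_assess(dataset$conditions[[i]])
      data.frame(condition = i, load_mass = dataset$conditions[[i]]$load_mass,
                 H = dataset$conditions[[i]]$H, V = dataset$conditions[[i]]$V,
                 D = dataset$conditions[[i]]$D, RWL = res$RWL, LI = res$LI,
                 risk_level = res$risk_level)
    }))
    write.csv(tab, file.path(cfg$output_dir, "rnle.csv"), row.names = FALSE)
    tab
  })
  rnle_tab <- st$result; timings <- st$log

  st <- stage("process", timings,
              lapply(dataset$trials, function(tr)
                process_trial(tr, dataset$subjects[[tr$subject_id]])))
  processed <- st$result; timings <- st$log

  st <- stage("calibrate", timings, {
    out <- list()
    for (i in seq_along(dataset$subjects)) {
      sid <- names(dataset$subjects)[i]
      ptr <- Filter(function(p) p$subject_id == sid, processed)
      ccfg <- cfg$calibration
      ccfg$seed <- cfg$seed * 100L + i
      model0 <- trunk_model(dataset$subjects[[sid]])
      out[[sid]] <- calibrate(model0, ptr, ccfg)
    }
    write_json_file(lapply(out, function(r)
      list(objective = r$objective, initial_objective = r$initial_objective,
           converged = r$converged, iterations = r$iterations,
           seed = r$seed, params = r$params)),
      file.path(cfg$output_dir, "calibration.json"))
    out
  })
  calibrations <- st$result; timings <- st$log

  st <- stage("loads", timings, {
    rows <- lapply(processed, function(p) {
      loads <- estimate_trial_loads(calibrations[[p$subject_id]]$model, p)
      summarize_trial(p, loads)
    })
    summaries <- do.call(rbind, rows)
    write.csv(summaries, file.path(cfg$output_dir, "summaries.csv"),
              row.names = FALSE)
    summaries
  })
  summaries <- st$result; timings <- st$log

  st <- stage("stats", timings, {
    metrics <- c("rom_deg", grep("^peak_", names(summaries), value = TRUE))
    stats <- lapply(metrics, function(m) {
      normality <- lapply(sort(unique(summaries$li_level)), function(lev) {
        vals <- summaries[[m]][summaries$li_level == lev]
        res <- tryCatch(normality_test(vals), error = function(e)
          list(W = NA, p = NA))
        c(level = lev, res)
      })
      list(metric = m, normality = normality,
           wilcoxon = wilcoxon_pairwise(summaries, m))
    })
    names(stats) <- metrics
    write_json_file(stats, file.path(cfg$output_dir, "stats.json"))
    stats
  })
  stats <- st$result; timings <- st$log

  st <- stage("cluster", timings, {
    report <- cluster_loads(summaries, k = cfg$k, seed = cfg$seed + 9000L)
    sil <- silhouette_scan(summaries, seed = cfg$seed + 9000L)
    write_json_file(list(k = report$k,
                         centroids = as.data.frame(report$centroids),
                         sizes = report$sizes,
                         crosstab = as.data.frame.matrix(report$crosstab),
                         t_table = report$t_table,
                         silhouette = sil),
                    file.path(cfg$output_dir, "clusters.json"))
    list(report = report, silhouette = sil)
  })
  clusters <- st$result; timings <- st$log

  if (cfg$make_figures && requireNamespace("ggplot2", quietly = TRUE)) {
    try(save_pipeline_figures(summaries, clusters$report, cfg$output_dir),
        silent = TRUE)
  }

  outputs <- list.files(cfg$output_dir, pattern = "\\.(csv|json)$",
                        full.names = TRUE)
  manifest <- list(seed = cfg$seed,
                   generator = cfg$generator,
                   calibration = cfg$calibration[c("adjustable",
                                                   "calibration_levels",
                                                   "restarts", "maxit")],
                   k = cfg$k,
                   timings_s = timings,
                   checksums = as.list(tools::md5sum(outputs)),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  write_json_file(manifest, file.path(cfg$output_dir, "manifest.json"))

  invisible(list(summaries = summaries, stats = stats,
                 clusters = clusters$report,
                 silhouette = clusters$silhouette,
                 calibrations = calibrations, rnle = rnle_tab,
                 dataset = dataset, manifest = manifest))
}

#' Violin and scatter figures for a pipeline run
#'
#' @param summaries Trial summaries.
#' @param report A `cluster_report`.
#' @param dir Output directory.
#' @return Paths of the written figures, invisibly.
#' @export
save_pipeline_figures <- function(summaries, report, dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for figures", call. = FALSE)
  gg <- ggplot2::ggplot(summaries,
                        ggplot2::aes(factor(li_level), peak_compression_bw)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, size = 0.8) +
    ggplot2::labs(x = "Risk level (lifting index)",
                  y = "Peak compression (x BW)")
  f1 <- file.path(dir, "compression_by_level.pdf")
  ggplot2::ggsave(f1, gg, width = 5, height = 4)
  df <- data.frame(moment = summaries$peak_moment_norm,
                   compression = summaries$peak_compression_bw,
                   cluster = factor(report$assignments))
  gg2 <- ggplot2::ggplot(df, ggplot2::aes(moment, compression, colour = cluster)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Peak moment (N m/kg)", y = "Peak compression (x BW)")
  f2 <- file.path(dir, "clusters.pdf")
  ggplot2::ggsave(f2, gg2, width = 5, height = 4)
  invisible(c(f1, f2))
}
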