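# File formats and the pipeline entry point.
#
# Traces are delimited text with mandatory unit-suffixed column names
# (`time_s,length_mm,force_mN,stim`) and a structured key-value metadata
# sidecar (`<stem>.meta.yaml`).  Loop metrics are always recomputed from
# the raw samples, never trusted from disk.

TRACE_COLUMNS <- c("time_s", "length_mm", "force_mN", "stim")

sidecar_path <- function(path) {
  paste0(sub("\\.[^.]+$", "", path), ".meta.yaml")
}

#' Write a trace to disk
#'
#' Writes the samples as CSV and the metadata as a YAML sidecar next to it.
#'
#' @param trace A [wl_trace()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "wl_trace"))
  df <- as.data.frame(trace)
  readr::write_csv(df, path)
  m <- trace$meta
  yaml::write_yaml(list(
    mass_kg = m$mass_kg, lmax_mm = m$l_max_mm, l0_mm = m$l0_mm,
    strain = m$strain, cycle_freq_hz = m$cycle_freq_hz,
    density_kg_m3 = m$density_kg_m3, sampling_rate_hz = m$sampling_rate_hz,
    treatment = m$treatment,
    dose = if (is.na(m$dose)) NULL else m$dose,
    pulse_width_ms = m$stimulus$pulse_width_ms,
    current_mA = m$stimulus$current_mA), sidecar_path(path))
  invisible(path)
}

#' Read a trace from disk
#'
#' Reads a CSV trace plus its metadata sidecar and returns a validated
#' [wl_trace()].  Rejections are descriptive: a missing column is named, a
#' shuffled time column is reported as non-monotone, and metadata units
#' are taken from the mandatory column-name suffixes.
#'
#' @param path CSV path written by [write_trace()] (or by the rig export).
#' @return A [wl_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such trace file: %s", path), call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(TRACE_COLUMNS, names(df))
  if (length(missing))
    stop(sprintf("trace %s is missing column '%s'", basename(path), missing[1]),
         call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("metadata sidecar not found: %s", sc), call. = FALSE)
  m <- yaml::read_yaml(sc)
  meta <- wl_meta(mass_kg = m$mass_kg, l_max_mm = m$lmax_mm,
                  l0_mm = m$l0_mm %||% (0.9 * m$lmax_mm),
                  strain = m$strain %||% 0.04,
                  cycle_freq_hz = m$cycle_freq_hz %||% 6,
                  density_kg_m3 = m$density_kg_m3 %||% 1060,
                  sampling_rate_hz = m$sampling_rate_hz %||% 10000,
                  treatment = m$treatment %||% "unknown",
                  dose = m$dose %||% NA_character_,
                  stimulus = wl_stimulus(
                    pulse_width_ms = m$pulse_width_ms %||% 1.0,
                    current_mA = m$current_mA %||% 120))
  wl_trace(df$time_s, df$length_mm, df$force_mN, df$stim, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export every trace of a simulated study
#'
#' Writes one CSV + sidecar per loop recording, named
#' `<arm>_<prep_id>_t<time>min.csv`.
#'
#' @param data A `wl_study_data` simulated with `keep_traces = TRUE`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_study_traces <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (p in c(data$drug, data$vehicle)) {
    if (is.null(p$recordings))
      stop("dataset was simulated without traces (keep_traces = FALSE)", call. = FALSE)
    for (nm in names(p$recordings)) {
      tmin <- sub("^t", "", nm)
      f <- file.path(dir, sprintf("%s_%s_t%smin.csv", p$arm, p$prep_id, tmin))
      write_trace(p$recordings[[nm]], f)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}

#' Read a study configuration file
#'
#' Reads a YAML study configuration (keys: preset, n_drug, n_vehicle,
#' seed, and optionally noise, schedule, sampling_rate_hz, n_cycles,
#' threshold, alpha) and returns a [study_config()].
#'
#' @param path YAML path.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (k in c("preset", "n_drug", "n_vehicle", "seed"))
    if (is.null(y[[k]]))
      stop(sprintf("config %s is missing required key '%s'", basename(path), k),
           call. = FALSE)
  noise <- do.call(noise_model, y$noise %||% list())
  schedule <- do.call(wl_schedule, y$schedule %||% list())
  study_config(preset = y$preset, n_drug = y$n_drug,
               n_vehicle = y$n_vehicle, seed = y$seed, noise = noise,
               schedule = schedule,
               sampling_rate_hz = y$sampling_rate_hz %||% 10000,
               n_cycles = y$n_cycles %||% 1,
               threshold = y$threshold %||% 0.20, alpha = y$alpha %||% 0.05,
               keep_traces = y$keep_traces %||% TRUE)
}

#' Run the full pipeline for one study
#'
#' Simulate (or accept a pre-simulated dataset), analyse, and write the
#' artifacts: per-loop metrics, group summary, effect sizes, statistics
#' tables, exclusion log, characteristics and figures.  Every exclusion is
#' logged as a message.  Deterministic under the config seed.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory; `NULL` writes nothing.
#' @param figures Write PNG figures.
#' @param write_traces Also export every raw trace (large).
#' @param data Optional pre-simulated `wl_study_data` matching `config`.
#' @return List with `data` and `result`, invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config, out_dir = NULL, figures = TRUE,
                         write_traces = FALSE, data = NULL) {
  if (is.null(data)) data <- simulate_study(config)
  result <- analyze_study(data)
  for (i in seq_len(nrow(result$exclusions)))
    message(sprintf("excluded %s (%s): %s", result$exclusions$prep_id[i],
                    result$exclusions$arm[i], result$exclusions$reason[i]))
  message(sprintf("inotropy call for %s: %s", config$preset, result$inotropy))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    metrics <- dplyr::bind_rows(lapply(c(data$drug, data$vehicle), function(p)
      dplyr::mutate(p$metrics, prep_id = p$prep_id, arm = p$arm,
                    .before = 1)))
    readr::write_csv(metrics, file.path(out_dir, "loop_metrics.csv"))
    readr::write_csv(result$summary, file.path(out_dir, "group_summary.csv"))
    chars <- prep_characteristics(data)
    readr::write_csv(chars, file.path(out_dir, "characteristics.csv"))
    render_report(result, data, out_dir, figures = figures)
    if (write_traces) write_study_traces(data, file.path(out_dir, "traces"))
  }
  invisible(list(data = data, result = result))
}

#' Analyse a directory of trace files
#'
#' Reads every trace written by [write_study_traces()] (file pattern
#' `<arm>_<prep_id>_t<time>min.csv`), recomputes all loop metrics from the
#' raw samples and assembles a `wl_study_data` ready for
#' [analyze_study()].
#'
#' @param dir Directory of trace CSVs with sidecars.
#' @param schedule A [wl_schedule()].
#' @param threshold,alpha Analysis options.
#' @return A `wl_study_data`.
#' @export
read_trace_dir <- function(dir, schedule = wl_schedule(), threshold = 0.20,
                           alpha = 0.05) {
  files <- list.files(dir, pattern = "^(drug|vehicle)_.+_t[0-9.]+min\\.csv$",
                      full.names = TRUE)
  if (!length(files)) stop(sprintf("no trace files found in %s", dir), call. = FALSE)
  info <- do.call(rbind, regmatches(basename(files),
    regexec("^(drug|vehicle)_(.+)_t([0-9.]+)min\\.csv$", basename(files))))
  preps <- list()
  for (i in seq_along(files)) {
    id <- info[i, 3]
    if (is.null(preps[[id]]))
      preps[[id]] <- list(prep_id = id, arm = info[i, 2], rows = list(),
                          recordings = list())
    tr <- read_trace(files[i])
    tmin <- as.numeric(info[i, 4])
    m <- trace_metrics(tr, loop_time_min = tmin)
    mm <- m[, setdiff(names(m), "loop_time_min")]
    preps[[id]]$rows[[length(preps[[id]]$rows) + 1]] <-
      tibble::as_tibble(c(list(time_min = tmin), lapply(mm, mean)))
    preps[[id]]$recordings[[paste0("t", tmin)]] <- tr
    preps[[id]]$treatment <- tr$meta$treatment
    preps[[id]]$meta <- tr$meta
  }
  preps <- lapply(preps, function(p) {
    p$metrics <- dplyr::arrange(dplyr::bind_rows(p$rows), .data$time_min)
    p$rows <- NULL
    p
  })
  arms <- vapply(preps, `[[`, "", "arm")
  cfg <- structure(list(preset = preps[[which(arms == "drug")[1]]]$treatment,
                        schedule = schedule, threshold = threshold,
                        alpha = alpha, keep_traces = TRUE),
                   class = "wl_config")
  structure(list(config = cfg, drug = unname(preps[arms == "drug"]),
                 vehicle = unname(preps[arms == "vehicle"])),
            class = "wl_study_data")
}
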