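# Study-level simulation: whole protocols, arms and datasets.

#' Study configuration
#'
#' Everything needed to simulate and analyse one drug-vs-vehicle study.
#' All randomness flows from `seed`.
#'
#' @param preset Name of the drug preset (must resolve in `presets`).
#' @param n_drug,n_vehicle Preparations per arm.
#' @param seed Integer seed (mandatory: reproducibility is part of the
#'   contract).
#' @param noise A [noise_model()].
#' @param schedule A [wl_schedule()].
#' @param sampling_rate_hz Sampling rate for simulated traces, Hz.
#' @param n_cycles Cycles per loop recording.
#' @param threshold Stability-filter threshold (fractional deviation).
#' @param alpha Significance level for the statistical workflow.
#' @param presets Preset registry; defaults to the shipped registry.
#' @param keep_traces Keep the simulated traces in the dataset (needed for
#'   loop-overlay figures; drop for large batch runs).
#' @return An object of class `wl_config`.
#' @export
study_config <- function(preset, n_drug, n_vehicle, seed,
                         noise = noise_model(), schedule = wl_schedule(),
                         sampling_rate_hz = 10000, n_cycles = 1,
                         threshold = 0.20, alpha = 0.05,
                         presets = preset_registry(), keep_traces = TRUE) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a seed is mandatory", call. = FALSE)
  if (!preset %in% names(presets))
    stop(sprintf("unknown preset '%s'; registry has: %s", preset,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  structure(list(preset = preset, n_drug = n_drug, n_vehicle = n_vehicle,
                 seed = as.integer(seed), noise = noise, schedule = schedule,
                 sampling_rate_hz = sampling_rate_hz, n_cycles = n_cycles,
                 threshold = threshold, alpha = alpha, presets = presets,
                 keep_traces = keep_traces),
            class = "wl_config")
}

# Simulate one preparation's full protocol: a loop recording at every
# schedule time, with the treatment effect active after the stabilisation
# window.  Uses the current RNG state for the per-recording noise factors.
simulate_prep_timecourse <- function(params, preset, schedule = wl_schedule(),
                                     noise = noise_model(),
                                     sampling_rate_hz = 10000, n_cycles = 1,
                                     keep_traces = FALSE) {
  times <- schedule$times_min
  stab_end <- schedule$stabilisation_end_min
  recordings <- if (keep_traces) stats::setNames(vector("list", length(times)),
                                                 paste0("t", times)) else NULL
  rows <- vector("list", length(times))
  base_cache <- new.env(parent = emptyenv())
  for (k in seq_along(times)) {
    tau <- times[k]
    eff <- if (tau > stab_end) drug_effect(preset, tau - stab_end)
           else identity_effect()
    nf <- 1
    if (!is.null(noise)) {
      nf <- exp(stats::rnorm(1, 0, noise$sigma_force))
      nf <- nf * max(0, 1 - noise$drift_per_hour * tau / 60)
    }
    # recordings sharing effect scales differ only by the per-loop noise
    # factor, so the noise-free force trace is computed once per effect level
    key <- sprintf("%.12g_%.12g_%.12g", eff$s_amp, eff$s_relax, eff$s_pas)
    if (is.null(base_cache[[key]]))
      base_cache[[key]] <- simulate_workloop_trace(
        params, effect = eff, n_cycles = n_cycles,
        sampling_rate_hz = sampling_rate_hz, noise_factor = 1,
        treatment = preset$name)
    tr <- base_cache[[key]]
    if (nf != 1) tr$force_mN <- tr$force_mN * nf
    m <- trace_metrics(tr, loop_time_min = tau)
    mm <- m[, setdiff(names(m), "loop_time_min")]
    rows[[k]] <- tibble::as_tibble(c(list(time_min = tau), lapply(mm, mean)))
    if (keep_traces) recordings[[k]] <- tr
  }
  list(metrics = dplyr::bind_rows(rows), recordings = recordings)
}

simulate_prep <- function(prep_id, arm, preset, config) {
  draw <- sample_preparation(config$noise)
  tw_trace <- simulate_twitch_trace(draw$params,
                                    sampling_rate_hz = config$sampling_rate_hz)
  tw <- twitch_metrics(tw_trace)
  geo <- muscle_geometry(draw$params$mass, draw$params$L_opt * 1e-3,
                         draw$meta$density_kg_m3, tw$F_developed_mN)
  sim <- simulate_prep_timecourse(draw$params, preset, config$schedule,
                                  config$noise, config$sampling_rate_hz,
                                  config$n_cycles,
                                  keep_traces = config$keep_traces)
  list(prep_id = prep_id, arm = arm, treatment = preset$name,
       params = draw$params, meta = draw$meta, twitch = tw, geometry = geo,
       metrics = sim$metrics, recordings = sim$recordings)
}

#' Simulate a full drug-vs-vehicle study
#'
#' Draws `n_drug` + `n_vehicle` preparations, runs each through the
#' 80-minute protocol (a loop recording every 5 minutes, treatment active
#' after the 20-minute stabilisation window) and returns the complete
#' dataset.  Deterministic under the config seed.
#'
#' @param config A [study_config()].
#' @return An object of class `wl_study_data`: list with `config`, `drug`
#'   and `vehicle` (lists of preparations, each holding metadata, twitch
#'   metrics, geometry, per-loop metrics and, optionally, raw traces).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "wl_config"))
  set.seed(config$seed)
  drug_preset <- config$presets[[config$preset]]
  veh_name <- drug_preset$vehicle
  if (!veh_name %in% names(config$presets))
    stop(sprintf("vehicle preset '%s' not in registry", veh_name), call. = FALSE)
  veh_preset <- config$presets[[veh_name]]
  drug <- lapply(seq_len(config$n_drug), function(i)
    simulate_prep(sprintf("d_%s_%02d", config$preset, i), "drug", drug_preset,
                  config))
  vehicle <- lapply(seq_len(config$n_vehicle), function(i)
    simulate_prep(sprintf("v_%s_%02d", veh_name, i), "vehicle", veh_preset,
                  config))
  structure(list(config = config, drug = drug, vehicle = vehicle),
            class = "wl_study_data")
}

#' Analyse a simulated or recorded study dataset
#'
#' The full analysis workflow: apply the stability exclusion filter,
#' normalise each included preparation to its stabilisation mean, summarise
#' the arms, compute drug-vs-vehicle effect sizes at every treatment time,
#' run the mixed-design repeated-measures ANOVA, run per-timepoint
#' independent t-tests when the ANOVA is significant (the reported p-values
#' are not multiplicity-corrected, mirroring the original workflow), and
#' classify the treatment's inotropy.
#'
#' @param data A `wl_study_data` from [simulate_study()] (or assembled from
#'   read traces).
#' @param threshold Stability-filter threshold; defaults to the config's.
#' @param alpha Significance level; defaults to the config's.
#' @return An object of class `wl_study_result`.
#' @export
analyze_study <- function(data, threshold = data$config$threshold,
                          alpha = data$config$alpha) {
  stopifnot(inherits(data, "wl_study_data"))
  sched <- data$config$schedule
  stab_end <- sched$stabilisation_end_min
  preps <- c(data$drug, data$vehicle)
  arms <- vapply(preps, `[[`, "", "arm")

  exclusions <- list()
  long <- list()
  for (p in preps) {
    tc <- p$metrics
    tc$time_min <- tc$time_min
    filt <- stability_filter(tc, threshold, stab_end)
    if (!filt$included) {
      exclusions[[length(exclusions) + 1]] <-
        tibble::tibble(prep_id = p$prep_id, arm = p$arm, reason = filt$reason)
      next
    }
    tc <- normalize_to_stabilisation(tc, stab_end)
    tc$prep_id <- p$prep_id
    tc$arm <- p$arm
    long[[length(long) + 1]] <- tc
  }
  if (length(long) == 0) stop("all preparations excluded", call. = FALSE)
  long <- dplyr::bind_rows(long)
  exclusions <- if (length(exclusions)) dplyr::bind_rows(exclusions)
                else tibble::tibble(prep_id = character(), arm = character(),
                                    reason = character())

  summary <- dplyr::summarise(
    long, mean_pct = mean(.data$pct_of_stab),
    sem_pct = stats::sd(.data$pct_of_stab) / sqrt(dplyr::n()),
    mean_Pnorm = mean(.data$Pnorm_W_per_kg), n = dplyr::n(),
    .by = c("arm", "time_min"))

  treat_times <- sched$treat_times_min
  drug_long <- long[long$arm == "drug", ]
  veh_long <- long[long$arm == "vehicle", ]

  anova_df <- long[long$time_min > stab_end, ]
  rm <- rm_anova(anova_df, value = "pct_of_stab", group = "arm",
                 time = "time_min", subject = "prep_id")
  gate <- isTRUE(rm$p[rm$effect == "group"] < alpha) ||
    isTRUE(rm$p[rm$effect == "group:time"] < alpha)

  eff_rows <- lapply(treat_times, function(tm) {
    es <- effect_size(drug_long, veh_long, tm)
    tibble::tibble(time_min = tm, effect_pp = es$effect_pp,
                   sem_pp = es$sem_pp, n_drug = es$n_drug,
                   n_vehicle = es$n_vehicle)
  })
  effects <- dplyr::bind_rows(eff_rows)

  if (gate) {
    tt <- per_timepoint_ttests(drug_long, veh_long, treat_times,
                               value = "pct_of_stab")
  } else {
    tt <- tibble::tibble(time_min = treat_times, t = NA_real_, df = NA_real_,
                         p = NA_real_)
  }
  ttests <- dplyr::left_join(effects, tt, by = "time_min")

  result <- structure(list(
    preset = data$config$preset, schedule = sched, alpha = alpha,
    summary = summary, time_courses = long, effects = effects,
    rm_anova = rm, anova_significant = gate, ttests = ttests,
    exclusions = exclusions,
    n_included = c(drug = length(unique(drug_long$prep_id)),
                   vehicle = length(unique(veh_long$prep_id)))),
    class = "wl_study_result")
  result$inotropy <- classify_inotropy(result, alpha)
  result
}

#' @export
print.wl_study_result <- function(x, ...) {
  cat(sprintf("<wl_study_result> %s: %s inotropy call\n", x$preset, x$inotropy))
  cat(sprintf("  included n: %d drug, %d vehicle (%d excluded)\n",
              x$n_included["drug"], x$n_included["vehicle"],
              nrow(x$exclusions)))
  i <- which.max(abs(x$effects$effect_pp))
  cat(sprintf("  largest effect: %+.1f +/- %.1f pp at %g min\n",
              x$effects$effect_pp[i], x$effects$sem_pp[i],
              x$effects$time_min[i]))
  print(x$rm_anova)
  invisible(x)
}
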