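# Drug-effect presets.
#
# Each preset is a set of phenomenological full-effect scales -- activation
# amplitude (s_amp), relaxation rate (s_relax) and passive force (s_pas) --
# plus onset kinetics and the documented time of maximal response.  The
# scales interpolate from 1 (no effect) to their full-effect values along
# the onset time-course E(t).  Amplitude scales are calibrated by
# [calibrate_preset()] so that the noise-free pipeline reproduces each
# drug's reported power-output change at its maximal-response time.

#' Construct a drug preset
#'
#' @param name Preset name.
#' @param s_amp Activation-amplitude scale at full effect.
#' @param s_relax Relaxation-rate scale at full effect (< 1 = faster
#'   relaxation).
#' @param s_pas Passive-force scale at full effect.
#' @param tau_on_min Onset time constant, minutes.
#' @param tau_off_min Decay time constant in minutes for a biphasic
#'   (transient) response; `Inf` for a sustained monophasic response.
#' @param t_max_effect_min Documented time of maximal response, minutes of
#'   treatment.
#' @param target_delta_pp Calibration target: drug-minus-vehicle change in
#'   stabilisation-normalised power at `t_max_effect_min`, percentage
#'   points.
#' @param vehicle Name of the matched vehicle-control preset.
#' @param dose Dose label (metadata).
#' @return An object of class `wl_preset`.
#' @export
drug_preset <- function(name, s_amp = 1, s_relax = 1, s_pas = 1,
                        tau_on_min = 10, tau_off_min = Inf,
                        t_max_effect_min = NA_real_,
                        target_delta_pp = 0, vehicle = "vehicle_kh",
                        dose = NA_character_) {
  stopifnot(s_amp > 0, tau_on_min > 0, tau_off_min > tau_on_min)
  structure(list(name = name, s_amp = s_amp, s_relax = s_relax,
                 s_pas = s_pas, tau_on_min = tau_on_min,
                 tau_off_min = tau_off_min,
                 t_max_effect_min = t_max_effect_min,
                 target_delta_pp = target_delta_pp, vehicle = vehicle,
                 dose = dose),
            class = "wl_preset")
}

#' Identity (vehicle) effect scales
#' @return List with `s_amp`, `s_relax`, `s_pas`, all 1.
#' @export
identity_effect <- function() list(s_amp = 1, s_relax = 1, s_pas = 1)

is_vehicle_preset <- function(preset) {
  preset$s_amp == 1 && preset$s_relax == 1 && preset$s_pas == 1
}

#' Drug-effect time-course
#'
#' The effect level `E(t)` at `t` minutes of treatment: monophasic
#' presets follow `E(t) = 1 - exp(-t / tau_on)`; biphasic presets (finite
#' `tau_off`) follow a difference of exponentials normalised to peak 1 at
#' its maximum.  Each scale interpolates from 1 to its full-effect value by
#' `E(t)`.
#'
#' @param preset A [drug_preset()].
#' @param t_treat_min Minutes since treatment start (>= 0).
#' @return List with `E`, `s_amp`, `s_relax`, `s_pas`.
#' @export
drug_effect <- function(preset, t_treat_min) {
  if (t_treat_min < 0) stop("treatment time must be non-negative", call. = FALSE)
  if (is.finite(preset$tau_off_min)) {
    t1 <- preset$tau_on_min
    t2 <- preset$tau_off_min
    t_pk <- log(t2 / t1) * t1 * t2 / (t2 - t1)
    e0 <- exp(-t_pk / t2) - exp(-t_pk / t1)
    E <- (exp(-t_treat_min / t2) - exp(-t_treat_min / t1)) / e0
  } else {
    E <- 1 - exp(-t_treat_min / preset$tau_on_min)
  }
  list(E = E,
       s_amp = 1 + (preset$s_amp - 1) * E,
       s_relax = 1 + (preset$s_relax - 1) * E,
       s_pas = 1 + (preset$s_pas - 1) * E)
}

#' Load the preset registry
#'
#' Reads the installed registry of drug presets (six reference inotropes
#' plus the two vehicle controls, which are modelled identically).
#'
#' @param path Path to a registry YAML file; defaults to the registry
#'   shipped with the package.
#' @return Named list of [drug_preset()] objects.
#' @export
preset_registry <- function(path = system.file("extdata", "presets.yaml",
                                               package = "workloopr")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(x) {
    x$tau_off_min <- if (is.null(x$tau_off_min)) Inf else as.numeric(x$tau_off_min)
    do.call(drug_preset, x)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Calibrate a preset's amplitude scale
#'
#' Adjusts `s_amp` by root bisection so that the noise-free full pipeline
#' -- simulate the 80-minute protocol for one drug and one vehicle
#' preparation with identical parameters, analyse, normalise to
#' stabilisation -- yields the preset's `target_delta_pp` at its
#' documented maximal-response time, within `tol` percentage points.
#' `s_relax` and `s_pas` are held at their preset values.
#'
#' @param preset A [drug_preset()] with `target_delta_pp` and
#'   `t_max_effect_min` set.
#' @param params A [muscle_params()]; calibration is noise-free, so the
#'   median preparation is used.
#' @param schedule A [wl_schedule()].
#' @param bracket Search interval for `s_amp`.
#' @param tol Calibration tolerance, percentage points.
#' @param sampling_rate_hz Sampling rate for the simulated traces.
#' @return The preset with calibrated `s_amp` and an added
#'   `achieved_delta_pp`.
#' @export
calibrate_preset <- function(preset, params = muscle_params(),
                             schedule = wl_schedule(), bracket = c(0.2, 3),
                             tol = 0.05, sampling_rate_hz = 10000) {
  if (is.na(preset$t_max_effect_min))
    stop("preset has no documented maximal-response time", call. = FALSE)
  if (preset$target_delta_pp == 0 && is_vehicle_preset(preset)) {
    preset$achieved_delta_pp <- 0
    return(preset)
  }
  objective <- function(s_amp) {
    p <- preset
    p$s_amp <- s_amp
    noise_free_delta(p, params, schedule, sampling_rate_hz) -
      preset$target_delta_pp
  }
  lo <- objective(bracket[1])
  hi <- objective(bracket[2])
  if (sign(lo) == sign(hi))
    stop(sprintf("calibration target %+.1f pp not bracketed within s_amp in [%g, %g]",
                 preset$target_delta_pp, bracket[1], bracket[2]), call. = FALSE)
  root <- stats::uniroot(objective, bracket, tol = 1e-6)
  preset$s_amp <- root$root
  preset$achieved_delta_pp <- noise_free_delta(preset, params, schedule,
                                               sampling_rate_hz)
  if (abs(preset$achieved_delta_pp - preset$target_delta_pp) > tol)
    warning(sprintf("calibration of '%s' achieved %+.3f pp for target %+.1f pp",
                    preset$name, preset$achieved_delta_pp,
                    preset$target_delta_pp))
  preset
}

# Noise-free drug-minus-vehicle delta at the preset's maximal-response
# time, computed through the full loop-analysis pipeline.  The noise-free
# vehicle time-course is exactly 100%, so only the drug arm is simulated.
noise_free_delta <- function(preset, params, schedule, sampling_rate_hz) {
  tc <- simulate_prep_timecourse(params, preset, schedule,
                                 noise = NULL,
                                 sampling_rate_hz = sampling_rate_hz)$metrics
  tc <- normalize_to_stabilisation(tc, schedule$stabilisation_end_min)
  t_abs <- schedule$stabilisation_end_min + preset$t_max_effect_min
  pct <- tc$pct_of_stab[tc$time_min == t_abs]
  if (length(pct) != 1)
    stop(sprintf("maximal-response time %g min (treatment) is not on the schedule",
                 preset$t_max_effect_min), call. = FALSE)
  pct - 100
}
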