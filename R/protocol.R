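# Experimental protocol logic: length optimisation, the loop schedule,
# stabilisation normalisation, the stability exclusion filter, muscle
# geometry, and drug-vs-vehicle effect sizes.

#' Protocol schedule
#'
#' The loop-recording schedule: a work-loop recording at the start of the
#' protocol and every `loop_interval_min` minutes thereafter for
#' `total_min` minutes (17 recordings by default), with the recordings
#' at or before `stabilisation_end_min` forming the stabilisation
#' (baseline) window.  Treatment (drug or vehicle) starts at the end of the
#' stabilisation window.
#'
#' @param loop_interval_min Minutes between loop recordings.
#' @param total_min Total protocol duration in minutes.
#' @param stabilisation_end_min End of the stabilisation window, minutes.
#' @return An object of class `wl_schedule` with elements `times_min`,
#'   `stab_times_min` and `treat_times_min`.
#' @export
wl_schedule <- function(loop_interval_min = 5, total_min = 80,
                        stabilisation_end_min = 20) {
  stopifnot(loop_interval_min > 0, total_min >= loop_interval_min,
            stabilisation_end_min >= loop_interval_min,
            stabilisation_end_min < total_min)
  times <- seq(0, total_min, by = loop_interval_min)
  structure(list(loop_interval_min = loop_interval_min,
                 total_min = total_min,
                 stabilisation_end_min = stabilisation_end_min,
                 times_min = times,
                 stab_times_min = times[times <= stabilisation_end_min],
                 treat_times_min = times[times > stabilisation_end_min]),
            class = "wl_schedule")
}

#' Isometric twitch metrics
#'
#' Active, passive and developed force of an isometric twitch: the active
#' force is the maximum force after the stimulus, the passive force the
#' minimum force over the pre-stimulus window, and the developed force
#' their difference.
#'
#' @param trace A [wl_trace()] recorded at constant length containing one
#'   stimulus marker.
#' @return List with `F_active_mN`, `F_passive_mN`, `F_developed_mN`.
#' @export
twitch_metrics <- function(trace) {
  stopifnot(inherits(trace, "wl_trace"))
  i_stim <- which(trace$stim > 0)
  if (length(i_stim) == 0)
    stop("no stimulus marker in trace; cannot locate the twitch", call. = FALSE)
  i0 <- i_stim[1]
  pre <- if (i0 > 1) trace$force_mN[1:(i0 - 1)] else trace$force_mN[1]
  f_pas <- min(pre)
  f_act <- max(trace$force_mN)
  list(F_active_mN = f_act, F_passive_mN = f_pas,
       F_developed_mN = f_act - f_pas)
}

#' Locate the optimal muscle length
#'
#' Given twitch developed forces measured at a series of increasing
#' lengths, returns the length of maximal developed force (`L_max`) and the
#' working initial length `L0 = 0.9 * L_max`.  Ties resolve to the smallest
#' length (conservative stretch).  If the developed force is still rising
#' at the final length, `L_max` is not bracketed and a warning is issued.
#'
#' @param length_mm Increasing vector of tested lengths, mm.
#' @param developed_mN Developed force at each length, mN.
#' @return List with `L_max_mm` and `L0_mm`.
#' @export
find_lmax <- function(length_mm, developed_mN) {
  stopifnot(length(length_mm) == length(developed_mN))
  if (length(length_mm) < 3)
    stop("need at least 3 lengths to bracket L_max", call. = FALSE)
  if (is.unsorted(length_mm, strictly = TRUE))
    stop("lengths must be strictly increasing", call. = FALSE)
  i <- which.max(developed_mN)  # which.max takes the first (smallest length) on ties
  if (any(developed_mN[-i] == developed_mN[i]))
    warning("ties in developed force; taking the smallest length")
  if (i == length(length_mm))
    warning("developed force still rising at the final length; L_max not bracketed")
  list(L_max_mm = length_mm[i], L0_mm = 0.9 * length_mm[i])
}

#' Muscle geometry and isometric stress
#'
#' Fibre cross-sectional area from mass, fibre length and an assumed
#' density, and the isometric stress from the developed force.
#'
#' @param mass_kg Wet muscle mass, kg.
#' @param fibre_length_m Fibre length at `L_max`, m.
#' @param density_kg_m3 Assumed muscle density, kg m^-3.
#' @param f_developed_mN Isometric developed force at `L_max`, mN.
#' @return List with `CSA_m2` and `stress_kN_m2`.
#' @export
muscle_geometry <- function(mass_kg, fibre_length_m, density_kg_m3 = 1060,
                            f_developed_mN) {
  if (any(c(mass_kg, fibre_length_m, density_kg_m3) <= 0))
    stop("mass, fibre length and density must all be positive", call. = FALSE)
  csa <- mass_kg / (density_kg_m3 * fibre_length_m)
  stress <- (f_developed_mN * 1e-3) / csa / 1e3  # N / m^2 -> kN m^-2
  list(CSA_m2 = csa, stress_kN_m2 = stress)
}

stab_values <- function(time_course, stabilisation_end_min = 20) {
  stopifnot(is.data.frame(time_course),
            all(c("time_min", "Pnorm_W_per_kg") %in% names(time_course)))
  time_course$Pnorm_W_per_kg[time_course$time_min <= stabilisation_end_min]
}

#' Stability exclusion filter
#'
#' A preparation is excluded when any single stabilisation-window power
#' value deviates from the stabilisation mean by more than
#' `threshold * mean` (default 20%), or when the stabilisation mean is not
#' positive.
#'
#' @param time_course Data frame with columns `time_min` and
#'   `Pnorm_W_per_kg` for one preparation.
#' @param threshold Maximal tolerated fractional deviation from the
#'   stabilisation mean.
#' @param stabilisation_end_min End of the stabilisation window, minutes.
#' @return List with `included` (logical), `max_deviation` (fraction) and
#'   `reason` (character, `NA` when included).
#' @export
stability_filter <- function(time_course, threshold = 0.20,
                             stabilisation_end_min = 20) {
  p <- stab_values(time_course, stabilisation_end_min)
  if (length(p) < 2)
    stop("need at least two stabilisation loops", call. = FALSE)
  m <- mean(p)
  if (m <= 0)
    return(list(included = FALSE, max_deviation = NA_real_,
                reason = "nonpositive stabilisation mean power"))
  dev <- max(abs(p - m)) / m
  if (dev > threshold)
    list(included = FALSE, max_deviation = dev,
         reason = sprintf("stabilisation power varied %.1f%% from the mean (limit %.0f%%)",
                          100 * dev, 100 * threshold))
  else
    list(included = TRUE, max_deviation = dev, reason = NA_character_)
}

#' Normalise a time-course to its stabilisation mean
#'
#' Expresses each power value as a percentage of that preparation's mean
#' power over the stabilisation window, so every preparation is on a common
#' 100% baseline.  By construction the normalised values average exactly
#' 100 over the stabilisation window.
#'
#' @inheritParams stability_filter
#' @return The input with an added `pct_of_stab` column.
#' @export
normalize_to_stabilisation <- function(time_course,
                                       stabilisation_end_min = 20) {
  m <- mean(stab_values(time_course, stabilisation_end_min))
  if (!is.finite(m) || m == 0)
    stop("zero stabilisation mean power; cannot normalise", call. = FALSE)
  time_course$pct_of_stab <- 100 * time_course$Pnorm_W_per_kg / m
  time_course
}

#' Drug-vs-vehicle effect size at one time point
#'
#' Difference of the group means of stabilisation-normalised power at a
#' given protocol time, in percentage points (drug minus vehicle), with the
#' standard error of the difference.
#'
#' @param drug,vehicle Data frames with columns `prep_id`, `time_min` and
#'   `pct_of_stab`, one row per preparation and time.
#' @param time_min Protocol time at which to compare, minutes.
#' @return List with `effect_pp`, `sem_pp`, `n_drug`, `n_vehicle`.
#' @export
effect_size <- function(drug, vehicle, time_min) {
  pick <- function(d) d$pct_of_stab[d$time_min == time_min]
  x <- pick(drug)
  y <- pick(vehicle)
  if (length(x) == 0 || length(y) == 0)
    stop(sprintf("time %g min not present in both groups", time_min), call. = FALSE)
  sem2 <- function(v) if (length(v) > 1) stats::var(v) / length(v) else 0
  list(effect_pp = mean(x) - mean(y),
       sem_pp = sqrt(sem2(x) + sem2(y)),
       n_drug = length(x), n_vehicle = length(y))
}

#' Classify inotropy from an analysed study
#'
#' A treatment is called a positive inotrope when the repeated-measures
#' ANOVA shows a significant treatment or treatment-by-time effect and the
#' largest significant per-timepoint effect size is positive; a negative
#' inotrope when that effect is negative; otherwise no call is made.
#'
#' @param study A `wl_study_result` from [analyze_study()].
#' @param alpha Significance level.
#' @return One of `"positive"`, `"negative"`, `"none"`.
#' @export
classify_inotropy <- function(study, alpha = 0.05) {
  an <- study$rm_anova
  p_group <- an$p[an$effect == "group"]
  p_int <- an$p[an$effect == "group:time"]
  if (!(isTRUE(p_group < alpha) || isTRUE(p_int < alpha))) return("none")
  tt <- study$ttests
  sig <- tt[!is.na(tt$p) & tt$p < alpha, , drop = FALSE]
  if (nrow(sig) == 0) return("none")
  top <- sig$effect_pp[which.max(abs(sig$effect_pp))]
  if (top > 0) "positive" else if (top < 0) "negative" else "none"
}
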