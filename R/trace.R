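# Trace containers and validation.
#
# Unit conventions, used throughout: force in mN, length in mm, time in s,
# mass in kg.  Work and power are reported in J and W (1 mN x 1 mm = 1e-6 J).

MN_MM_TO_J <- 1e-6
MN_MM_PER_S_TO_W <- 1e-6

#' Stimulus settings
#'
#' Describes the electrical stimulus delivered once per work-loop cycle.
#' The current is metadata only; it does not enter any computation.
#'
#' @param pulse_width_ms Pulse width in ms.
#' @param current_mA Stimulation current in mA (metadata).
#' @param phase_offset Fraction of the cycle at which the pulse begins;
#'   0 means the pulse coincides with the onset of lengthening.
#' @return An object of class `wl_stimulus`.
#' @export
wl_stimulus <- function(pulse_width_ms = 1.0, current_mA = 120,
                        phase_offset = 0) {
  stopifnot(pulse_width_ms > 0)
  structure(list(pulse_width_ms = pulse_width_ms, current_mA = current_mA,
                 phase_offset = phase_offset),
            class = "wl_stimulus")
}

#' Preparation metadata
#'
#' Metadata accompanying a recorded trace: anatomy of the preparation and
#' the work-loop protocol settings under which it was recorded.
#'
#' @param mass_kg Wet muscle mass in kg.
#' @param l_max_mm Length of maximal isometric developed force, in mm.
#' @param l0_mm Initial (loop mean) length in mm; defaults to 90% of `l_max_mm`.
#' @param strain Strain amplitude of the imposed sinusoid (half peak-to-peak,
#'   dimensionless); the rig default is 0.04 (i.e. +/- 4%).
#' @param cycle_freq_hz Cycle frequency in Hz.
#' @param density_kg_m3 Assumed muscle density, kg m^-3.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param treatment Treatment label (preset name or free text).
#' @param dose Dose label (metadata).
#' @param stimulus A [wl_stimulus()] object.
#' @return An object of class `wl_meta`.
#' @export
wl_meta <- function(mass_kg, l_max_mm, l0_mm = 0.9 * l_max_mm, strain = 0.04,
                    cycle_freq_hz = 6, density_kg_m3 = 1060,
                    sampling_rate_hz = 10000, treatment = "vehicle_kh",
                    dose = NA_character_, stimulus = wl_stimulus()) {
  stopifnot(mass_kg > 0, l_max_mm > 0, l0_mm > 0, l0_mm <= l_max_mm,
            strain > 0, strain < 0.2, cycle_freq_hz > 0, density_kg_m3 > 0,
            sampling_rate_hz > 0)
  structure(list(mass_kg = mass_kg, l_max_mm = l_max_mm, l0_mm = l0_mm,
                 strain = strain, cycle_freq_hz = cycle_freq_hz,
                 density_kg_m3 = density_kg_m3,
                 sampling_rate_hz = sampling_rate_hz, treatment = treatment,
                 dose = dose, stimulus = stimulus),
            class = "wl_meta")
}

#' Sampled force/length trace
#'
#' A uniformly sampled record of one segment of a work-loop (or isometric)
#' experiment: time, muscle length, force and the stimulus marker, plus
#' preparation metadata.  The constructor validates uniform sampling,
#' finiteness and positivity of length.
#'
#' @param time_s Sample times in s, strictly increasing on a uniform grid.
#' @param length_mm Muscle length per sample, mm (> 0).
#' @param force_mN Force per sample, mN.
#' @param stim Binary stimulus marker per sample (0/1); optional.
#' @param meta A [wl_meta()] object.
#' @return An object of class `wl_trace`.
#' @export
wl_trace <- function(time_s, length_mm, force_mN, stim = NULL, meta) {
  n <- length(time_s)
  if (is.null(stim)) stim <- integer(n)
  if (length(length_mm) != n || length(force_mN) != n || length(stim) != n)
    stop("trace columns must all have the same length", call. = FALSE)
  if (n < 2) stop("trace must contain at least two samples", call. = FALSE)
  dts <- diff(time_s)
  if (any(dts <= 0)) stop("time not monotone", call. = FALSE)
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-9 * dt))
    stop("non-uniform sampling: time grid is not constant", call. = FALSE)
  if (!all(is.finite(length_mm)) || !all(is.finite(force_mN)))
    stop("length and force must be finite", call. = FALSE)
  if (any(length_mm <= 0)) stop("length must be positive", call. = FALSE)
  if (!inherits(meta, "wl_meta")) stop("meta must be a wl_meta object", call. = FALSE)
  structure(list(time_s = as.numeric(time_s), length_mm = as.numeric(length_mm),
                 force_mN = as.numeric(force_mN), stim = as.integer(stim),
                 dt = dt, meta = meta),
            class = "wl_trace")
}

#' @export
print.wl_trace <- function(x, ...) {
  cat(sprintf("<wl_trace> %d samples @ %.6g s, %.3g s total, treatment=%s\n",
              length(x$time_s), x$dt, diff(range(x$time_s)),
              x$meta$treatment))
  invisible(x)
}

#' @export
as.data.frame.wl_trace <- function(x, ...) {
  data.frame(time_s = x$time_s, length_mm = x$length_mm,
             force_mN = x$force_mN, stim = x$stim)
}
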