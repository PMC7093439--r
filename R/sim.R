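# Phenomenological twitch and work-loop simulator.
#
# The muscle is a Hill-type model: active force is the product of an
# activation transient, a force-length parabola and a force-velocity
# relation, scaled by the peak isometric force; passive force is an
# exponential spring referenced to the working initial length.  The model
# stands in for the living preparation so the full analysis pipeline can be
# exercised; its defaults are set so that simulated preparations reproduce
# the twitch forces, loop shapes and stabilisation power outputs observed
# on the rig.

#' Muscle model parameters
#'
#' @param F_iso_max Peak twitch active-force scale, mN.  Equal to the
#'   developed force of a single isometric twitch at `L_opt`.
#' @param tau_act Activation rise time constant, s.
#' @param tau_relax Relaxation (decay) time constant, s.
#' @param t_lat Stimulus-to-force mechanical latency, s.  Absorbs the
#'   excitation-contraction coupling delay and the sigmoidal onset that a
#'   two-exponential transient lacks.
#' @param L_opt Optimum length of the force-length relation, mm (the
#'   length of maximal developed force, `L_max`).
#' @param fl_width Half-width of the force-length parabola as a fraction of
#'   `L_opt`.  Cardiac muscle operates on a steep ascending limb, so the
#'   default is narrow.
#' @param v_max Maximal shortening velocity in muscle lengths per second.
#' @param hill_curv Force-velocity curvature (the Hill `a/F0` ratio);
#'   larger is closer to linear.
#' @param ecc_amp Asymptotic eccentric force enhancement above isometric
#'   (the lengthening plateau is `1 + ecc_amp`).
#' @param ecc_vhalf Lengthening velocity, as a fraction of `v_max`, at
#'   which half the eccentric enhancement is reached.
#' @param f_pas0 Passive force at the working initial length `L0`, mN (the
#'   preload set during length optimisation).
#' @param k_pas Passive exponential force scale, mN.
#' @param beta_pas Passive exponential rate, mm^-1.
#' @param rate_pot Force-frequency potentiation: the factor by which the
#'   activation amplitude under steady 6 Hz pacing exceeds that of the
#'   single post-rest twitch used for length optimisation.
#' @param mass Wet muscle mass, kg.
#' @return An object of class `wl_params`.
#' @export
muscle_params <- function(F_iso_max = 15.7, tau_act = 0.012,
                          tau_relax = 0.022, t_lat = 0.039, L_opt = 2.2,
                          fl_width = 0.26, v_max = 14, hill_curv = 2.0,
                          ecc_amp = 0.4, ecc_vhalf = 0.5, f_pas0 = 3.0,
                          k_pas = 0.9, beta_pas = 6, rate_pot = 1.6,
                          mass = 0.73e-6) {
  stopifnot(F_iso_max >= 0, tau_act > 0, tau_relax > 0, tau_act < tau_relax,
            t_lat >= 0, L_opt > 0, fl_width > 0, v_max > 0, hill_curv > 0,
            k_pas >= 0, beta_pas > 0, rate_pot > 0, mass > 0)
  structure(as.list(environment()), class = "wl_params")
}

#' Activation transient
#'
#' The dimensionless activation following one stimulus: a latency-shifted
#' difference of exponentials,
#' `a(t) = s_amp * A0 * (exp(-(t - t_lat)/(tau_relax * s_relax)) -
#' exp(-(t - t_lat)/tau_act))`, zero before the latency has elapsed, with
#' `A0` normalising the unscaled (`s_amp = s_relax = 1`) peak to 1.
#'
#' @param t_since_stim Time since the stimulus, s (vectorised).
#' @param params A [muscle_params()].
#' @param s_amp Amplitude scale (drug effect).
#' @param s_relax Relaxation-rate scale (< 1 = faster relaxation).
#' @return Activation values (dimensionless, peak 1 when unscaled).
#' @export
activation <- function(t_since_stim, params, s_amp = 1, s_relax = 1) {
  ta <- params$tau_act
  tr0 <- params$tau_relax
  tr <- tr0 * s_relax
  stopifnot(tr > ta)
  t_pk <- log(tr0 / ta) * ta * tr0 / (tr0 - ta)
  a0 <- exp(-t_pk / tr0) - exp(-t_pk / ta)
  tt <- t_since_stim - params$t_lat
  out <- numeric(length(tt))
  on <- tt > 0
  out[on] <- s_amp * (exp(-tt[on] / tr) - exp(-tt[on] / ta)) / a0
  out
}

force_length <- function(L, params) {
  pmax(0, 1 - ((L - params$L_opt) / (params$fl_width * params$L_opt))^2)
}

force_velocity <- function(v, params, L_ref) {
  vm <- params$v_max * L_ref  # mm/s
  conc <- pmax(0, 1 - v / vm) / (1 + v / (params$hill_curv * vm))
  ecc <- 1 + params$ecc_amp * (-v) / ((-v) + params$ecc_vhalf * vm)
  ifelse(v >= 0, conc, ecc)
}

passive_force <- function(L, params, L0) {
  params$f_pas0 + params$k_pas * (expm1(params$beta_pas * (L - L0)))
}

#' Hill-type force model
#'
#' Total force at a given length, velocity and activation level: the
#' active component `a * F_iso_max * fl(L) * fv(v)` plus the passive
#' exponential spring, clipped at zero.
#'
#' @param L Length, mm.
#' @param v Shortening velocity, mm/s (positive shortening).
#' @param a Activation (dimensionless, already drug-scaled).
#' @param params A [muscle_params()].
#' @param L0 Reference length for the passive spring, mm; defaults to
#'   `0.9 * L_opt`, the working initial length.
#' @param s_pas Passive-force scale (drug effect).
#' @return Force in mN.
#' @export
force_model <- function(L, v, a, params, L0 = 0.9 * params$L_opt,
                        s_pas = 1) {
  stopifnot(all(L > 0))
  active <- a * params$F_iso_max * force_length(L, params) *
    force_velocity(v, params, L_ref = L0)
  pmax(0, active + s_pas * passive_force(L, params, L0))
}

#' Simulate an isometric twitch
#'
#' A single post-rest stimulus at constant length: the trace the rig
#' records during length optimisation.  No force-frequency potentiation is
#' applied (the muscle is rested), so the developed force of the simulated
#' twitch at `L_opt` equals `F_iso_max`.
#'
#' @param params A [muscle_params()].
#' @param length_mm Constant length of the twitch, mm.
#' @param duration_s Trace duration, s.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param stim_delay_s Time of the stimulus within the trace, s.
#' @param meta Optional [wl_meta()]; a default is built from `params`.
#' @return A [wl_trace()].
#' @export
simulate_twitch_trace <- function(params = muscle_params(),
                                  length_mm = params$L_opt,
                                  duration_s = 0.3,
                                  sampling_rate_hz = 10000,
                                  stim_delay_s = 0.05, meta = NULL) {
  dt <- 1 / sampling_rate_hz
  t <- seq(0, duration_s - dt, by = dt)
  a <- activation(t - stim_delay_s, params)
  L0 <- 0.9 * params$L_opt
  F <- force_model(rep(length_mm, length(t)), v = 0, a = a, params = params,
                   L0 = L0)
  stim <- as.integer(t >= stim_delay_s & t < stim_delay_s + 1e-3)
  if (is.null(meta))
    meta <- wl_meta(mass_kg = params$mass, l_max_mm = params$L_opt,
                    sampling_rate_hz = sampling_rate_hz)
  wl_trace(t, rep(length_mm, length(t)), F, stim, meta)
}

#' Simulate a work-loop trace
#'
#' One or more complete cycles of the commanded sinusoid
#' `L(t) = L0 * (1 + strain * sin(2 pi f t))`, with a stimulus at the start
#' of each lengthening phase and force from the Hill-type model.  The
#' stimulation is phase-locked to the commanded cycle, so every cycle holds
#' exactly `round(sampling_rate / cycle_freq)` samples.  Activation is the
#' steady-state superposition of the current and previous stimulus, scaled
#' by the force-frequency potentiation `rate_pot`.  A single multiplicative
#' force-noise factor applies to the whole recording (loop-to-loop noise is
#' drawn per recording by the study simulator).
#'
#' @param params A [muscle_params()].
#' @param effect Drug-effect scales as returned by [drug_effect()]:
#'   a list with `s_amp`, `s_relax`, `s_pas`.
#' @param n_cycles Number of cycles to record.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param cycle_freq_hz Cycle frequency, Hz.
#' @param strain Strain amplitude (half peak-to-peak).
#' @param noise_factor Multiplicative force noise factor for this recording.
#' @param treatment Treatment label stored in the metadata.
#' @return A [wl_trace()].
#' @export
simulate_workloop_trace <- function(params = muscle_params(),
                                    effect = identity_effect(),
                                    n_cycles = 1,
                                    sampling_rate_hz = 10000,
                                    cycle_freq_hz = 6, strain = 0.04,
                                    noise_factor = 1,
                                    treatment = "vehicle_kh") {
  stopifnot(n_cycles >= 1)
  n <- round(sampling_rate_hz / cycle_freq_hz)
  dt <- 1 / sampling_rate_hz
  L0 <- 0.9 * params$L_opt
  th <- 2 * pi * (0:(n - 1)) / n
  L <- L0 * (1 + strain * sin(th))
  v <- -L0 * strain * 2 * pi * cycle_freq_hz * cos(th)  # shortening positive
  t_cyc <- (0:(n - 1)) * dt
  period <- n * dt
  a <- activation(t_cyc, params, effect$s_amp, effect$s_relax) +
    activation(t_cyc + period, params, effect$s_amp, effect$s_relax)
  F1 <- force_model(L, v, a * params$rate_pot, params, L0 = L0,
                    s_pas = effect$s_pas) * noise_factor
  stim1 <- as.integer(t_cyc < 1e-3)
  N <- n * n_cycles
  tr_meta <- wl_meta(mass_kg = params$mass, l_max_mm = params$L_opt,
                     l0_mm = L0, strain = strain,
                     cycle_freq_hz = cycle_freq_hz,
                     sampling_rate_hz = sampling_rate_hz,
                     treatment = treatment)
  wl_trace(time_s = (0:(N - 1)) * dt, length_mm = rep(L, n_cycles),
           force_mN = rep(F1, n_cycles), stim = rep(stim1, n_cycles),
           meta = tr_meta)
}

#' Loop-to-loop and inter-preparation noise model
#'
#' @param sigma_force Log-scale SD of the multiplicative force noise drawn
#'   once per loop recording.
#' @param sigma_mass Log-scale SD of the inter-preparation mass spread.
#' @param sigma_stress Log-scale SD of the inter-preparation isometric
#'   stress spread (the spread of `F_iso_max` at a given geometry).
#' @param sigma_lmax Log-scale SD of the inter-preparation `L_max` spread.
#' @param drift_per_hour Fractional run-down of activation amplitude per
#'   hour (0 = stable preparation).
#' @return An object of class `wl_noise`.
#' @export
noise_model <- function(sigma_force = 0.03, sigma_mass = 0.45,
                        sigma_stress = 0.35, sigma_lmax = 0.20,
                        drift_per_hour = 0) {
  stopifnot(sigma_force >= 0, sigma_mass >= 0, sigma_stress >= 0,
            sigma_lmax >= 0, drift_per_hour >= 0)
  structure(list(sigma_force = sigma_force, sigma_mass = sigma_mass,
                 sigma_stress = sigma_stress, sigma_lmax = sigma_lmax,
                 drift_per_hour = drift_per_hour),
            class = "wl_noise")
}

#' Draw one preparation
#'
#' Samples a preparation's anatomy from log-normal distributions (median
#' mass 0.73 mg, median `L_max` 2.2 mm, median isometric stress
#' 50 kN m^-2) and derives the twitch force scale from stress times
#' cross-sectional area, so that mass-normalised power is independent of
#' muscle size, as in real preparations.  Uses the current RNG state.
#'
#' @param noise A [noise_model()].
#' @param base Template [muscle_params()] supplying the kinetic constants.
#' @return List with `params` ([muscle_params()]) and `meta` ([wl_meta()]).
#' @export
sample_preparation <- function(noise = noise_model(),
                               base = muscle_params()) {
  mass <- 0.73e-6 * exp(stats::rnorm(1, 0, noise$sigma_mass))
  lmax <- 2.2 * exp(stats::rnorm(1, 0, noise$sigma_lmax))
  stress <- 50 * exp(stats::rnorm(1, 0, noise$sigma_stress))  # kN m^-2
  csa <- mass / (1060 * lmax * 1e-3)                          # m^2
  f_iso <- stress * csa * 1e6                                 # mN
  params <- base
  params$F_iso_max <- f_iso
  params$L_opt <- lmax
  params$mass <- mass
  meta <- wl_meta(mass_kg = mass, l_max_mm = lmax)
  list(params = params, meta = meta)
}
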