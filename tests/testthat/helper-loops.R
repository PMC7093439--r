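# Shared builders for synthetic loops used across tests.

# Rectangle loop: force f_short while shortening, f_long while lengthening,
# over a symmetric excursion about l0.  Corners are represented by repeated
# lengths (zero-length segments) so the phase areas are exact rectangles.
rect_loop <- function(l0 = 2, half_exc = 0.1, f_short = 10, f_long = 2,
                      n_seg = 50, cycle_freq_hz = 6) {
  up1 <- seq(l0, l0 + half_exc, length.out = n_seg)          # phase 1
  down <- seq(l0 + half_exc, l0 - half_exc, length.out = 2 * n_seg)
  up2 <- seq(l0 - half_exc, l0, length.out = n_seg)          # phase 3
  L <- c(up1, down, up2)
  F <- c(rep(f_long, n_seg), rep(f_short, 2 * n_seg), rep(f_long, n_seg))
  n <- length(L)
  dt <- 1 / (n * cycle_freq_hz)
  wl_loop(time_s = (0:(n - 1)) * dt, length_mm = L, force_mN = F, dt = dt,
          cycle_freq_hz = cycle_freq_hz)
}

# Ellipse loop: L = l0 + a sin(theta), F = f0 - b cos(theta); force is
# higher during shortening, so the analytic net work is +pi*a*b (mN mm).
ellipse_loop <- function(n = 1000, a = 0.1, b = 5, l0 = 2, f0 = 10,
                         cycle_freq_hz = 6) {
  th <- 2 * pi * (0:(n - 1)) / n
  dt <- 1 / (n * cycle_freq_hz)
  wl_loop(time_s = (0:(n - 1)) * dt, length_mm = l0 + a * sin(th),
          force_mN = f0 - b * cos(th), dt = dt,
          cycle_freq_hz = cycle_freq_hz)
}

# A randomised but physiological simulated loop (noise on force only).
random_sim_loop <- function() {
  prep <- sample_preparation()
  eff <- list(s_amp = runif(1, 0.7, 1.4), s_relax = runif(1, 0.8, 1.2),
              s_pas = runif(1, 0.8, 1.2))
  nf <- exp(rnorm(1, 0, 0.03))
  tr <- simulate_workloop_trace(prep$params, effect = eff, noise_factor = nf)
  segment_cycles(tr)[[1]]
}

zero_noise <- function() noise_model(sigma_force = 0, sigma_mass = 0,
                                     sigma_stress = 0, sigma_lmax = 0)

quick_study <- function(preset, n_drug, n_vehicle, seed,
                        noise = noise_model(), keep_traces = FALSE) {
  study_config(preset, n_drug, n_vehicle, seed = seed, noise = noise,
               keep_traces = keep_traces)
}

# Full-effect loop pair (baseline vs drug at its documented maximal
# response) for loop-shape signature checks, noise-free.
signature_pair <- function(preset_name) {
  reg <- preset_registry()
  p <- reg[[preset_name]]
  base <- segment_cycles(simulate_workloop_trace())[[1]]
  eff <- drug_effect(p, p$t_max_effect_min)
  drug <- segment_cycles(simulate_workloop_trace(effect = eff))[[1]]
  list(base = base, drug = drug, i1 = base$i1, i2 = base$i2, n = base$n)
}
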