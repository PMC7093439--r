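# Twitch/work-loop simulator: activation kinetics, force model,
# preparation sampling and whole-study generation.

test_that("activation transient has the closed-form peak", {
  p <- muscle_params()
  expect_equal(activation(0, p), 0)
  expect_equal(activation(p$t_lat, p), 0)
  # peak of the unscaled double exponential is 1 at the analytic time
  t_pk <- p$t_lat +
    log(p$tau_relax / p$tau_act) * p$tau_act * p$tau_relax /
      (p$tau_relax - p$tau_act)
  expect_equal(activation(t_pk, p), 1, tolerance = 1e-12)
  tt <- seq(0, 0.3, by = 1e-5)
  expect_equal(max(activation(tt, p)), 1, tolerance = 1e-6)
  # amplitude scale is linear
  expect_equal(max(activation(tt, p, s_amp = 1.2)), 1.2, tolerance = 1e-6)
})

test_that("force model: force-length, force-velocity and passive limits", {
  p <- muscle_params()
  L0 <- 0.9 * p$L_opt
  # parabola peak and roots
  expect_equal(force_model(p$L_opt, 0, 1, p) -
                 force_model(p$L_opt, 0, 0, p), p$F_iso_max)
  root <- p$L_opt * (1 - p$fl_width)
  expect_equal(force_model(root, 0, 1, p), force_model(root, 0, 0, p))
  # isometric force-velocity limit: fv(0) = 1
  expect_equal(force_model(p$L_opt, 0, 0.5, p) -
                 force_model(p$L_opt, 0, 0, p), 0.5 * p$F_iso_max)
  # no activation at the reference length -> the resting preload only
  expect_equal(force_model(L0, 0, 0, p), p$f_pas0)
  p0 <- muscle_params(f_pas0 = 0, k_pas = 0)
  expect_equal(force_model(0.9 * p0$L_opt, 0, 0, p0), 0)
})

test_that("simulated twitch develops F_iso_max at the optimum length", {
  p <- muscle_params()
  tw <- twitch_metrics(simulate_twitch_trace(p))
  expect_equal(tw$F_developed_mN, p$F_iso_max, tolerance = 1e-6)
})

test_that("work-loop traces are well-formed", {
  tr <- simulate_workloop_trace(n_cycles = 3)
  expect_true(all(is.finite(tr$force_mN)) && all(tr$force_mN >= 0))
  # one stimulus per cycle, each of the configured 1 ms width
  runs <- rle(tr$stim)
  expect_equal(sum(runs$values == 1), 3)
  expect_true(all(runs$lengths[runs$values == 1] == 10))
  # a zero-activation (passive) loop absorbs, never produces, work
  pas <- simulate_workloop_trace(muscle_params(F_iso_max = 0))
  expect_lte(net_work(segment_cycles(pas)[[1]]), 1e-15)
  # the default loop shows the three-phase shape: peak force near the
  # lengthening-to-shortening transition, low force during re-lengthening
  loop <- segment_cycles(simulate_workloop_trace())[[1]]
  expect_gt(net_work(loop), 0)
  i_pk <- which.max(loop$force_mN)
  expect_true(i_pk > loop$i1 && i_pk < loop$i2)
  expect_lt(mean(loop$force_mN[loop$i2:loop$n]),
            0.3 * max(loop$force_mN))
})

test_that("drug effect time-courses: onset, limits and the biphasic peak", {
  reg <- preset_registry()
  dig <- reg$digoxin
  e0 <- drug_effect(dig, 0)
  expect_equal(e0$s_amp, 1)
  expect_equal(drug_effect(dig, 1e6)$s_amp, dig$s_amp, tolerance = 1e-9)
  expect_error(drug_effect(dig, -1), "non-negative")
  # isoprenaline: biphasic, peaking ~10 min into treatment, then declining
  iso <- reg$isoprenaline
  tt <- seq(1, 60, by = 0.25)
  E <- vapply(tt, function(t) drug_effect(iso, t)$E, 0)
  expect_equal(tt[which.max(E)], 10, tolerance = 0.5)
  expect_equal(max(E), 1, tolerance = 1e-3)
  expect_lt(drug_effect(iso, 40)$E, drug_effect(iso, 10)$E)
})

test_that("sampled preparations reproduce the observed anatomy and power", {
  set.seed(20)
  draws <- replicate(100, sample_preparation(), simplify = FALSE)
  mass_mg <- vapply(draws, function(d) d$params$mass * 1e6, 0)
  expect_gt(median(mass_mg), 0.73 * 0.7)
  expect_lt(median(mass_mg), 0.73 * 1.3)
  # noise-free stabilisation power predominantly within the observed
  # 9.7-18.2 W/kg range of group means
  pnorm <- vapply(draws, function(d) {
    loop <- segment_cycles(simulate_workloop_trace(d$params))[[1]]
    net_power(loop, d$meta)$P_norm_W_per_kg
  }, 0)
  expect_gte(mean(pnorm >= 9.7 & pnorm <= 18.2), 0.6)
})

test_that("study simulation has the right shape and is reproducible", {
  cfg <- quick_study("digoxin", 6, 7, seed = 5)
  data <- simulate_study(cfg)
  expect_length(data$drug, 6)
  expect_length(data$vehicle, 7)
  expect_true(all(vapply(c(data$drug, data$vehicle),
                         function(p) nrow(p$metrics), 0L) == 17L))
  # same seed -> identical dataset
  data2 <- simulate_study(quick_study("digoxin", 6, 7, seed = 5))
  expect_equal(data$drug[[3]]$metrics, data2$drug[[3]]$metrics)
  expect_equal(data$vehicle[[1]]$params$F_iso_max,
               data2$vehicle[[1]]$params$F_iso_max)
  # zero-noise vehicle arm is flat at exactly 100%
  nv <- simulate_study(quick_study("vehicle_kh", 2, 2, seed = 1,
                                   noise = zero_noise()))
  r <- analyze_study(nv)
  expect_equal(r$time_courses$pct_of_stab,
               rep(100, nrow(r$time_courses)), tolerance = 1e-12)
})
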