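# Loop extraction, phase partition, areas, work and power.

test_that("segmentation recovers the commanded cycles", {
  tr <- simulate_workloop_trace(n_cycles = 6)
  loops <- segment_cycles(tr)
  expect_length(loops, 6)
  expect_true(all(vapply(loops, `[[`, 0, "n") == 1667))

  one <- segment_cycles(simulate_workloop_trace(n_cycles = 1))
  expect_length(one, 1)
  L <- one[[1]]$length_mm
  l0 <- 0.9 * muscle_params()$L_opt
  # first and last sample at the initial length, within one sample's travel
  max_step <- max(abs(diff(L)))
  expect_lt(abs(L[1] - l0), max_step)
  expect_lt(abs(L[length(L)] - l0), max_step)

  # a trailing half cycle is dropped
  tr2 <- simulate_workloop_trace(n_cycles = 2)
  keep <- seq_len(floor(length(tr2$time_s) * 0.75))
  tr15 <- wl_trace(tr2$time_s[keep], tr2$length_mm[keep],
                   tr2$force_mN[keep], tr2$stim[keep], tr2$meta)
  expect_length(segment_cycles(tr15), 1)

  short <- wl_trace(tr2$time_s[1:500], tr2$length_mm[1:500],
                    tr2$force_mN[1:500], meta = tr2$meta)
  expect_error(segment_cycles(short), "shorter than one complete cycle")
})

test_that("phase partition finds the length extrema of the sampled sinusoid", {
  loop <- segment_cycles(simulate_workloop_trace())[[1]]
  # quarter- and three-quarter-cycle indices of the 1667-point sinusoid
  expect_identical(loop$i1, 418L)  # sample 417 counting from zero
  expect_identical(loop$i2, 1251L) # sample 1250 counting from zero
  expect_true(1 < loop$i1 && loop$i1 < loop$i2 && loop$i2 <= loop$n)

  # a loop starting a quarter-cycle late (at maximum length) is malformed
  n <- 1000
  th <- 2 * pi * (0:(n - 1)) / n
  dt <- 1 / (n * 6)
  expect_error(
    wl_loop((0:(n - 1)) * dt, 2 * (1 + 0.04 * cos(th)), rep(5, n), dt, 6),
    "malformed")
  # non-monotone length within a quarter cycle is malformed
  L <- 2 * (1 + 0.04 * sin(th))
  L[120] <- L[120] - 0.05
  expect_error(wl_loop((0:(n - 1)) * dt, L, rep(5, n), dt, 6), "malformed")
})

test_that("rectangle loop: areas, net work, power and orientation", {
  loop <- rect_loop()  # 10 mN shortening / 2 mN lengthening over 0.2 mm
  a <- loop_areas(loop)
  expect_equal(unname(a["A2"]), 2.0e-6, tolerance = 1e-12)
  expect_equal(unname(a["A1"] + a["A3"]), 0.4e-6, tolerance = 1e-12)
  expect_equal(net_work(loop), 1.6e-6, tolerance = 1e-12)
  expect_equal(shoelace_work(loop), 1.6e-6, tolerance = 1e-12)

  # net power at 6 Hz, 1 mg preparation
  meta <- wl_meta(mass_kg = 1e-6, l_max_mm = 2.5)
  p <- net_power(loop, meta)
  expect_equal(p$P_net_W, 9.6e-6, tolerance = 1e-3)
  expect_equal(p$P_norm_W_per_kg, 9.6, tolerance = 1e-3)

  # identical force up and down -> degenerate loop, zero net work
  flat <- rect_loop(f_short = 5, f_long = 5)
  expect_equal(net_work(flat), 0, tolerance = 1e-18)

  # reversed traversal flips the shoelace sign
  rev_loop <- list(length_mm = rev(loop$length_mm),
                   force_mN = rev(loop$force_mN))
  expect_equal(shoelace_work(rev_loop), -shoelace_work(loop),
               tolerance = 1e-15)

  # zero force -> all areas zero
  zero <- rect_loop(f_short = 0, f_long = 0)
  expect_equal(unname(loop_areas(zero)), c(0, 0, 0))
})

test_that("ellipse loop: analytic net work and O(n^-2) convergence", {
  a <- 0.1; b <- 5
  exact <- pi * a * b * 1e-6
  errs <- vapply(c(200, 400, 800), function(n) {
    abs(net_work(ellipse_loop(n = n, a = a, b = b)) - exact)
  }, 0)
  expect_lt(errs[3] / exact, 1e-4)
  # halving the step divides the error by ~4
  expect_equal(errs[1] / errs[2], 4, tolerance = 0.15)
  expect_equal(errs[2] / errs[3], 4, tolerance = 0.15)
  expect_equal(net_work(ellipse_loop(n = 4000, a = a, b = b)), exact,
               tolerance = 1e-6)
})

test_that("instantaneous power: constant-velocity and isometric segments", {
  # constant 10 mN force while shortening at 1 mm/s
  n <- 101
  dt <- 1e-3
  seg <- list(length_mm = seq(2, 1.9, length.out = n),
              force_mN = rep(10, n), dt = dt)
  p <- instantaneous_power(seg)
  expect_equal(p[2:(n - 1)], rep(10e-6, n - 2), tolerance = 1e-9)
  iso <- list(length_mm = rep(2, n), force_mN = rep(10, n), dt = dt)
  expect_equal(instantaneous_power(iso), rep(0, n))
})

test_that("decomposition identity and power-work equivalence on simulated loops", {
  set.seed(101)
  for (k in 1:25) {
    loop <- random_sim_loop()
    w <- net_work(loop)
    expect_equal(w, shoelace_work(loop), tolerance = 1e-9)
    p <- mean(loop$p_inst_W)
    # time-average power equals work per cycle over the loop duration ...
    expect_equal(p, w / (loop$n * loop$dt), tolerance = 1e-12)
    # ... and work x nominal cycle frequency within discretisation error
    expect_equal(p, w * loop$cycle_freq_hz, tolerance = 1e-3)
    # force during shortening above force during lengthening -> positive work
    expect_gt(w, 0)
  }
})

test_that("linear scaling of force and mass", {
  set.seed(7)
  loop <- random_sim_loop()
  scaled <- loop
  scaled$force_mN <- 3 * loop$force_mN
  scaled$p_inst_W <- instantaneous_power(scaled)
  expect_equal(loop_areas(scaled), 3 * loop_areas(loop), tolerance = 1e-14)
  expect_equal(net_work(scaled), 3 * net_work(loop), tolerance = 1e-14)
  meta1 <- wl_meta(mass_kg = 1e-6, l_max_mm = 2.5)
  meta2 <- wl_meta(mass_kg = 2e-6, l_max_mm = 2.5)
  expect_equal(net_power(loop, meta1)$P_norm_W_per_kg,
               2 * net_power(loop, meta2)$P_norm_W_per_kg, tolerance = 1e-14)
})

test_that("trace validation rejects broken inputs", {
  meta <- wl_meta(mass_kg = 1e-6, l_max_mm = 2.2)
  t <- c(0, 1e-4, 2.5e-4, 3e-4)
  expect_error(wl_trace(t, rep(2, 4), rep(1, 4), meta = meta),
               "non-uniform sampling")
  t2 <- (0:3) * 1e-4
  expect_error(wl_trace(t2, c(2, 2, -1, 2), rep(1, 4), meta = meta),
               "length must be positive")
  expect_error(wl_trace(t2, rep(2, 4), c(1, NA, 1, 1), meta = meta),
               "finite")
})
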