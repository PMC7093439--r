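# Work-loop extraction and loop-level mechanics.
#
# A work-loop is one closed contraction cycle in the force-length plane.
# The loop is partitioned into three phases:
#   phase 1 -- lengthening under activation (initial length -> maximum length)
#   phase 2 -- active shortening           (maximum length -> minimum length)
#   phase 3 -- passive re-lengthening      (minimum length -> initial length)
# Net work is the phase-2 area minus the sum of the phase-1 and phase-3
# areas; net power output is net work times cycle frequency, reported per
# kilogram of wet muscle mass.

#' Segment a trace into work-loop cycles
#'
#' Splits a uniformly sampled trace into complete cycles of
#' `round(sampling_rate / cycle_freq)` samples each, starting at the first
#' sample (which must lie at the initial length on the rising limb of the
#' commanded sinusoid).  A trailing partial cycle is discarded.
#'
#' @param trace A [wl_trace()].
#' @param cycle_freq_hz Cycle frequency in Hz; defaults to the value in the
#'   trace metadata.
#' @return A list of `wl_loop` objects.
#' @export
segment_cycles <- function(trace, cycle_freq_hz = trace$meta$cycle_freq_hz) {
  stopifnot(inherits(trace, "wl_trace"))
  fs <- 1 / trace$dt
  if (fs < 100 * cycle_freq_hz)
    stop("sampling rate must be at least 100x the cycle frequency", call. = FALSE)
  n <- round(fs / cycle_freq_hz)
  n_total <- length(trace$time_s)
  n_loops <- floor(n_total / n)
  if (n_loops < 1)
    stop("trace shorter than one complete cycle", call. = FALSE)
  lapply(seq_len(n_loops), function(k) {
    idx <- ((k - 1) * n + 1):(k * n)
    wl_loop(time_s = trace$time_s[idx], length_mm = trace$length_mm[idx],
            force_mN = trace$force_mN[idx], dt = trace$dt,
            cycle_freq_hz = cycle_freq_hz)
  })
}

#' Construct a single work-loop
#'
#' Builds a `wl_loop` from the samples of one complete cycle, computing the
#' phase partition, per-sample shortening velocity and instantaneous power.
#'
#' @param time_s,length_mm,force_mN Samples of one cycle; the first sample
#'   must lie at the initial length on the rising limb.
#' @param dt Sampling interval in s.
#' @param cycle_freq_hz Cycle frequency in Hz.
#' @return An object of class `wl_loop` with elements `i1`, `i2` (phase
#'   boundaries), `v_mm_s` (shortening-positive velocity) and `p_inst_W`.
#' @export
wl_loop <- function(time_s, length_mm, force_mN, dt = time_s[2] - time_s[1],
                    cycle_freq_hz = 6) {
  n <- length(length_mm)
  loop <- structure(list(time_s = time_s, length_mm = length_mm,
                         force_mN = force_mN, n = n, dt = dt,
                         cycle_freq_hz = cycle_freq_hz),
                    class = "wl_loop")
  pb <- partition_phases(loop)
  loop$i1 <- pb[["i1"]]
  loop$i2 <- pb[["i2"]]
  loop$v_mm_s <- loop_velocity(loop)
  loop$p_inst_W <- loop$force_mN * loop$v_mm_s * MN_MM_PER_S_TO_W
  loop
}

#' Partition a loop into its three phases
#'
#' Phase boundaries are taken from the commanded-length extrema: `i1` is the
#' index of maximum length (first sample of phase 2) and `i2` the index of
#' minimum length (first sample of phase 3).  The commanded length is
#' noise-free on the rig, so extrema are located by `which.max`/`which.min`.
#' A loop whose length signal is not monotone within each quarter-cycle
#' (beyond `tol` relative tolerance), or that does not start at the initial
#' length on the rising limb, is rejected as malformed.
#'
#' @param loop A `wl_loop` (or a list with `length_mm`).
#' @param tol Relative noise tolerance on length monotonicity.
#' @return Named integer vector `c(i1 = , i2 = )` (1-based indices).
#' @export
partition_phases <- function(loop, tol = 1e-6) {
  L <- loop$length_mm
  n <- length(L)
  i1 <- which.max(L)
  i2 <- which.min(L)
  rng <- max(L) - min(L)
  bad <- function(msg) stop(sprintf("malformed loop: %s", msg), call. = FALSE)
  if (rng <= 0) bad("length signal is constant")
  if (!(i1 > 1 && i1 < i2 && i2 <= n))
    bad("length extrema out of order; loop must start at initial length on the rising limb")
  mid <- (max(L) + min(L)) / 2
  if (abs(L[1] - mid) > 0.05 * rng + tol * mid)
    bad("first sample is not at the initial (mid-range) length")
  slack <- tol * rng + .Machine$double.eps * max(abs(L))
  if (any(diff(L[1:i1]) < -slack) || any(diff(L[i2:n]) < -slack))
    bad("length not monotone while lengthening")
  if (any(diff(L[i1:i2]) > slack))
    bad("length not monotone while shortening")
  c(i1 = i1, i2 = i2)
}

loop_velocity <- function(loop) {
  L <- loop$length_mm
  n <- length(L)
  # central differences; the loop is periodic, so wrap around at the ends
  Lp <- c(L[-1], L[1])
  Lm <- c(L[n], L[-n])
  -(Lp - Lm) / (2 * loop$dt)
}

phase_trapz <- function(L, F, idx) {
  x <- L[idx]
  y <- F[idx]
  sum(diff(x) * (y[-1] + y[-length(y)])) / 2
}

#' Per-phase loop areas
#'
#' Work per phase as the absolute trapezoidal integral of force over length,
#' with the connecting segment between the last sample of a phase and the
#' first sample of the next assigned to the earlier phase, and the closure
#' segment (last sample back to the first) assigned to phase 3.
#'
#' @param loop A `wl_loop`.
#' @return Named numeric vector `c(A1 = , A2 = , A3 = )` in J.
#' @export
loop_areas <- function(loop) {
  L <- loop$length_mm
  F <- loop$force_mN
  n <- loop$n
  a1 <- abs(phase_trapz(L, F, 1:loop$i1))
  a2 <- abs(phase_trapz(L, F, loop$i1:loop$i2))
  a3 <- abs(phase_trapz(L, F, c(loop$i2:n, 1L)))
  c(A1 = a1, A2 = a2, A3 = a3) * MN_MM_TO_J
}

#' Net work of a loop
#'
#' Net work per cycle, `A2 - (A1 + A3)`: the work done during shortening
#' minus the work absorbed while lengthening the muscle.  May be negative
#' for pathological loops.
#'
#' @param loop A `wl_loop`.
#' @return Net work in J.
#' @export
net_work <- function(loop) {
  a <- loop_areas(loop)
  unname(a["A2"] - (a["A1"] + a["A3"]))
}

#' Net work by the shoelace formula
#'
#' Signed area of the closed force-length polygon, `-\\int F dL` around the
#' loop including the closure segment.  Serves as an independent cross-check
#' of the phase-decomposed [net_work()]: the two agree to numerical
#' round-off whenever the length signal is monotone within each phase.
#'
#' @param loop A `wl_loop`.
#' @return Net work in J (positive when the loop is traversed so that force
#'   during shortening exceeds force during lengthening).
#' @export
shoelace_work <- function(loop) {
  L <- loop$length_mm
  F <- loop$force_mN
  Lc <- c(L, L[1])
  Fc <- c(F, F[1])
  -sum(diff(Lc) * (Fc[-1] + Fc[-length(Fc)])) / 2 * MN_MM_TO_J
}

#' Instantaneous power of a loop
#'
#' Per-sample power, the product of instantaneous force and instantaneous
#' shortening velocity.  Velocity is estimated by central differences with
#' periodic wrap-around at the cycle ends, and is positive during
#' shortening, so positive power is work done by the muscle.
#'
#' @param loop A `wl_loop`.
#' @return Numeric vector of per-sample power in W.
#' @export
instantaneous_power <- function(loop) {
  loop$force_mN * loop_velocity(loop) * MN_MM_PER_S_TO_W
}

#' Net power output of a loop
#'
#' Average of the instantaneous power over the cycle (which, with the
#' periodic central-difference velocity, equals net work times cycle
#' frequency to round-off), and its mass-normalised value.
#'
#' @param loop A `wl_loop`.
#' @param meta A [wl_meta()] carrying the wet muscle mass.
#' @return List with `P_net_W` and `P_norm_W_per_kg`.
#' @export
net_power <- function(loop, meta) {
  if (!is.numeric(meta$mass_kg) || meta$mass_kg <= 0)
    stop("muscle mass must be positive", call. = FALSE)
  p_inst <- if (!is.null(loop$p_inst_W)) loop$p_inst_W
            else instantaneous_power(loop)
  p <- mean(p_inst)
  list(P_net_W = p, P_norm_W_per_kg = p / meta$mass_kg)
}

#' Loop metrics
#'
#' All per-loop summary quantities as a one-row tibble: phase areas, net
#' work, peak and minimum force, net power and mass-normalised net power.
#'
#' @param loop A `wl_loop`.
#' @param meta A [wl_meta()].
#' @param loop_time_min Minutes into the protocol at which the loop was
#'   recorded (carried through for time-course assembly).
#' @return A one-row tibble.
#' @export
loop_metrics <- function(loop, meta, loop_time_min = NA_real_) {
  a <- loop_areas(loop)
  w <- unname(a["A2"] - (a["A1"] + a["A3"]))
  p <- net_power(loop, meta)
  tibble::tibble(loop_time_min = loop_time_min,
                 A1_J = unname(a["A1"]), A2_J = unname(a["A2"]),
                 A3_J = unname(a["A3"]), Wnet_J = w,
                 Fpeak_mN = max(loop$force_mN), Fmin_mN = min(loop$force_mN),
                 Pnet_W = p$P_net_W, Pnorm_W_per_kg = p$P_norm_W_per_kg)
}

#' Loop metrics for every cycle of a trace
#'
#' Convenience wrapper: segments a trace and computes [loop_metrics()] for
#' each complete cycle.
#'
#' @param trace A [wl_trace()].
#' @param loop_time_min Minutes into the protocol for this recording.
#' @return A tibble with one row per loop.
#' @export
trace_metrics <- function(trace, loop_time_min = NA_real_) {
  loops <- segment_cycles(trace)
  dplyr::bind_rows(lapply(loops, loop_metrics, meta = trace$meta,
                          loop_time_min = loop_time_min))
}
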