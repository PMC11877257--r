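test_that("passive properties are recovered from analytic RC traces", {
  sw <- rc_sweep(R = 400, C = 30, amp = -20)
  expect_equal(resting_potential(sw), -70)
  expect_equal(input_resistance(sw), 400, tolerance = 1e-3)
  expect_lt(abs(membrane_time_constant(sw) - 12), 0.1)
  # doubling R at fixed C doubles the time constant estimate
  sw2 <- rc_sweep(R = 800, C = 30, amp = -20)
  expect_equal(membrane_time_constant(sw2) / membrane_time_constant(sw), 2,
               tolerance = 0.02)
  # tau = 15 ms ideal exponential
  sw3 <- rc_sweep(R = 500, C = 30, amp = -20)
  expect_lt(abs(membrane_time_constant(sw3) - 15), 0.1)
  expect_error(input_resistance(rc_sweep(amp = 20)), "hyperpolarizing")
})

test_that("resting potential averages noise down and rejects spiking baselines", {
  sw <- rc_sweep(amp = -20, noise_sd = 0.5, seed = 4)
  expect_lt(abs(resting_potential(sw) - (-70)), 0.05)
  bad <- rc_sweep(amp = -20)
  bad$voltage_mV[500] <- 20
  expect_error(resting_potential(bad), "spikes")
})

test_that("capacitance follows c = tau / r in pF", {
  expect_equal(capacitance(500, 20), 40)
  expect_equal(capacitance(400, 10), 25)
  expect_error(capacitance(-1, 10), "positive")
  expect_error(capacitance(100, 0), "positive")
})

test_that("Ohm's law examples reproduce reported population values", {
  # deflection -10.784 mV at -20 pA: the SBC-like mean input resistance
  t <- seq(0, 1000, by = 0.1)
  v <- rep(-70, length(t))
  during <- t >= 200 & t <= 700
  v[during] <- -70 - 10.784 * (1 - exp(-(t[during] - 200) / 15))
  v[t > 700] <- -70
  sw <- voltage_sweep(t, v, 10, step_protocol(-20, 200, 500))
  expect_equal(input_resistance(sw), 539.2, tolerance = 1e-3)
})

test_that("spike detection matches a brute-force scan and orders events", {
  cs <- simulate_cell_sweeps(membrane_params())
  sw <- cs$suprathreshold
  sp <- detect_spikes(sw)
  expect_gt(nrow(sp), 1L)
  expect_true(all(diff(sp$threshold_time_ms) > 0))
  expect_true(all(sp$peak_time_ms >= sp$threshold_time_ms))
  expect_true(all(sp$peak_mV > sp$threshold_mV))
  # independent per-sample oracle on a short segment around the first spike
  i0 <- which(sw$time_ms >= sp$peak_time_ms[1] - 20 &
                sw$time_ms <= sp$peak_time_ms[1] + 5)
  v <- sw$voltage_mV[i0]; t <- sw$time_ms[i0]; dt <- 0.1
  pk <- which(v == max(v))[1]
  d2 <- c(NA, (v[3:length(v)] - 2 * v[2:(length(v) - 1)] +
                 v[1:(length(v) - 2)]) / dt^2, NA)
  w1 <- pk - 130; w2 <- pk - 30
  crit <- max(3 * sd(d2[w1:w2], na.rm = TRUE), 20)
  j <- (w2:pk)[which(d2[w2:pk] > crit)[1]]
  expect_equal(sp$threshold_time_ms[1], t[j])
  expect_equal(sp$threshold_mV[1], v[j])
  # subthreshold sweep: no events
  expect_equal(nrow(detect_spikes(cs$subthreshold)), 0L)
})

test_that("simulated spike threshold is recovered within 1 mV", {
  for (g in c(0, 3)) {
    cs <- simulate_cell_sweeps(membrane_params(kslow_conductance_nS = g))
    sp <- detect_spikes(cs$suprathreshold)
    expect_lt(abs(sp$threshold_mV[1] - (-36)), 1)
  }
})

test_that("spike shape geometry is exact on a triangular spike", {
  sw <- triangle_spike_sweep(thr = -40, peak = 10, rise_ms = 2)
  ev <- list(threshold_time_ms = 98, threshold_mV = -40,
             peak_time_ms = 100, peak_mV = 10)
  sh <- spike_shape(ev, sw)
  expect_equal(sh$peak_amplitude_mV, 50)
  expect_equal(sh$half_width_ms, 2, tolerance = 1e-6)
  expect_equal(sh$max_rise_slope_mV_per_ms, 25, tolerance = 0.01)
  # amplitude and half-width invariant to a DC offset
  sw_off <- voltage_sweep(sw$time_ms, sw$voltage_mV + 13, sw$sampling_khz,
                          sw$protocol)
  ev_off <- within(as.data.frame(ev), {
    threshold_mV <- threshold_mV + 13; peak_mV <- peak_mV + 13
  })
  sh_off <- spike_shape(ev_off, sw_off)
  expect_equal(sh_off$peak_amplitude_mV, sh$peak_amplitude_mV)
  expect_equal(sh_off$half_width_ms, sh$half_width_ms)
})

test_that("truncated spikes are rejected by spike_shape", {
  sw <- triangle_spike_sweep(peak_at = 199.5)  # falls off the sweep end
  ev <- list(threshold_time_ms = 197.5, threshold_mV = -40,
             peak_time_ms = 199.5, peak_mV = 10)
  expect_error(spike_shape(ev, sw), "truncated")
})

test_that("depolarizing hump measures overshoot against the late plateau", {
  # analytic trace with a 2 mV early transient over a flat plateau
  t <- seq(0, 2400, by = 0.1)
  v <- rep(-70, length(t))
  during <- t >= 200 & t < 2200
  td <- t[during] - 200
  kern <- exp(-td / 60) * (1 - exp(-td / 5))
  v[during] <- -45 + 2 * kern / max(kern)
  sw <- voltage_sweep(t, v, 10, step_protocol(60, 200, 2000))
  expect_equal(depolarizing_hump(sw), 2, tolerance = 0.1)
  # monotone charging curve: no overshoot, value ~ 0 (slightly negative)
  mono <- rc_sweep(R = 400, C = 30, amp = 50, dur = 2000, total = 2400)
  expect_lt(depolarizing_hump(mono), 0.01)
  expect_gt(depolarizing_hump(mono), -1)
  spiky <- sw; spiky$voltage_mV[5000] <- 30
  expect_error(depolarizing_hump(spiky), "spike")
})

test_that("first-spike latency boundary cases behave", {
  cs <- simulate_cell_sweeps(membrane_params(kslow_conductance_nS = 3))
  lat <- first_spike_latency(cs$suprathreshold)
  true_lat <- attr(cs$suprathreshold, "spike_onsets_ms")[1] - 200
  expect_lt(abs(lat - true_lat), 0.2)
  expect_error(first_spike_latency(cs$subthreshold), "no spike")
  flat <- rc_sweep(amp = -20)
  expect_error(first_spike_latency(flat), "no depolarizing step")
})

test_that("AHP amplitude and duration match an exponential undershoot", {
  sw <- ahp_sweep(depth = 2, tau = 150)
  m <- ahp_measures(sw)
  expect_equal(m$ahp_amplitude_mV, 2, tolerance = 0.01)
  # first time within 0.5 mV of steady state: tau * log(depth / 0.5)
  expect_equal(m$ahp_duration_ms, 150 * log(2 / 0.5), tolerance = 1)
  flat <- ahp_sweep(depth = 1e-6, tau = 150)
  expect_lt(ahp_measures(flat)$ahp_amplitude_mV, 0.01)
})

test_that("firing-pattern classification respects the cutoff and bursts", {
  expect_equal(classify_firing_pattern(1037, 2000, 400), "LS")
  expect_equal(classify_firing_pattern(50, 2000, 400), "NLS")
  expect_equal(classify_firing_pattern(50, 2000, 0), "LS")   # degenerate cutoff
  expect_equal(classify_firing_pattern(10, 2000, 400,
                                       spike_times_ms = c(10, 20, 30),
                                       burst_window_ms = 50), "BS")
  expect_error(classify_firing_pattern(2500, 2000), "exceeds")
})

test_that("features are invariant to a time-axis offset", {
  sw <- rc_sweep(R = 300, C = 30, amp = -20)
  shifted <- voltage_sweep(sw$time_ms + 500, sw$voltage_mV, sw$sampling_khz,
                           step_protocol(-20, 700, 500), "shift")
  expect_equal(input_resistance(shifted), input_resistance(sw))
  expect_equal(membrane_time_constant(shifted), membrane_time_constant(sw),
               tolerance = 1e-9)
})

test_that("end-to-end extraction recovers simulator ground truth", {
  p <- membrane_params(input_resistance_Mohm = 350, capacitance_pF = 25,
                       kslow_conductance_nS = 3, hump_conductance_nS = 0.1)
  cs <- simulate_cell_sweeps(p)
  ep <- extract_properties(cs)
  pr <- ep$properties
  expect_rel_error(pr[["input_resistance_Mohm"]], 350, 0.02)
  expect_rel_error(pr[["time_constant_ms"]], 8.75, 0.02)
  expect_rel_error(pr[["capacitance_pF"]], 25, 0.02)
  expect_lt(abs(pr[["threshold_mV"]] - (-36)), 1)
  expect_identical(ep$firing_pattern, "LS")
  expect_true(all(is.finite(pr)))
  expect_identical(names(pr), canonical_features())
})
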