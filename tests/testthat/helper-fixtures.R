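# Fixtures built in code: analytic traces with known properties, and small
# labelled tables. All deterministic.

# ideal RC charging response to a current step (closed form)
rc_sweep <- function(R = 400, C = 30, amp = -20, onset = 200, dur = 500,
                     total = 1000, khz = 10, E = -70, noise_sd = 0,
                     seed = NULL) {
  t <- seq(0, total, by = 1 / khz)
  tau <- R * C / 1000
  dv <- amp * R / 1000          # pA * MOhm -> mV (steady-state deflection)
  v <- rep(E, length(t))
  during <- t >= onset & t < onset + dur
  v[during] <- E + dv * (1 - exp(-(t[during] - onset) / tau))
  after <- t >= onset + dur
  v_end <- E + dv * (1 - exp(-dur / tau))
  v[after] <- E + (v_end - E) * exp(-(t[after] - onset - dur) / tau)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + rnorm(length(v), sd = noise_sd)
  }
  voltage_sweep(t, v, khz, step_protocol(amp, onset, dur), "rc")
}

# exponential AHP tail: step ends at `off`, undershoot of known depth/tau
ahp_sweep <- function(depth = 2, tau = 150, steady = -70, off = 2200,
                      total = 3400, khz = 10) {
  t <- seq(0, total, by = 1 / khz)
  v <- rep(steady, length(t))
  during <- t >= 200 & t < off
  v[during] <- steady + 5           # depolarized plateau during the step
  post <- t >= off
  v[post] <- steady - depth * exp(-(t[post] - off) / tau)
  voltage_sweep(t, v, khz, step_protocol(300, 200, off - 200), "ahp")
}

# triangular spike of known geometry riding on a flat baseline
triangle_spike_sweep <- function(base = -60, thr = -40, peak = 10,
                                 rise_ms = 2, khz = 10, total = 200,
                                 peak_at = 100) {
  t <- seq(0, total, by = 1 / khz)
  v <- rep(base, length(t))
  up <- t >= peak_at - rise_ms & t <= peak_at
  v[up] <- thr + (peak - thr) * (t[up] - (peak_at - rise_ms)) / rise_ms
  dn <- t > peak_at & t <= peak_at + rise_ms
  v[dn] <- peak - (peak - thr) * (t[dn] - peak_at) / rise_ms
  voltage_sweep(t, v, khz, step_protocol(100, 50, 100), "tri")
}

# small labelled feature table with obvious two-class structure in the
# first `k_info` features
toy_table <- function(n_per = 10, k_info = 2, sep = 4, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(2 * n_per * 12), 2 * n_per, 12,
                 dimnames = list(NULL, canonical_features()))
  vals[seq_len(n_per), seq_len(k_info)] <-
    vals[seq_len(n_per), seq_len(k_info)] + sep
  feature_table(vals, morphology = rep(c("NGC", "SBC-like"), each = n_per))
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
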