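# Extraction of the 12 intrinsic electrophysiological properties from
# current-clamp sweeps. Conventions: the hyperpolarizing (-20 pA, 0.5 s)
# sweep yields input resistance, time constant and capacitance; the
# just-suprathreshold 2 s sweep yields spike shape and first-spike latency;
# the just-below-threshold sweep yields the depolarizing hump; the +300 pA
# sweep yields the AHP measures.

.baseline_window <- function(sweep, min_ms = 100) {
  on <- sweep$protocol$onset_ms
  if (on - sweep$time_ms[1L] < min_ms)
    stop("need at least ", min_ms, " ms of pre-onset baseline")
  which(sweep$time_ms < on)
}

#' Resting membrane potential
#'
#' Mean voltage over the pre-onset, zero-injection baseline.
#'
#' @param sweep A \code{\link{voltage_sweep}} with >= 100 ms baseline before
#'   the step onset.
#' @return Resting potential, mV.
#' @export
resting_potential <- function(sweep) {
  idx <- .baseline_window(sweep)
  if (any(sweep$voltage_mV[idx] > 0))
    stop("spikes detected in baseline; cannot measure resting potential")
  mean(sweep$voltage_mV[idx])
}

.steady_deflection <- function(sweep, window_ms = 100) {
  pr <- sweep$protocol
  base <- mean(sweep$voltage_mV[.baseline_window(sweep)])
  t_end <- pr$onset_ms + pr$duration_ms
  idx <- which(sweep$time_ms > t_end - window_ms & sweep$time_ms <= t_end)
  v <- sweep$voltage_mV[idx]
  # flatness check: linear drift over the averaging window
  slope <- stats::coef(stats::lm.fit(cbind(1, sweep$time_ms[idx]), v))[2L]
  if (abs(slope) * window_ms > 1)
    warning("steady state not reached (drift ",
            signif(slope * window_ms, 2), " mV over the last ", window_ms,
            " ms)")
  list(baseline = base, steady = mean(v), delta = mean(v) - base)
}

#' Input resistance from a hyperpolarizing step
#'
#' Ohm's law on the steady-state response to a -20 pA step:
#' \eqn{R = \Delta V_{steady} / I}, with \eqn{\Delta V} taken as the mean of
#' the final 100 ms of the step minus the pre-onset baseline.
#'
#' @param sweep Sweep with a hyperpolarizing current step.
#' @return Input resistance, MOhm.
#' @export
input_resistance <- function(sweep) {
  amp <- sweep$protocol$amplitude_pA
  if (amp >= 0) stop("input resistance requires a hyperpolarizing step")
  d <- .steady_deflection(sweep)
  1000 * d$delta / amp   # mV / pA -> GOhm -> MOhm via *1000
}

#' Membrane time constant from a hyperpolarizing step
#'
#' Time from step onset for the potential to fall from rest by
#' \eqn{1 - 1/e} (~63\%) of its steady-state deflection, with linear
#' interpolation between samples.
#'
#' @inheritParams input_resistance
#' @return Time constant, ms.
#' @export
membrane_time_constant <- function(sweep) {
  amp <- sweep$protocol$amplitude_pA
  if (amp >= 0) stop("time constant requires a hyperpolarizing step")
  d <- .steady_deflection(sweep)
  target <- d$baseline + (1 - exp(-1)) * d$delta
  on <- sweep$protocol$onset_ms
  idx <- which(sweep$time_ms >= on &
                 sweep$time_ms <= on + sweep$protocol$duration_ms)
  v <- sweep$voltage_mV[idx]; t <- sweep$time_ms[idx]
  below <- if (d$delta < 0) v <= target else v >= target
  j <- which(below)[1L]
  if (is.na(j)) stop("voltage never crosses the 63% level")
  if (j == 1L) return(t[1L] - on)
  # linear interpolation between samples j-1 and j
  frac <- (target - v[j - 1L]) / (v[j] - v[j - 1L])
  (t[j - 1L] + frac * (t[j] - t[j - 1L])) - on
}

#' Cell capacitance from resistance and time constant
#'
#' \eqn{C = \tau / R}: with \eqn{\tau} in ms and \eqn{R} in MOhm the ratio is
#' in nF and is reported in pF.
#'
#' @param r Input resistance, MOhm.
#' @param tau Membrane time constant, ms.
#' @return Capacitance, pF.
#' @examples
#' capacitance(500, 20)  # 40 pF
#' @export
capacitance <- function(r, tau) {
  if (any(r <= 0) || any(tau <= 0)) stop("r and tau must be positive")
  1000 * tau / r
}

#' Detect action potentials and their thresholds
#'
#' Candidate spikes are local maxima above \code{peak_min_mV} preceded by a
#' rise faster than \code{rise_min_mV_per_ms}. For each candidate the
#' threshold is the first point before the peak at which the second
#' derivative of the voltage exceeds three times its standard deviation over
#' the pre-onset window (a 10 ms window ending 1 ms before the peak);
#' derivatives are central differences.
#'
#' @param sweep A \code{\link{voltage_sweep}} sampled at >= 5 kHz.
#' @param peak_min_mV Minimum absolute peak voltage (mV).
#' @param rise_min_mV_per_ms Minimum upstroke slope qualifying a peak.
#' @param sd_mult Threshold criterion multiplier on the pre-window SD.
#' @return Data frame with one row per spike: \code{threshold_time_ms},
#'   \code{threshold_mV}, \code{peak_time_ms}, \code{peak_mV}, ordered by
#'   time. Zero rows if no spikes.
#' @export
detect_spikes <- function(sweep, peak_min_mV = 0, rise_min_mV_per_ms = 10,
                          sd_mult = 3) {
  if (sweep$sampling_khz < 5) stop("spike detection requires >= 5 kHz sampling")
  v <- sweep$voltage_mV; t <- sweep$time_ms; n <- length(v)
  dt <- 1 / sweep$sampling_khz
  dv <- c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * dt), NA)
  d2v <- c(NA, (v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)]) / dt^2, NA)
  is_peak <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n],
               FALSE) & v > peak_min_mV
  peaks <- which(is_peak)
  # require a fast upstroke within 2 ms before the peak
  keep <- vapply(peaks, function(i) {
    lo <- max(2L, i - round(2 / dt))
    any(dv[lo:i] > rise_min_mV_per_ms, na.rm = TRUE)
  }, logical(1))
  peaks <- peaks[keep]
  # collapse maxima closer than 1 ms (plateau-sampled peaks)
  if (length(peaks) > 1L)
    peaks <- peaks[c(TRUE, diff(t[peaks]) > 1)]
  out <- lapply(peaks, function(i) {
    # SD reference window: 10 ms of pre-onset trace ending 3 ms before the
    # peak (i.e. before the upstroke); a floor guards the noiseless case
    w1 <- max(2L, i - round(13 / dt)); w2 <- max(2L, i - round(3 / dt))
    crit <- sd_mult * stats::sd(d2v[w1:w2], na.rm = TRUE)
    if (!is.finite(crit) || crit < 20) crit <- 20
    seg <- w2:i
    j <- seg[which(d2v[seg] > crit)[1L]]
    if (is.na(j)) j <- i - which.max(rev(dv[w2:i])) + 1L  # fall back to max slope
    data.frame(threshold_time_ms = t[j], threshold_mV = v[j],
               peak_time_ms = t[i], peak_mV = v[i])
  })
  if (!length(out))
    return(data.frame(threshold_time_ms = numeric(0),
                      threshold_mV = numeric(0),
                      peak_time_ms = numeric(0), peak_mV = numeric(0)))
  do.call(rbind, out)
}

#' Spike shape measures
#'
#' Peak amplitude (peak minus threshold), half-width (time between the
#' interpolated crossings of threshold + amplitude/2) and maximum rise slope
#' (largest central-difference dV/dt between threshold and peak) for one
#' detected spike.
#'
#' @param event One-row data frame as returned by \code{\link{detect_spikes}}
#'   (or a list with the same fields).
#' @param sweep The sweep the event was detected in.
#' @return Named list: \code{peak_amplitude_mV}, \code{half_width_ms},
#'   \code{max_rise_slope_mV_per_ms}.
#' @export
spike_shape <- function(event, sweep) {
  v <- sweep$voltage_mV; t <- sweep$time_ms
  dt <- 1 / sweep$sampling_khz
  i_thr <- .sweep_index(sweep, event$threshold_time_ms)
  i_pk <- .sweep_index(sweep, event$peak_time_ms)
  amp <- event$peak_mV - event$threshold_mV
  half <- event$threshold_mV + amp / 2
  cross_up <- NULL
  for (j in i_thr:i_pk) if (v[j] >= half) { cross_up <- j; break }
  t_up <- if (cross_up == i_thr) t[cross_up] else
    t[cross_up - 1L] + (half - v[cross_up - 1L]) /
      (v[cross_up] - v[cross_up - 1L]) * dt
  cross_dn <- NULL
  j <- i_pk
  while (j < length(v)) {
    j <- j + 1L
    if (v[j] <= half) { cross_dn <- j; break }
    if (v[j] > v[i_pk]) break  # rising again: next spike before repolarization
  }
  if (is.null(cross_dn))
    stop("spike truncated: no descending half-amplitude crossing")
  t_dn <- t[cross_dn - 1L] + (half - v[cross_dn - 1L]) /
    (v[cross_dn] - v[cross_dn - 1L]) * dt
  dv_seg <- diff(v[i_thr:i_pk]) / dt
  list(peak_amplitude_mV = amp,
       half_width_ms = t_dn - t_up,
       max_rise_slope_mV_per_ms = if (length(dv_seg)) max(dv_seg) else NA_real_)
}

#' Depolarizing hump amplitude
#'
#' Difference between the maximum potential within 200 ms after the onset of
#' a just-below-threshold step and the mean potential over the final 300 ms
#' of the same step. Near zero for a monotone charging curve; positive when
#' a transient inward conductance overshoots the plateau.
#'
#' @param sweep Sweep with a subthreshold depolarizing step >= 500 ms.
#' @return Hump amplitude, mV (not clipped; may be slightly negative).
#' @export
depolarizing_hump <- function(sweep) {
  pr <- sweep$protocol
  if (pr$duration_ms < 500) stop("hump requires a step of at least 500 ms")
  t <- sweep$time_ms; v <- sweep$voltage_mV
  step_idx <- which(t >= pr$onset_ms & t <= pr$onset_ms + pr$duration_ms)
  if (any(v[step_idx] > 0))
    stop("spike detected during the step; hump requires a subthreshold sweep")
  early <- which(t >= pr$onset_ms & t <= pr$onset_ms + 200)
  late <- which(t >= pr$onset_ms + pr$duration_ms - 300 &
                  t <= pr$onset_ms + pr$duration_ms)
  max(v[early]) - mean(v[late])
}

#' First-spike latency
#'
#' Time from the onset of the just-suprathreshold current injection to the
#' threshold of the first spike.
#'
#' @param sweep Sweep with a depolarizing step evoking >= 1 spike.
#' @param spikes Optional precomputed \code{\link{detect_spikes}} output.
#' @return Latency, ms.
#' @export
first_spike_latency <- function(sweep, spikes = NULL) {
  pr <- sweep$protocol
  if (pr$amplitude_pA <= 0)
    stop("no depolarizing step in this sweep")
  if (is.null(spikes)) spikes <- detect_spikes(sweep)
  in_step <- spikes$threshold_time_ms >= pr$onset_ms &
    spikes$threshold_time_ms <= pr$onset_ms + pr$duration_ms
  if (!any(in_step))
    stop("no spike during the step; cannot measure latency")
  min(spikes$threshold_time_ms[in_step]) - pr$onset_ms
}

#' Afterhyperpolarization amplitude and duration
#'
#' After a +300 pA step, the AHP amplitude is the steady-state potential
#' (mean of the last 200 ms of the recording, required flat) minus the
#' minimum potential within 400 ms of step offset, reported positive. The
#' duration is the time from offset until the potential first enters and
#' stays within \code{band_mV} of the steady state for \code{hold_ms}.
#'
#' @param sweep Sweep with a +300 pA step and >= 1 s post-step recording.
#' @param band_mV Steady-state re-entry band (mV).
#' @param hold_ms Time the potential must stay in the band (ms).
#' @return Named list: \code{ahp_amplitude_mV}, \code{ahp_duration_ms}.
#' @export
ahp_measures <- function(sweep, band_mV = 0.5, hold_ms = 50) {
  pr <- sweep$protocol
  off <- pr$onset_ms + pr$duration_ms
  t <- sweep$time_ms; v <- sweep$voltage_mV
  if (t[length(t)] - off < 1000)
    stop("AHP measurement requires >= 1 s of post-step recording")
  tail_idx <- which(t >= t[length(t)] - 200)
  steady <- mean(v[tail_idx])
  if (stats::sd(v[tail_idx]) > 1 ||
      abs(v[tail_idx][1L] - v[tail_idx][length(tail_idx)]) > 1)
    stop("unstable tail: no steady state after the step")
  win <- which(t >= off & t <= off + 400)
  amp <- steady - min(v[win])
  post <- which(t >= off)
  inband <- abs(v[post] - steady) <= band_mV
  need <- round(hold_ms * sweep$sampling_khz)
  r <- rle(inband)
  ends <- cumsum(r$lengths)
  k <- which(r$values & r$lengths >= need)[1L]
  dur <- if (is.na(k)) t[post[length(post)]] - off
         else t[post[ends[k] - r$lengths[k] + 1L]] - off
  list(ahp_amplitude_mV = amp, ahp_duration_ms = max(dur, 0))
}

#' Classify the firing pattern of a cell
#'
#' Late-spiking (LS) if the first-spike latency on a 2 s just-suprathreshold
#' step is at or above \code{ls_cutoff_ms}; otherwise non-late-spiking (NLS).
#' Burst-spiking (BS) is reported only when burst detection is enabled
#' (\code{burst_window_ms} given) and at least three spikes fall within that
#' window of step onset.
#'
#' @param latency_ms First-spike latency from \code{\link{first_spike_latency}}.
#' @param step_duration_ms Duration of the step the latency was measured on.
#' @param ls_cutoff_ms LS/NLS latency cutoff (ms). The default of 400 ms on a
#'   2 s step is a package choice; it is configurable because no standard
#'   numeric cutoff exists.
#' @param spike_times_ms Optional spike threshold times relative to step
#'   onset (needed for burst detection).
#' @param burst_window_ms Optional burst window; enables BS detection.
#' @return One of \code{"LS"}, \code{"NLS"}, \code{"BS"}.
#' @export
classify_firing_pattern <- function(latency_ms, step_duration_ms = 2000,
                                    ls_cutoff_ms = 400,
                                    spike_times_ms = NULL,
                                    burst_window_ms = NULL) {
  if (latency_ms < 0) stop("latency must be >= 0")
  if (latency_ms > step_duration_ms)
    stop("latency exceeds step duration")
  if (!is.null(burst_window_ms) && !is.null(spike_times_ms) &&
      sum(spike_times_ms >= 0 & spike_times_ms <= burst_window_ms) >= 3L)
    return("BS")
  if (latency_ms >= ls_cutoff_ms) "LS" else "NLS"
}

#' Extract all 12 intrinsic properties of one cell
#'
#' Applies the individual extractors to the standard four-sweep protocol set
#' (see \code{\link{simulate_cell_sweeps}} for the expected layout) and
#' returns the canonical 12-feature vector plus the LS/NLS classification.
#'
#' @param sweeps Named list with sweeps \code{hyperpol} (-20 pA, 0.5 s),
#'   \code{subthreshold} (just-below-threshold, 2 s), \code{suprathreshold}
#'   (just-suprathreshold, 2 s) and \code{ahp} (+300 pA, 2 s).
#' @param ls_cutoff_ms LS/NLS cutoff passed to
#'   \code{\link{classify_firing_pattern}}.
#' @return Named list: \code{properties} (named numeric vector in canonical
#'   order) and \code{firing_pattern}.
#' @export
extract_properties <- function(sweeps, ls_cutoff_ms = 400) {
  stopifnot(all(c("hyperpol", "subthreshold", "suprathreshold", "ahp")
                %in% names(sweeps)))
  r <- input_resistance(sweeps$hyperpol)
  tau <- membrane_time_constant(sweeps$hyperpol)
  spikes <- detect_spikes(sweeps$suprathreshold)
  if (nrow(spikes) == 0L) stop("no spikes in the suprathreshold sweep")
  shape <- spike_shape(spikes[1L, ], sweeps$suprathreshold)
  lat <- first_spike_latency(sweeps$suprathreshold, spikes)
  ahp <- ahp_measures(sweeps$ahp)
  props <- c(
    resting_vm_mV = resting_potential(sweeps$hyperpol),
    threshold_mV = spikes$threshold_mV[1L],
    peak_amplitude_mV = shape$peak_amplitude_mV,
    half_width_ms = shape$half_width_ms,
    first_spike_latency_ms = lat,
    max_rise_slope_mV_per_ms = shape$max_rise_slope_mV_per_ms,
    ahp_amplitude_mV = ahp$ahp_amplitude_mV,
    ahp_duration_ms = ahp$ahp_duration_ms,
    input_resistance_Mohm = r,
    time_constant_ms = tau,
    capacitance_pF = capacitance(r, tau),
    depolarizing_hump_mV = depolarizing_hump(sweeps$subthreshold))
  list(properties = props,
       firing_pattern = classify_firing_pattern(
         lat, sweeps$suprathreshold$protocol$duration_ms, ls_cutoff_ms,
         spike_times_ms = spikes$threshold_time_ms -
           sweeps$suprathreshold$protocol$onset_ms))
}
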