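# Synthetic paired recordings (gap-junction and GABAergic pairs) and
# optogenetic datasets with stored ground truth.

# normalized difference-of-exponentials synaptic kernel, peak = 1
.psc_kernel <- function(t, tau_rise = 0.3, tau_decay = 8) {
  k <- (1 - exp(-t / tau_rise)) * exp(-t / tau_decay)
  k[t < 0] <- 0
  tpk <- tau_rise * log(1 + tau_decay / tau_rise)
  k / ((1 - exp(-tpk / tau_rise)) * exp(-tpk / tau_decay))
}

#' Simulate a paired recording
#'
#' Integrates two single-compartment cells, optionally joined by a gap
#' junction whose conductance is chosen so that the steady-state coupling
#' coefficient \eqn{\Delta V_2 / \Delta V_1} equals \code{coupling}
#' (\eqn{g = cc \, g_{L2} / (1 - cc)}), and/or by a GABAergic synapse that
#' triggers an outward postsynaptic current \code{chem_latency_ms} after
#' each presynaptic spike threshold crossing (recorded with the
#' postsynaptic cell voltage-clamped at +6 mV, outward positive).
#'
#' Two stimulation modes: \code{"spikes"} evokes a train of action
#' potentials in cell 1 with brief 600 pA / 2 ms pulses (connection
#' detection); \code{"step"} injects a 2 s subthreshold step into cell 1
#' (coupling-coefficient measurement).
#'
#' @param kind Connection ground truth: \code{"none"}, \code{"electrical"},
#'   \code{"chemical"} or \code{"both"}.
#' @param coupling Target steady-state coupling coefficient in [0, 1).
#' @param gaba_amp_pA Unitary IPSC peak amplitude (pA, outward positive).
#' @param chem_latency_ms Synaptic latency from presynaptic spike threshold
#'   to IPSC onset (ms).
#' @param stim \code{"spikes"} or \code{"step"}.
#' @param n_aps Number of evoked APs in \code{"spikes"} mode.
#' @param ap_interval_ms Interval between evoked APs (ms).
#' @param step_pA Amplitude of the 2 s step in \code{"step"} mode.
#' @param params1,params2 \code{\link{membrane_params}} of the two cells.
#' @param noise_sd_mV Voltage noise SD of the current-clamp traces.
#' @param noise_sd_pA Current noise SD of the voltage-clamp trace.
#' @param holding_mV Holding potential of the voltage-clamped cell.
#' @param sampling_khz Sampling rate (kHz).
#' @param seed Optional seed.
#' @return Object of class \code{"paired_recording"}: \code{pre_sweep}
#'   (cell 1 voltage), \code{post_cc} (cell 2 voltage), \code{post_vc}
#'   (cell 2 holding current, \code{"spikes"} mode only: list with
#'   \code{time_ms}, \code{current_pA}, \code{holding_mV}),
#'   \code{ap_times_ms}, \code{stim_cell}, and a ground-truth
#'   \code{annotations} list.
#' @export
simulate_pair <- function(kind = c("none", "electrical", "chemical", "both"),
                          coupling = 0.05, gaba_amp_pA = 200,
                          chem_latency_ms = 2.6,
                          stim = c("spikes", "step"),
                          n_aps = 8, ap_interval_ms = 500, step_pA = -100,
                          params1 = membrane_params(),
                          params2 = membrane_params(),
                          noise_sd_mV = 0.05, noise_sd_pA = 4,
                          holding_mV = 6, sampling_khz = 10, seed = NULL) {
  kind <- match.arg(kind)
  stim <- match.arg(stim)
  electrical <- kind %in% c("electrical", "both")
  chemical <- kind %in% c("chemical", "both")
  if (electrical && (coupling < 0 || coupling >= 1))
    stop("coupling must be in [0, 1)")
  if (chemical && gaba_amp_pA <= 0)
    stop("chemical connection requires gaba_amp_pA > 0")
  if (chem_latency_ms < 0) stop("chem_latency_ms must be >= 0")

  dt <- 1 / sampling_khz
  pre_ms <- 200
  if (stim == "spikes") {
    sweep_ms <- pre_ms + n_aps * ap_interval_ms
    protocol <- step_protocol(600, pre_ms, 2)  # first pulse; train built below
  } else {
    sweep_ms <- pre_ms + 2000 + 400
    protocol <- step_protocol(step_pA, pre_ms, 2000)
  }
  n <- round(sweep_ms * sampling_khz) + 1L
  time_ms <- (seq_len(n) - 1L) * dt

  I1 <- numeric(n)
  if (stim == "spikes") {
    for (k in seq_len(n_aps)) {
      i0 <- round((pre_ms + (k - 1) * ap_interval_ms) * sampling_khz) + 1L
      I1[i0:(i0 + round(2 * sampling_khz))] <- 600
    }
  } else {
    i0 <- round(pre_ms * sampling_khz) + 1L
    i1 <- round((pre_ms + 2000) * sampling_khz)
    I1[i0:i1] <- step_pA
  }

  gL1 <- 1000 / params1$input_resistance_Mohm
  gL2 <- 1000 / params2$input_resistance_Mohm
  g_gap <- if (electrical) coupling * gL2 / (1 - coupling) else 0
  E1 <- params1$leak_reversal_mV; E2 <- params2$leak_reversal_mV
  C1 <- params1$capacitance_pF;  C2 <- params2$capacitance_pF
  V_T <- params1$spike_threshold_mV
  dT <- params1$spike_sharpness_mV
  body <- .spike_body(V_T, params1$spike_peak_mV, params1$spike_width_ms, dt)
  nbody <- length(body)

  .with_seed(seed, {
    # recording (instrument) noise: white at the sampling rate, added to the
    # stored traces rather than integrated, so event-triggered-average
    # baselines have independent samples
    nz1 <- stats::rnorm(n, sd = noise_sd_mV)
    nz2 <- stats::rnorm(n, sd = noise_sd_mV)
    nzI <- stats::rnorm(n, sd = noise_sd_pA)

    V1 <- numeric(n); V2 <- numeric(n)
    V1[1L] <- E1; V2[1L] <- E2
    ap_times <- numeric(0)
    i <- 1L
    while (i < n) {
      v1 <- V1[i]; v2 <- V2[i]
      I_exp <- gL1 * dT * exp(min((v1 - V_T) / dT, 3))
      dv1 <- ((E1 - v1) * gL1 + I1[i] + I_exp + g_gap * (v2 - v1)) / C1 * dt
      dv2 <- ((E2 - v2) * gL2 + g_gap * (v1 - v2)) / C2 * dt
      v1n <- v1 + dv1
      v2n <- v2 + dv2
      if (v1n >= V_T && stim == "spikes") {
        ap_times <- c(ap_times, time_ms[i + 1L])
        k <- min(nbody, n - i - 1L)
        if (k > 0L) {
          V1[(i + 1L):(i + k)] <- body[seq_len(k)]
          # gap current into the follower during the pasted spike
          for (j in seq_len(k)) {
            v2 <- V2[i + j - 1L]
            V2[i + j] <- v2 + (((E2 - v2) * gL2 +
                                  g_gap * (V1[i + j] - v2)) / C2) * dt
          }
        }
        i <- i + k + 1L
        if (i <= n) {
          V1[i] <- params1$reset_mV
          v2 <- V2[i - 1L]
          V2[i] <- v2 + (((E2 - v2) * gL2 + g_gap * (V1[i] - v2)) / C2) * dt
        }
      } else {
        if (v1n >= V_T) v1n <- V_T - 0.5  # clamp stray crossings in step mode
        V1[i + 1L] <- v1n
        V2[i + 1L] <- v2n
        i <- i + 1L
      }
    }

    pre_sweep <- voltage_sweep(time_ms, V1 + nz1, sampling_khz, protocol, "pre")
    post_cc <- voltage_sweep(time_ms, V2 + nz2, sampling_khz, protocol, "post")
    post_vc <- NULL
    if (stim == "spikes") {
      I_vc <- nzI
      if (chemical) {
        for (t0 in ap_times + chem_latency_ms)
          I_vc <- I_vc + gaba_amp_pA * .psc_kernel(time_ms - t0)
      }
      if (electrical)  # gap-junction artifact into the clamped cell (inward)
        I_vc <- I_vc - g_gap * (V1 - holding_mV)
      post_vc <- list(time_ms = time_ms, current_pA = I_vc,
                      holding_mV = holding_mV)
    }
    structure(
      list(pre_sweep = pre_sweep, post_cc = post_cc, post_vc = post_vc,
           ap_times_ms = ap_times, stim_cell = 1L,
           annotations = list(kind = kind, coupling = coupling,
                              g_gap_nS = g_gap,
                              gaba_amp_pA = if (chemical) gaba_amp_pA else 0,
                              chem_latency_ms = chem_latency_ms)),
      class = "paired_recording")
  })
}

#' @export
print.paired_recording <- function(x, ...) {
  cat(sprintf("Paired recording (%s): %d evoked APs, %s\n",
              x$annotations$kind, length(x$ap_times_ms),
              if (is.null(x$post_vc)) "post in current clamp"
              else "post in current + voltage clamp"))
  invisible(x)
}

.default_opto_groups <- function() {
  data.frame(
    group = c("L2/3PyN", "L2/3IN", "L5/6PyN", "L5/6IN"),
    mean_amp_pA = c(371.9, 233.5, 551.5, 57.0),
    sem_amp_pA = c(72.3, 60.3, 124.1, 13.2),
    mean_lat_ms = c(4.0, 4.0, 3.6, 5.1),
    sem_lat_ms = c(0.5, 0.2, 0.3, 0.3),
    n = c(14L, 18L, 12L, 6L),
    stringsAsFactors = FALSE)
}

#' Simulate an optogenetic eIPSC dataset
#'
#' Per-cell light-evoked IPSC amplitudes and latencies drawn from per-group
#' normal distributions with SD reconstructed as SEM * sqrt(n). Defaults are
#' the reported layer-specific eIPSC summaries for photoactivation of NDNF+
#' L1 interneurons (L2/3 and L5/6 pyramidal neurons and interneurons).
#'
#' @param group_specs Data frame with columns \code{group},
#'   \code{mean_amp_pA}, \code{sem_amp_pA}, \code{mean_lat_ms},
#'   \code{sem_lat_ms}, \code{n}; defaults to the reported four groups.
#' @param seed Optional seed.
#' @return Data frame with one row per cell: \code{group},
#'   \code{amplitude_pA}, \code{latency_ms}.
#' @export
simulate_opto_dataset <- function(group_specs = .default_opto_groups(),
                                  seed = NULL) {
  if (any(group_specs$n < 2L))
    stop("each group needs n >= 2 (variance undefined otherwise)")
  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(group_specs)), function(i) {
      g <- group_specs[i, ]
      data.frame(group = g$group,
                 amplitude_pA = stats::rnorm(g$n, g$mean_amp_pA,
                                             g$sem_amp_pA * sqrt(g$n)),
                 latency_ms = pmax(0.5, stats::rnorm(g$n, g$mean_lat_ms,
                                                     g$sem_lat_ms * sqrt(g$n))),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a light-pulse train and the evoked spikes
#'
#' Spike probability per 5 ms pulse is 1 at stimulation frequencies up to
#' 20 Hz and decays as 20/f above (emulating depolarization block and
#' channelrhodopsin off-kinetics at high rates).
#'
#' @param freq_hz Stimulation frequency (Hz).
#' @param n_pulses Number of pulses.
#' @param seed Optional seed.
#' @return List: \code{pulse_times_ms}, \code{spike_times_ms}.
#' @export
simulate_pulse_train <- function(freq_hz, n_pulses = 7, seed = NULL) {
  if (freq_hz <= 0) stop("freq_hz must be positive")
  pulses <- (seq_len(n_pulses) - 1L) * 1000 / freq_hz
  p <- if (freq_hz <= 20) 1 else 20 / freq_hz
  .with_seed(seed, {
    fired <- stats::runif(n_pulses) <= p
    list(pulse_times_ms = pulses,
         spike_times_ms = pulses[fired] + 2 + stats::runif(sum(fired), 0, 1))
  })
}

#' Simulate a single light-evoked IPSC trace
#'
#' Baseline current noise plus one outward synaptic event of known
#' amplitude beginning \code{latency_ms} after the light onset.
#'
#' @param amplitude_pA Peak eIPSC amplitude (0 = no response).
#' @param latency_ms Light onset to eIPSC onset (ms).
#' @param light_onset_ms Light pulse onset in the trace (ms).
#' @param sweep_ms Trace duration (ms).
#' @param noise_sd_pA Baseline current noise SD.
#' @param sampling_khz Sampling rate.
#' @param seed Optional seed.
#' @return List: \code{time_ms}, \code{current_pA}, \code{light_onset_ms}.
#' @export
simulate_eipsc_trace <- function(amplitude_pA, latency_ms = 4,
                                 light_onset_ms = 100, sweep_ms = 500,
                                 noise_sd_pA = 3, sampling_khz = 10,
                                 seed = NULL) {
  n <- round(sweep_ms * sampling_khz) + 1L
  time_ms <- (seq_len(n) - 1L) / sampling_khz
  .with_seed(seed, {
    cur <- stats::rnorm(n, sd = noise_sd_pA)
    if (amplitude_pA > 0)
      cur <- cur + amplitude_pA *
        .psc_kernel(time_ms - light_onset_ms - latency_ms,
                    tau_rise = 0.5, tau_decay = 15)
    list(time_ms = time_ms, current_pA = cur,
         light_onset_ms = light_onset_ms)
  })
}
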