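# Single-compartment leaky integrate-and-fire simulator with an
# exponential spike-initiation term, a slowly inactivating (D-type-like)
# outward K+ conductance that delays the first spike, a transient inward
# conductance that produces the depolarizing hump of non-late-spiking
# cells, and a spike-triggered adaptation conductance that generates the
# post-train AHP. Units: mV, ms, pA, nS, pF, MOhm throughout; a
# conductance current g[nS] * (V - E)[mV] is directly in pA, and the leak
# term (E_L - V)/R is in nA and is multiplied by 1000.

#' Membrane parameters for the sweep simulator
#'
#' @param leak_reversal_mV Resting/leak reversal potential (mV).
#' @param input_resistance_Mohm Input resistance (MOhm).
#' @param capacitance_pF Cell capacitance (pF). The passive time constant is
#'   \code{R * C / 1000} ms.
#' @param spike_threshold_mV Spike initiation threshold (mV).
#' @param spike_sharpness_mV Exponential sharpening scale of the spike
#'   initiation current (mV).
#' @param reset_mV Post-spike reset potential (mV).
#' @param kslow_conductance_nS Peak conductance of the slowly inactivating
#'   K+ current. Zero gives immediate (non-late) spiking; larger values delay
#'   the first spike at just-suprathreshold drive.
#' @param kslow_tau_ms Inactivation time constant of the slow K+ gate (ms).
#' @param kslow_reversal_mV K+ reversal potential (mV).
#' @param hump_conductance_nS Peak conductance of the transient inward
#'   current producing the depolarizing hump (nS); zero disables it.
#' @param hump_tau_ms Inactivation time constant of the hump gate (ms).
#' @param noise_sd_mV Stationary SD of Ornstein-Uhlenbeck membrane noise (mV).
#' @param spike_peak_mV Peak potential of the stereotyped spike body (mV).
#' @param spike_width_ms Duration of the spike body; its half-width is half
#'   this value.
#' @param ahp_increment_nS Spike-triggered increment of the adaptation (AHP)
#'   conductance (nS).
#' @param ahp_tau_ms Decay time constant of the adaptation conductance (ms).
#' @param seed Optional integer seed making traces reproducible.
#'
#' @return Object of class \code{"membrane_params"}.
#' @export
membrane_params <- function(leak_reversal_mV = -70,
                            input_resistance_Mohm = 400,
                            capacitance_pF = 30,
                            spike_threshold_mV = -36,
                            spike_sharpness_mV = 2,
                            reset_mV = -55,
                            kslow_conductance_nS = 0,
                            kslow_tau_ms = 300,
                            kslow_reversal_mV = -90,
                            hump_conductance_nS = 0,
                            hump_tau_ms = 60,
                            noise_sd_mV = 0,
                            spike_peak_mV = 40,
                            spike_width_ms = 2.4,
                            ahp_increment_nS = 0.03,
                            ahp_tau_ms = 150,
                            seed = NULL) {
  p <- as.list(environment())
  if (p$capacitance_pF <= 0) stop("capacitance_pF must be positive")
  if (p$input_resistance_Mohm <= 0) stop("input_resistance_Mohm must be positive")
  if (p$kslow_tau_ms <= 0) stop("kslow_tau_ms must be positive")
  if (p$noise_sd_mV < 0) stop("noise_sd_mV must be >= 0")
  if (p$spike_peak_mV <= p$spike_threshold_mV)
    stop("spike_peak_mV must exceed spike_threshold_mV")
  structure(p, class = "membrane_params")
}

# run expr with a private RNG stream; leaves the global stream untouched
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stereotyped spike body: raised sine from threshold to peak and back,
# half-width = width/2, max rise slope = amplitude * pi / width
.spike_body <- function(threshold, peak, width_ms, dt) {
  n <- max(3L, round(width_ms / dt))
  t <- seq_len(n - 1L) * dt
  threshold + (peak - threshold) * sin(pi * t / width_ms)^2
}

#' Simulate a current-clamp voltage sweep
#'
#' Integrates the membrane equation
#' \deqn{C dV/dt = (E_L - V)/R + I_{inj}(t) - g_K m(V) a (V - E_K)
#'       + g_h m_h(V) b (E_h - V) + g_L \Delta_T e^{(V - V_T)/\Delta_T}
#'       - g_w w (V - E_K)}
#' with forward-Euler steps at the sampling rate. The slow K+ gate
#' \eqn{a} starts fully available and inactivates with
#' \code{kslow_tau_ms} once the cell is depolarized more than ~10 mV above
#' rest (sigmoidal activation), which holds a just-suprathreshold response
#' below threshold until the conductance has inactivated — the late-spiking
#' mechanism. The transient gate \eqn{b} likewise inactivates (time constant
#' \code{hump_tau_ms}) and, while available, passes an inward current
#' (reversal 0 mV) that produces the early depolarizing hump. When V crosses
#' threshold a stereotyped spike body with known peak, width and slope is
#' emitted and V is reset.
#'
#' @param params A \code{\link{membrane_params}}.
#' @param protocol A \code{\link{step_protocol}}; must fit in the sweep.
#' @param sweep_ms Total sweep duration (ms); default covers the step plus
#'   a 1000 ms tail (for AHP measurement) and the pre-onset baseline.
#' @param sampling_khz Sampling rate and integration step (kHz).
#' @param cell_id Cell identifier stored in the sweep.
#' @return A \code{\link{voltage_sweep}} (attribute \code{"spike_onsets_ms"}
#'   records the simulator's own threshold-crossing times).
#' @examples
#' p <- membrane_params(input_resistance_Mohm = 400, capacitance_pF = 30)
#' sw <- simulate_sweep(p, step_protocol(-20, 200, 500))
#' @export
simulate_sweep <- function(params, protocol,
                           sweep_ms = protocol$onset_ms + protocol$duration_ms + 1000,
                           sampling_khz = 10, cell_id = "sim") {
  stopifnot(inherits(params, "membrane_params"),
            inherits(protocol, "step_protocol"))
  dt <- 1 / sampling_khz
  if (protocol$onset_ms + protocol$duration_ms > sweep_ms)
    stop("protocol does not fit in sweep window")
  n <- round(sweep_ms * sampling_khz) + 1L
  time_ms <- (seq_len(n) - 1L) * dt

  E_L <- params$leak_reversal_mV
  R <- params$input_resistance_Mohm
  C <- params$capacitance_pF
  gL <- 1000 / R                       # nS
  V_T <- params$spike_threshold_mV
  dT <- params$spike_sharpness_mV
  E_K <- params$kslow_reversal_mV
  gK <- params$kslow_conductance_nS
  gH <- params$hump_conductance_nS
  body <- .spike_body(V_T, params$spike_peak_mV, params$spike_width_ms, dt)
  nbody <- length(body)

  I <- rep(protocol$holding_pA, n)
  i0 <- round(protocol$onset_ms * sampling_khz) + 1L
  i1 <- round((protocol$onset_ms + protocol$duration_ms) * sampling_khz)
  I[i0:min(i1, n)] <- I[i0:min(i1, n)] + protocol$amplitude_pA

  tau_m <- R * C / 1000
  noise <- if (params$noise_sd_mV > 0)
    .with_seed(params$seed,
               stats::rnorm(n, sd = params$noise_sd_mV * sqrt(2 * dt / tau_m)))
  else numeric(n)

  V <- numeric(n)
  V[1L] <- E_L
  a <- 1; b <- 1; w <- 0
  spikes <- numeric(0)
  i <- 1L
  while (i < n) {
    v <- V[i]
    act <- 1 / (1 + exp(-(v - (E_L + 10)) / 2))
    I_k <- gK * act * a * (v - E_K)
    I_h <- gH * act * b * (0 - v)
    I_exp <- gL * dT * exp(min((v - V_T) / dT, 3))
    I_w <- w * (v - E_K)
    dv <- ((E_L - v) * gL + I[i] + I_exp - I_k + I_h - I_w) / C * dt
    a <- a + (1 - act - a) / params$kslow_tau_ms * dt
    b <- b + (1 - act - b) / params$hump_tau_ms * dt
    w <- w - w / params$ahp_tau_ms * dt
    v_new <- v + dv + noise[i + 1L]
    if (abs(v_new) > 200)
      stop("integration instability (|V| > 200 mV); reduce conductances or step")
    if (v_new >= V_T) {
      # spike: paste stereotyped body, then reset
      spikes <- c(spikes, time_ms[i + 1L])
      k <- min(nbody, n - i - 1L)
      if (k > 0L) V[(i + 1L):(i + k)] <- body[seq_len(k)]
      i <- i + k + 1L
      if (i <= n) V[i] <- params$reset_mV
      w <- w + params$ahp_increment_nS
      a <- a + (0 - a) * 0.2   # spike-driven extra inactivation of the slow gate
    } else {
      V[i + 1L] <- v_new
      i <- i + 1L
    }
  }
  sw <- voltage_sweep(time_ms, V, sampling_khz, protocol, cell_id)
  attr(sw, "spike_onsets_ms") <- spikes
  sw
}

#' Simulate the standard protocol set for one cell
#'
#' Runs the four stimulus protocols the property extractor expects: a -20 pA
#' 500 ms hyperpolarizing step, a just-below-threshold and a
#' just-suprathreshold 2 s step (found by scanning \code{amplitude_grid_pA}
#' for the smallest step evoking at least one spike), and a +300 pA 2 s step
#' for AHP measurement.
#'
#' @param params A \code{\link{membrane_params}}.
#' @param amplitude_grid_pA Candidate 2 s step amplitudes (pA), ascending.
#' @param sampling_khz Sampling rate (kHz).
#' @param cell_id Cell identifier.
#' @return Named list of sweeps: \code{hyperpol}, \code{subthreshold},
#'   \code{suprathreshold}, \code{ahp}.
#' @export
simulate_cell_sweeps <- function(params,
                                 amplitude_grid_pA = seq(10, 300, by = 10),
                                 sampling_khz = 10, cell_id = "sim") {
  hyper <- simulate_sweep(params, step_protocol(-20, 200, 500),
                          sweep_ms = 1000, sampling_khz = sampling_khz,
                          cell_id = cell_id)
  supra <- NULL; sub <- NULL
  for (k in seq_along(amplitude_grid_pA)) {
    amp <- amplitude_grid_pA[k]
    sw <- simulate_sweep(params, step_protocol(amp, 200, 2000),
                         sweep_ms = 2400, sampling_khz = sampling_khz,
                         cell_id = cell_id)
    if (length(attr(sw, "spike_onsets_ms"))) {
      supra <- sw
      sub_amp <- if (k > 1L) amplitude_grid_pA[k - 1L] else amp / 2
      sub <- simulate_sweep(params, step_protocol(sub_amp, 200, 2000),
                            sweep_ms = 2400, sampling_khz = sampling_khz,
                            cell_id = cell_id)
      break
    }
    sub <- sw
  }
  if (is.null(supra))
    stop("no step in amplitude_grid_pA evoked a spike")
  ahp <- simulate_sweep(params, step_protocol(300, 200, 2000),
                        sweep_ms = 3400, sampling_khz = sampling_khz,
                        cell_id = cell_id)
  list(hyperpol = hyper, subthreshold = sub, suprathreshold = supra, ahp = ahp)
}
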