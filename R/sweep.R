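#' Current-step stimulation protocol
#'
#' Describes a rectangular current step delivered during a sweep: a holding
#' current with a single step of \code{amplitude_pA} starting at
#' \code{onset_ms} and lasting \code{duration_ms}.
#'
#' @param amplitude_pA Signed step amplitude in pA (negative = hyperpolarizing).
#' @param onset_ms Step onset relative to sweep start, ms.
#' @param duration_ms Step duration, ms. Must be positive.
#' @param holding_pA Holding current outside the step, pA.
#'
#' @return An object of class \code{"step_protocol"}.
#' @examples
#' step_protocol(-20, onset_ms = 200, duration_ms = 500)
#' @export
step_protocol <- function(amplitude_pA, onset_ms, duration_ms, holding_pA = 0) {
  stopifnot(is.numeric(amplitude_pA), length(amplitude_pA) == 1L)
  if (!is.finite(onset_ms) || onset_ms < 0)
    stop("onset_ms must be finite and >= 0")
  if (!is.finite(duration_ms) || duration_ms <= 0)
    stop("duration_ms must be positive")
  structure(
    list(amplitude_pA = as.numeric(amplitude_pA),
         onset_ms = as.numeric(onset_ms),
         duration_ms = as.numeric(duration_ms),
         holding_pA = as.numeric(holding_pA)),
    class = "step_protocol")
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf("Current step: %+g pA, onset %g ms, duration %g ms (holding %g pA)\n",
              x$amplitude_pA, x$onset_ms, x$duration_ms, x$holding_pA))
  invisible(x)
}

#' Single current-clamp voltage sweep
#'
#' Bundles a uniformly sampled membrane-voltage trace with its stimulation
#' protocol. Time is in ms, voltage in mV, sampling rate in kHz; time must be
#' strictly increasing with a constant step of \code{1/sampling_khz} ms.
#'
#' @param time_ms Time axis, ms.
#' @param voltage_mV Membrane voltage, mV; same length as \code{time_ms}.
#' @param sampling_khz Sampling rate in kHz.
#' @param protocol A \code{\link{step_protocol}}.
#' @param cell_id Character identifier of the recorded cell.
#'
#' @return An object of class \code{"voltage_sweep"}.
#' @export
voltage_sweep <- function(time_ms, voltage_mV, sampling_khz, protocol,
                          cell_id = "cell") {
  if (length(time_ms) != length(voltage_mV))
    stop("time_ms and voltage_mV must have equal length")
  if (!is.finite(sampling_khz) || sampling_khz <= 0)
    stop("sampling_khz must be positive")
  if (length(time_ms) < 2L) stop("sweep must contain at least two samples")
  dt <- 1 / sampling_khz
  steps <- diff(time_ms)
  if (any(steps <= 0) || max(abs(steps - dt)) > 1e-6 * dt + 1e-9)
    stop("time_ms must increase uniformly by 1/sampling_khz")
  if (!inherits(protocol, "step_protocol"))
    stop("protocol must be a step_protocol")
  # the protocol is on the same absolute time axis as time_ms
  if (protocol$onset_ms < time_ms[1L] - dt / 2 ||
      protocol$onset_ms + protocol$duration_ms >
        time_ms[length(time_ms)] + dt / 2)
    stop("protocol step does not fit inside the sweep window")
  structure(
    list(time_ms = as.numeric(time_ms),
         voltage_mV = as.numeric(voltage_mV),
         sampling_khz = as.numeric(sampling_khz),
         protocol = protocol,
         cell_id = as.character(cell_id)),
    class = "voltage_sweep")
}

#' @export
print.voltage_sweep <- function(x, ...) {
  cat(sprintf("Voltage sweep '%s': %d samples at %g kHz (%.1f ms)\n",
              x$cell_id, length(x$time_ms), x$sampling_khz,
              x$time_ms[length(x$time_ms)] - x$time_ms[1L]))
  print(x$protocol)
  invisible(x)
}

#' @export
plot.voltage_sweep <- function(x, ...) {
  graphics::plot(x$time_ms, x$voltage_mV, type = "l",
                 xlab = "Time (ms)", ylab = "Vm (mV)",
                 main = x$cell_id, ...)
  graphics::abline(v = x$protocol$onset_ms, lty = 3, col = "grey50")
  graphics::abline(v = x$protocol$onset_ms + x$protocol$duration_ms,
                   lty = 3, col = "grey50")
  invisible(x)
}

# index of the sample closest to time t (ms)
.sweep_index <- function(sweep, t) {
  i <- round((t - sweep$time_ms[1L]) * sweep$sampling_khz) + 1L
  max(1L, min(length(sweep$time_ms), as.integer(i)))
}
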