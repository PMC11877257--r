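# Quantification of paired recordings: gap-junction coupling, unitary IPSC
# detection via event-triggered averages, group connectivity maps, opto
# spike fidelity and evoked-IPSC measurement.

#' Gap-junction coupling coefficient
#'
#' Ratio of the steady-state membrane-potential change in the non-stimulated
#' cell to that in the stimulated cell during a 2 s subthreshold step;
#' deflections are the mean of the final 200 ms of the step minus the
#' pre-onset baseline in each cell.
#'
#' @param pair A \code{\link{simulate_pair}}-style \code{paired_recording}
#'   in \code{"step"} mode (post recorded in current clamp).
#' @return Coupling coefficient (attribute \code{"unreliable"} set when
#'   |deltaV| in the stimulated cell is below 1 mV).
#' @export
coupling_coefficient <- function(pair) {
  stopifnot(inherits(pair, "paired_recording"))
  measure <- function(sweep) {
    pr <- sweep$protocol
    t <- sweep$time_ms; v <- sweep$voltage_mV
    win <- t >= pr$onset_ms & t <= pr$onset_ms + pr$duration_ms
    if (any(v[win] > 0))
      stop("spike during the measurement window; use a subthreshold step")
    steady <- mean(v[t >= pr$onset_ms + pr$duration_ms - 200 &
                       t <= pr$onset_ms + pr$duration_ms])
    steady - mean(v[t < pr$onset_ms])
  }
  dv_stim <- measure(pair$pre_sweep)
  dv_post <- measure(pair$post_cc)
  cc <- dv_post / dv_stim
  if (abs(dv_stim) < 1) {
    warning("stimulated-cell deflection < 1 mV; coefficient unreliable")
    attr(cc, "unreliable") <- TRUE
  }
  cc
}

# event-triggered average of y around each event time; returns the average
# segment with its time axis relative to the event
.event_average <- function(time_ms, y, events, pre_ms = 10, post_ms = 10,
                           khz) {
  npre <- round(pre_ms * khz); npost <- round(post_ms * khz)
  segs <- lapply(events, function(e) {
    i <- round((e - time_ms[1L]) * khz) + 1L
    if (i - npre < 1L || i + npost > length(y)) return(NULL)
    y[(i - npre):(i + npost)]
  })
  segs <- segs[!vapply(segs, is.null, TRUE)]
  if (length(segs) < 3L)
    stop("need at least 3 clean events for an event-triggered average")
  avg <- Reduce(`+`, segs) / length(segs)
  list(lag_ms = (seq_along(avg) - npre - 1L) / khz, avg = avg,
       n_events = length(segs))
}

# onset latency at 10% of the averaged peak, linearly interpolated; the
# search never backtracks past i_min (the event itself), so deflection
# already present before the event (e.g. gap-junction transfer of the
# subthreshold ramp) is not counted as negative latency
.onset_latency <- function(lag_ms, avg, baseline, i_peak, i_min = 1L) {
  level <- baseline + 0.1 * (avg[i_peak] - baseline)
  j <- i_peak
  while (j > i_min && avg[j - 1L] - level > 0) j <- j - 1L
  if (j == i_min) return(lag_ms[i_min])
  frac <- (level - avg[j - 1L]) / (avg[j] - avg[j - 1L])
  lag_ms[j - 1L] + frac * (lag_ms[j] - lag_ms[j - 1L])
}

#' Detect electrical coupling from evoked action potentials
#'
#' Spike-triggered average of the postsynaptic current-clamp trace around
#' each presynaptic action potential; coupling is flagged when the peak
#' deflection within \code{window_ms} of the AP exceeds
#' \code{sd_mult} x the SD of the pre-event baseline of the average. The
#' latency is the time from the AP to the 10\%-of-peak onset of the averaged
#' spikelet.
#'
#' @param pair \code{paired_recording} in \code{"spikes"} mode with the post
#'   cell in current clamp.
#' @param window_ms Detection window after the AP (ms).
#' @param sd_mult Detection threshold in baseline SDs.
#' @return List: \code{electrical} (flag), \code{latency_ms} (NA when not
#'   detected), \code{peak_mV}, \code{n_events}.
#' @export
detect_electrical <- function(pair, window_ms = 5, sd_mult = 5) {
  stopifnot(inherits(pair, "paired_recording"))
  if (length(pair$ap_times_ms) < 3L) stop("fewer than 3 evoked APs")
  sw <- pair$post_cc
  eta <- .event_average(sw$time_ms, sw$voltage_mV, pair$ap_times_ms,
                        khz = sw$sampling_khz)
  base_idx <- eta$lag_ms >= -10 & eta$lag_ms <= -1
  base <- mean(eta$avg[base_idx])
  base_sd <- stats::sd(eta$avg[base_idx])
  win <- which(eta$lag_ms >= 0 & eta$lag_ms <= window_ms)
  i_peak <- win[which.max(eta$avg[win] - base)]
  peak <- eta$avg[i_peak] - base
  flag <- is.finite(base_sd) && peak > sd_mult * base_sd
  # latency is referenced to the ETA level at the AP itself, so the
  # gap-junction transfer of the subthreshold drive preceding the spike
  # does not pull the onset before the event
  list(electrical = flag,
       latency_ms = if (flag)
         .onset_latency(eta$lag_ms, eta$avg, eta$avg[win[1L]], i_peak,
                        i_min = win[1L]) else NA_real_,
       peak_mV = peak, n_events = eta$n_events)
}

#' Detect a unitary IPSC in a voltage-clamped postsynaptic cell
#'
#' Event-triggered average of the postsynaptic holding current (+6 mV,
#' outward positive) around each presynaptic AP; a chemical connection is
#' flagged when the outward deflection within \code{window_ms} exceeds
#' \code{sd_mult} x the baseline SD of the average. Amplitude is the peak of
#' the average; latency runs from the AP to the 10\%-of-peak onset.
#'
#' @param pair \code{paired_recording} in \code{"spikes"} mode with a
#'   voltage-clamp post trace.
#' @param window_ms Detection window after the AP (ms).
#' @param sd_mult Detection threshold in baseline SDs.
#' @return List: \code{chemical} (flag), \code{amplitude_pA},
#'   \code{latency_ms}, \code{n_events}.
#' @export
detect_uipsc <- function(pair, window_ms = 10, sd_mult = 5) {
  stopifnot(inherits(pair, "paired_recording"))
  if (is.null(pair$post_vc))
    stop("pair has no voltage-clamp post trace")
  if (length(pair$ap_times_ms) < 3L) stop("fewer than 3 evoked APs")
  vc <- pair$post_vc
  khz <- 1 / diff(vc$time_ms[1:2])
  eta <- .event_average(vc$time_ms, vc$current_pA, pair$ap_times_ms,
                        pre_ms = 10, post_ms = max(20, window_ms + 10),
                        khz = khz)
  base_idx <- eta$lag_ms >= -10 & eta$lag_ms <= -1
  base <- mean(eta$avg[base_idx])
  base_sd <- stats::sd(eta$avg[base_idx])
  win <- which(eta$lag_ms >= 0 & eta$lag_ms <= window_ms)
  i_peak <- win[which.max(eta$avg[win] - base)]
  peak <- eta$avg[i_peak] - base
  flag <- is.finite(base_sd) && peak > sd_mult * base_sd
  list(chemical = flag,
       amplitude_pA = if (flag) peak else NA_real_,
       latency_ms = if (flag)
         .onset_latency(eta$lag_ms, eta$avg, base, i_peak,
                        i_min = win[1L]) else NA_real_,
       n_events = eta$n_events)
}

#' Group-level connectivity map from connection calls
#'
#' Summarises tested and connected pair counts per group pair. Chemical
#' connections are directed (A to B distinct from B to A); electrical
#' coupling is undirected.
#'
#' @param calls Data frame with one row per tested pair: columns
#'   \code{cell_a}, \code{cell_b}, logical \code{electrical},
#'   \code{chemical_ab}, \code{chemical_ba}.
#' @param groups Named vector mapping cell ids to group labels.
#' @return List of two data frames. \code{electrical}: unordered group
#'   pairs with \code{tested}, \code{connected}, \code{proportion};
#'   \code{chemical}: ordered (directed) group pairs likewise.
#' @examples
#' calls <- data.frame(cell_a = c("a", "c"), cell_b = c("b", "d"),
#'                     electrical = c(TRUE, FALSE),
#'                     chemical_ab = c(FALSE, TRUE),
#'                     chemical_ba = c(FALSE, FALSE))
#' connectivity_map(calls, c(a = 2, b = 2, c = 2, d = 3))
#' @export
connectivity_map <- function(calls, groups) {
  empty <- data.frame(from = character(0), to = character(0),
                      tested = integer(0), connected = integer(0),
                      proportion = numeric(0), stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(list(electrical = empty, chemical = empty))
  missing_cells <- setdiff(unique(c(calls$cell_a, calls$cell_b)),
                           names(groups))
  if (length(missing_cells))
    stop("cells without group assignment: ",
         paste(missing_cells, collapse = ", "))
  ga <- as.character(groups[calls$cell_a])
  gb <- as.character(groups[calls$cell_b])
  # electrical: undirected -> order the group pair lexicographically
  e_from <- pmin(ga, gb); e_to <- pmax(ga, gb)
  agg <- function(from, to, connected) {
    key <- paste(from, to, sep = "\r")
    tested <- table(key)
    conn <- tapply(connected, key, sum)
    parts <- strsplit(names(tested), "\r", fixed = TRUE)
    data.frame(from = vapply(parts, `[`, "", 1L),
               to = vapply(parts, `[`, "", 2L),
               tested = as.integer(tested),
               connected = as.integer(conn[names(tested)]),
               proportion = as.numeric(conn[names(tested)] / tested),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  chem <- rbind(
    data.frame(from = ga, to = gb, connected = calls$chemical_ab),
    data.frame(from = gb, to = ga, connected = calls$chemical_ba))
  list(electrical = agg(e_from, e_to, calls$electrical),
       chemical = agg(chem$from, chem$to, chem$connected))
}

#' Spike fidelity of a pulse train
#'
#' Fraction of light pulses followed by at least one spike within one
#' inter-pulse interval (at most one counted per pulse).
#'
#' @param spike_times_ms Spike times (ms).
#' @param pulse_times_ms Regular pulse onsets (ms).
#' @return Fidelity in [0, 1].
#' @export
spike_fidelity <- function(spike_times_ms, pulse_times_ms) {
  if (!length(pulse_times_ms)) stop("no pulses")
  window <- if (length(pulse_times_ms) > 1L)
    stats::median(diff(pulse_times_ms)) else Inf
  hits <- vapply(pulse_times_ms, function(p)
    any(spike_times_ms >= p & spike_times_ms < p + window), logical(1))
  mean(hits)
}

#' Quantify a light-evoked IPSC
#'
#' Peak outward current within 100 ms of the light onset minus the
#' pre-pulse baseline; latency from light onset to the 10\%-of-peak
#' crossing. Returns a no-response result (not an error) when the peak does
#' not exceed \code{sd_mult} x the baseline SD.
#'
#' @param trace List with \code{time_ms} and \code{current_pA} (outward
#'   positive, +6 mV holding), e.g. from \code{\link{simulate_eipsc_trace}}.
#' @param light_onset_ms Light pulse onset (ms); defaults to the trace's
#'   own annotation when present.
#' @param sd_mult No-response threshold in baseline SDs.
#' @return List: \code{response} (flag), \code{amplitude_pA},
#'   \code{latency_ms}.
#' @export
eipsc_quantify <- function(trace, light_onset_ms = trace$light_onset_ms,
                           sd_mult = 3) {
  t <- trace$time_ms
  # 1 ms centred moving average: the eIPSC is slow relative to the sampling
  # noise, so smoothing keeps its peak while suppressing single-sample
  # noise maxima that would otherwise exceed any SD criterion
  khz <- 1 / diff(t[1:2])
  k <- max(1L, round(khz))
  if (k %% 2L == 0L) k <- k + 1L
  cur <- as.numeric(stats::filter(trace$current_pA, rep(1 / k, k),
                                  sides = 2))
  edge <- (k - 1L) / 2L
  cur[seq_len(edge)] <- cur[edge + 1L]
  cur[(length(cur) - edge + 1L):length(cur)] <- cur[length(cur) - edge]
  base_idx <- t < light_onset_ms
  if (!any(base_idx)) stop("no pre-pulse baseline")
  base <- mean(cur[base_idx])
  base_sd <- stats::sd(trace$current_pA[base_idx])
  win <- which(t >= light_onset_ms & t <= light_onset_ms + 100)
  i_peak <- win[which.max(cur[win] - base)]
  amp <- cur[i_peak] - base
  if (!is.finite(base_sd) || amp <= sd_mult * base_sd)
    return(list(response = FALSE, amplitude_pA = NA_real_,
                latency_ms = NA_real_))
  lat <- .onset_latency(t, cur, base, i_peak) - light_onset_ms
  list(response = TRUE, amplitude_pA = amp, latency_ms = lat)
}

#' Compare eIPSC amplitudes before and after a pharmacological block
#'
#' Paired (default) or unpaired Student's t-test with Cohen's d, plus group
#' means and SEMs — the comparison used for bicuculline block and TTX /
#' TTX+4-AP monosynaptic-transmission controls.
#'
#' @param before,after Amplitude series (paired: aligned by cell).
#' @param paired Paired comparison?
#' @return List from \code{\link{t_tests_and_d}}.
#' @export
block_comparison <- function(before, after, paired = TRUE) {
  if (paired && length(before) != length(after))
    stop("paired comparison requires equal lengths")
  t_tests_and_d(before, after, paired = paired)
}
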