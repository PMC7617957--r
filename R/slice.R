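# Intracellular sweep analysis: light-evoked EPSP measurement, monosynaptic
# gating, the paired input-bias index, and intrinsic properties.

#' Measure a light-evoked EPSP from averaged sweeps
#'
#' Sweeps are averaged; the baseline is the mean over the 50 ms preceding
#' light onset; the amplitude is the maximum of `V - baseline` in
#' `(1, search_ms]` ms after light onset. The onset latency is the last
#' upward crossing of `baseline + 2 * SD(baseline)` before the peak, linearly
#' interpolated between samples. If the peak does not clear the noise
#' criterion the cell is scored as non-responding (amplitude 0, onset NA).
#'
#' @param sweeps numeric matrix, time x sweeps (mV), or a vector for a single
#'   (pre-averaged) sweep.
#' @param time_ms time base (ms), one value per row.
#' @param light_onset_ms light onset (ms).
#' @param search_ms post-light window searched for the peak (ms, default 50).
#' @param min_sweeps minimum sweeps required (default 10, the lower end of
#'   the averaging range).
#' @return list with `amplitude_mv`, `onset_ms` (relative to light onset),
#'   `responding` (logical), and `average` (the averaged trace).
#' @export
measure_epsp <- function(sweeps, time_ms, light_onset_ms, search_ms = 50,
                         min_sweeps = 10) {
  if (is.matrix(sweeps)) {
    if (ncol(sweeps) < min_sweeps)
      stop(sprintf("need at least %d sweeps", min_sweeps), call. = FALSE)
    avg <- rowMeans(sweeps)
  } else avg <- as.numeric(sweeps)
  stopifnot(length(avg) == length(time_ms))
  base_idx <- time_ms >= light_onset_ms - 50 & time_ms < light_onset_ms
  if (!any(base_idx))
    stop("no pre-light baseline segment available", call. = FALSE)
  baseline <- mean(avg[base_idx])
  base_sd <- stats::sd(avg[base_idx])
  if (is.na(base_sd)) base_sd <- 0
  win <- which(time_ms > light_onset_ms + 1 &
               time_ms <= light_onset_ms + search_ms)
  if (!length(win)) stop("search window empty", call. = FALSE)
  dv <- avg[win] - baseline
  pk <- which.max(dv)
  amplitude <- dv[pk]
  noise_crit <- max(2 * base_sd, 1e-9)
  if (amplitude < noise_crit)
    return(list(amplitude_mv = 0, onset_ms = NA_real_, responding = FALSE,
                average = avg))
  # onset: last upward crossing of baseline + 2 SD before the peak
  thr <- baseline + noise_crit
  peak_i <- win[pk]
  search_from <- which(time_ms >= light_onset_ms)[1]
  seg <- search_from:peak_i
  above <- avg[seg] > thr
  cross <- which(above & !c(TRUE, above[-length(above)]))
  if (!length(cross)) {
    onset <- time_ms[seg[which(above)[1]]] - light_onset_ms
  } else {
    i2 <- seg[cross[length(cross)]]
    i1 <- i2 - 1L
    frac <- (thr - avg[i1]) / (avg[i2] - avg[i1])
    onset <- time_ms[i1] + frac * (time_ms[i2] - time_ms[i1]) - light_onset_ms
  }
  list(amplitude_mv = amplitude, onset_ms = onset, responding = TRUE,
       average = avg)
}

#' Gate a response as monosynaptic by onset latency
#'
#' Short-latency responses (onset at or below `max_latency_ms`) are
#' consistent with a direct thalamocortical synapse; later or undefined
#' onsets fail the gate.
#'
#' @param onset_ms measured onset latency (ms) or NA.
#' @param max_latency_ms gate (ms, default 6).
#' @return logical flag.
#' @export
gate_monosynaptic <- function(onset_ms, max_latency_ms = 6) {
  !is.na(onset_ms) && onset_ms <= max_latency_ms
}

#' Paired input-bias index
#'
#' `bias = A_ip / (A_ip + A_op)` on the mean EPSP peak amplitudes of a
#' simultaneously recorded IP-derived / other-progenitor-derived (OP) cell
#' pair. 0.5 means equal input strength; the group-level comparison is a
#' one-sample test against 0.5.
#'
#' @param a_ip,a_op mean EPSP amplitudes (mV), both >= 0 and not both zero.
#' @return bias in \[0, 1\].
#' @export
pair_bias <- function(a_ip, a_op) {
  if (a_ip < 0 || a_op < 0) stop("amplitudes must be >= 0", call. = FALSE)
  if (a_ip + a_op <= 0)
    stop("both amplitudes zero: bias undefined", call. = FALSE)
  a_ip / (a_ip + a_op)
}

#' Score a paired sweep set
#'
#' Measures both cells of every pair, gates on monosynaptic onset, and
#' computes the bias index.
#'
#' @param sweep_set list from [gen_paired_epsp_sweeps()] (or the same shape).
#' @param max_latency_ms monosynaptic gate (ms).
#' @return data.frame: `pair_id`, `a_ip`, `a_op`, `onset_ip`, `onset_op`,
#'   `bias`, `monosynaptic_ok`.
#' @export
score_pairs <- function(sweep_set, max_latency_ms = 6) {
  rows <- lapply(sweep_set$pairs, function(p) {
    ip <- measure_epsp(p$ip, p$time_ms, p$light_onset_ms)
    op <- measure_epsp(p$op, p$time_ms, p$light_onset_ms)
    data.frame(pair_id = p$pair_id, a_ip = ip$amplitude_mv,
               a_op = op$amplitude_mv, onset_ip = ip$onset_ms,
               onset_op = op$onset_ms,
               bias = pair_bias(ip$amplitude_mv, op$amplitude_mv),
               monosynaptic_ok = gate_monosynaptic(ip$onset_ms, max_latency_ms) &&
                 gate_monosynaptic(op$onset_ms, max_latency_ms))
  })
  do.call(rbind, rows)
}

#' Intrinsic membrane and spiking properties from current steps
#'
#' The resting membrane potential (RMP) is the mean pre-stimulus voltage
#' across the 0 pA sweeps. Spikes are detected as upward crossings of a
#' dV/dt criterion; per spike, the threshold is the voltage at the crossing
#' and the amplitude is the subsequent peak minus threshold. Frequency and
#' inter-spike intervals are reported per current step.
#'
#' @param sweeps list of sweeps, each a list with `v` (mV), `time_ms`,
#'   `current_pa`, and `stim_ms` = c(start, end) of the step.
#' @param dvdt_crit spike-detection criterion (mV/ms, default 20).
#' @return list with `rmp_mv` and `steps` (data.frame: `current_pa`,
#'   `n_spikes`, `freq_hz`, `spike_threshold_mv`, `spike_amplitude_mv`) and
#'   `isis_ms` (list per step).
#' @export
intrinsic_properties <- function(sweeps, dvdt_crit = 20) {
  zero <- Filter(function(s) s$current_pa == 0, sweeps)
  if (!length(zero))
    stop("no 0 pA sweeps: RMP undefined", call. = FALSE)
  rmp <- mean(vapply(zero, function(s)
    mean(s$v[s$time_ms < s$stim_ms[1]]), numeric(1)))
  res <- lapply(sweeps, function(s) {
    dt <- diff(s$time_ms[1:2])
    dvdt <- c(0, diff(s$v)) / dt
    above <- dvdt >= dvdt_crit
    onsets <- which(above & !c(FALSE, above[-length(above)]))
    onsets <- onsets[s$time_ms[onsets] >= s$stim_ms[1] &
                     s$time_ms[onsets] <= s$stim_ms[2]]
    thr <- peak <- numeric(0)
    if (length(onsets)) {
      ends <- c(onsets[-1], length(s$v))
      thr <- s$v[onsets]
      peak <- vapply(seq_along(onsets), function(i)
        max(s$v[onsets[i]:ends[i]]), numeric(1))
    }
    dur_s <- diff(s$stim_ms) / 1000
    spike_t <- s$time_ms[onsets]
    list(current_pa = s$current_pa, n_spikes = length(onsets),
         freq_hz = length(onsets) / dur_s,
         spike_threshold_mv = if (length(thr)) mean(thr) else NA_real_,
         spike_amplitude_mv = if (length(peak)) mean(peak - thr) else NA_real_,
         isis_ms = if (length(spike_t) > 1) diff(spike_t) else numeric(0))
  })
  steps <- do.call(rbind, lapply(res, function(r)
    data.frame(current_pa = r$current_pa, n_spikes = r$n_spikes,
               freq_hz = r$freq_hz, spike_threshold_mv = r$spike_threshold_mv,
               spike_amplitude_mv = r$spike_amplitude_mv)))
  list(rmp_mv = rmp, steps = steps, isis_ms = lapply(res, `[[`, "isis_ms"))
}
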