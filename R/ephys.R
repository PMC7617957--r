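# Extracellular signal conditioning and unit classification.

#' Multichannel probe recording
#'
#' Container for a channels x time voltage matrix with probe geometry.
#' Channels are ordered superficial to deep.
#'
#' @param samples numeric matrix, channels x time (uV).
#' @param fs sampling rate (Hz).
#' @param channel_spacing inter-channel spacing (um).
#' @return an object of class `probe_recording`.
#' @export
probe_recording <- function(samples, fs, channel_spacing) {
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (!is.numeric(channel_spacing) || channel_spacing <= 0)
    stop("channel_spacing must be > 0", call. = FALSE)
  structure(list(samples = samples, fs = fs,
                 channel_spacing = channel_spacing,
                 n_channels = nrow(samples)),
            class = "probe_recording")
}

# Zero-phase frequency-domain filter. `mag` maps frequency (Hz, >= 0) to a
# real magnitude response; it is applied symmetrically to the two-sided
# spectrum, so the output is real and has zero phase delay (latencies are
# preserved, which every downstream statistic depends on).
.fft_filter <- function(x, fs, mag) {
  n <- length(x)
  f <- seq(0, n - 1) / n * fs
  f <- pmin(f, fs - f)                    # fold to [0, fs/2]
  h <- mag(f)
  Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
}

# order-4 Butterworth power responses (forward-backward equivalent magnitude)
.butter_lp <- function(fc, order = 4) function(f) 1 / (1 + (f / fc)^(2 * order))
.butter_hp <- function(fc, order = 4) function(f) {
  r <- numeric(length(f))
  nz <- f > 0
  r[nz] <- 1 / (1 + (fc / f[nz])^(2 * order))
  r
}
.notch <- function(f0, q = 30) function(f) {
  bw <- f0 / q / 2                        # ~half-power half-width
  1 - exp(-((f - f0)^2) / (2 * bw^2))
}

#' Split a recording into multiunit and LFP bands
#'
#' Zero-phase band-pass 300-6000 Hz for the multiunit (MUA) band; zero-phase
#' low-pass below 300 Hz plus a 50 Hz notch for the LFP band. Filtering is
#' done in the frequency domain with order-4 Butterworth power responses
#' (the magnitude a forward-backward time-domain Butterworth would apply),
#' which preserves length and introduces no phase delay.
#'
#' @param rec a [probe_recording()], or a single-channel numeric vector.
#' @param fs sampling rate (Hz); taken from `rec` when it is a
#'   `probe_recording`.
#' @return list with `mua` and `lfp`, each the same shape as the input.
#' @export
split_bands <- function(rec, fs = NULL) {
  if (inherits(rec, "probe_recording")) {
    x <- rec$samples; fs <- rec$fs
  } else {
    x <- rec
    if (is.null(fs)) stop("fs required for a bare signal", call. = FALSE)
  }
  if (fs < 12000)
    stop("fs must be >= 12 kHz for the 6 kHz MUA band edge (Nyquist)",
         call. = FALSE)
  mua_mag <- function(f) .butter_hp(300)(f) * .butter_lp(6000)(f)
  lfp_mag <- function(f) .butter_lp(300)(f) * .notch(50)(f)
  filt <- function(v, mag) .fft_filter(v, fs, mag)
  if (is.matrix(x)) {
    mua <- t(apply(x, 1, filt, mag = mua_mag))
    lfp <- t(apply(x, 1, filt, mag = lfp_mag))
  } else {
    mua <- filt(x, mua_mag)
    lfp <- filt(x, lfp_mag)
  }
  list(mua = mua, lfp = lfp)
}

#' Detect multiunit events by robust amplitude thresholding
#'
#' Estimates the noise SD of a band-passed trace as the normalised median
#' absolute deviation, `sigma = median(|x - median(x)|) / 0.6745`, and
#' returns the times of negative-going crossings below `-k * sigma`, with a
#' refractory lockout so each event is counted once.
#'
#' @param x single-channel band-passed trace (uV).
#' @param fs sampling rate (Hz).
#' @param k threshold multiplier (default 5).
#' @param lockout_ms refractory lockout (ms, default 1).
#' @return sorted event times (s).
#' @export
detect_mua <- function(x, fs, k = 5, lockout_ms = 1) {
  stopifnot(is.numeric(x), length(x) > 1)
  sigma <- stats::median(abs(x - stats::median(x))) / 0.6745
  if (sigma == 0)
    stop("MAD of the trace is zero (constant signal): threshold undefined",
         call. = FALSE)
  thr <- -k * sigma
  below <- x < thr
  crossings <- which(below & !c(FALSE, below[-length(below)]))
  if (!length(crossings)) return(numeric(0))
  lock <- max(1L, round(lockout_ms / 1000 * fs))
  keep <- crossings[1]
  last <- crossings[1]
  for (i in crossings[-1]) {
    if (i - last >= lock) { keep <- c(keep, i); last <- i }
  }
  (keep - 1) / fs
}

#' Current source density by central second spatial difference
#'
#' `csd[i, ] = (lfp[i-1, ] - 2 lfp[i, ] + lfp[i+1, ]) / spacing^2` for interior
#' channels; edge channels are dropped. Under this sign convention a sink
#' (net inward current, e.g. the thalamorecipient layer) is a local minimum.
#'
#' @param lfp channels x time LFP matrix (uV), superficial to deep, or a
#'   [probe_recording()].
#' @param spacing channel spacing (um); taken from a `probe_recording`.
#' @param smooth if `TRUE`, apply a 3-channel Hamming smoothing across
#'   channels before differencing (off by default).
#' @return object of class `csd_profile`: list with `values` (interior
#'   channels x time), `channels` (original 1-based indices of the interior
#'   channels), and `spacing`.
#' @export
compute_csd <- function(lfp, spacing = NULL, smooth = FALSE) {
  if (inherits(lfp, "probe_recording")) {
    spacing <- lfp$channel_spacing; lfp <- lfp$samples
  }
  stopifnot(is.matrix(lfp))
  if (is.null(spacing)) stop("spacing required", call. = FALSE)
  n <- nrow(lfp)
  if (n < 3) stop("CSD needs at least 3 channels", call. = FALSE)
  if (smooth) {
    w <- c(0.23, 0.54, 0.23)
    sm <- lfp
    sm[2:(n - 1), ] <- w[1] * lfp[1:(n - 2), ] + w[2] * lfp[2:(n - 1), ] +
      w[3] * lfp[3:n, ]
    lfp <- sm
  }
  vals <- (lfp[1:(n - 2), , drop = FALSE] - 2 * lfp[2:(n - 1), , drop = FALSE] +
           lfp[3:n, , drop = FALSE]) / spacing^2
  structure(list(values = vals, channels = 2:(n - 1), spacing = spacing),
            class = "csd_profile")
}

#' Assign cortical layers from the deflection-evoked CSD
#'
#' Operationalises "the shortest-latency sink is L4": for each interior
#' channel the sink latency is the first time after deflection onset at which
#' the CSD falls below `sink_frac` times the global (negative) CSD minimum.
#' The channel with the smallest such latency is L4 (ties broken by larger
#' sink amplitude); channels superficial to it are L2/3, deeper ones
#' below-L4.
#'
#' @param csd a `csd_profile` from [compute_csd()], computed on the
#'   PW-triggered average.
#' @param onset_s deflection onset (s) on the CSD time base.
#' @param fs sampling rate of the CSD time axis (Hz).
#' @param sink_frac onset threshold as a fraction of the global minimum
#'   (default 0.3).
#' @return list with `l4_channel` (original channel index), `sink_latency_ms`,
#'   and `layers` (character vector over the interior channels:
#'   "L2/3", "L4", "below-L4").
#' @export
assign_layers <- function(csd, onset_s, fs, sink_frac = 0.3) {
  stopifnot(inherits(csd, "csd_profile"))
  v <- csd$values
  gmin <- min(v)
  if (!is.finite(gmin) || gmin >= 0)
    stop("no identifiable sink: CSD has no negative deflection", call. = FALSE)
  thr <- sink_frac * gmin                  # negative threshold
  onset_idx <- floor(onset_s * fs) + 1L
  post <- v[, onset_idx:ncol(v), drop = FALSE]
  lat <- apply(post, 1, function(row) {
    i <- which(row < thr)
    if (!length(i)) NA_real_ else (i[1] - 1) / fs * 1000
  })
  amp <- apply(post, 1, min)
  if (all(is.na(lat)))
    stop("no identifiable sink: no channel crosses the sink threshold",
         call. = FALSE)
  best <- which(lat == min(lat, na.rm = TRUE))
  if (length(best) > 1) best <- best[which.min(amp[best])]  # deeper sink wins
  l4 <- csd$channels[best]
  layers <- ifelse(csd$channels < l4, "L2/3",
                   ifelse(csd$channels == l4, "L4", "below-L4"))
  list(l4_channel = l4, sink_latency_ms = lat[best], layers = layers,
       sink_latency_by_channel = stats::setNames(lat, csd$channels))
}

#' Classify a unit as regular- or fast-spiking from its waveform
#'
#' Measures the trough-to-peak time (template minimum to the subsequent
#' maximum) and applies the 0.5 ms criterion: `t2p >= 0.5` ms is
#' regular-spiking (RS, primarily excitatory), `< 0.5` ms fast-spiking (FS,
#' putative interneuron). The boundary value is assigned to RS.
#'
#' @param waveform numeric template (uV), or a unit list with `waveform` and
#'   `fs` elements.
#' @param fs template sampling rate (Hz).
#' @return list with `cell_class` ("RS" or "FS") and `t2p_ms`.
#' @export
classify_waveform <- function(waveform, fs = NULL) {
  if (is.list(waveform)) { fs <- waveform$fs; waveform <- waveform$waveform }
  stopifnot(is.numeric(waveform), length(waveform) > 2)
  if (is.null(fs)) stop("fs required", call. = FALSE)
  trough <- which.min(waveform)
  if (trough >= length(waveform))
    stop("waveform has no samples after the trough", call. = FALSE)
  after <- waveform[(trough + 1):length(waveform)]
  peak_rel <- which.max(after)
  rise <- after[peak_rel] - waveform[trough]
  # a genuine repolarisation peak, not residual decay noise
  if (rise < 0.05 * diff(range(waveform)))
    stop("waveform has no post-trough peak", call. = FALSE)
  t2p <- peak_rel / fs * 1000
  list(cell_class = if (t2p >= 0.5) "RS" else "FS", t2p_ms = t2p)
}

#' Classify a unit as optotagged from light-evoked response latency
#'
#' For each light pulse, the trial latency is the first spike within
#' `(0, window_ms]` of pulse onset; reliability is the fraction of pulses
#' with such a spike. A unit is optotagged when its mean latency is below
#' 5 ms and its reliability reaches `reliability_floor`; all other units are
#' unlabeled (longer-latency or absent light responses).
#'
#' @param spike_times sorted spike times (s), or a unit list with
#'   `spike_times`.
#' @param light_onsets light pulse onsets (s), or a stimulus-log data.frame
#'   with `onset` and `kind` columns (rows with `kind == "light"` are used).
#' @param window_ms response window after the pulse (ms, default 10 — the
#'   in vivo pulse duration).
#' @param max_latency_ms tagging criterion on the mean latency (ms, default 5).
#' @param reliability_floor minimum fraction of responsive trials
#'   (default 0.5).
#' @return list with `tag_class` ("optotagged" or "unlabeled"),
#'   `mean_latency_ms`, and `reliability`.
#' @export
classify_optotag <- function(spike_times, light_onsets, window_ms = 10,
                             max_latency_ms = 5, reliability_floor = 0.5) {
  if (is.list(spike_times) && !is.null(spike_times$spike_times))
    spike_times <- spike_times$spike_times
  if (is.data.frame(light_onsets))
    light_onsets <- light_onsets$onset[light_onsets$kind == "light"]
  if (!length(light_onsets))
    stop("no light events in the stimulus log", call. = FALSE)
  lat <- vapply(light_onsets, function(on) {
    s <- spike_times[spike_times > on & spike_times <= on + window_ms / 1000]
    if (length(s)) (s[1] - on) * 1000 else NA_real_
  }, numeric(1))
  reliability <- mean(!is.na(lat))
  mean_lat <- if (any(!is.na(lat))) mean(lat, na.rm = TRUE) else NA_real_
  tagged <- !is.na(mean_lat) && mean_lat < max_latency_ms &&
    reliability >= reliability_floor
  list(tag_class = if (tagged) "optotagged" else "unlabeled",
       mean_latency_ms = mean_lat, reliability = reliability)
}
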