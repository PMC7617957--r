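# Synthetic-data generators with known ground truth.
#
# Every generator (i) validates its parameter object, (ii) seeds the RNG from
# params$seed so identical parameters give identical output, and (iii) returns
# a ground-truth table sufficient to score every downstream classifier or
# estimator without re-deriving truth.

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single finite probability in [0, 1]", name),
         call. = FALSE)
  x
}

.check_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop(sprintf("'%s' must be a single finite %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  x
}

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min)
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

#' Parameters for the synthetic extracellular session generator
#'
#' Describes a simulated awake-recording session: a population of units with
#' Poisson spontaneous firing, Bernoulli-per-deflection evoked spikes to
#' principal-whisker (PW) and adjacent-whisker (AW) deflections, a tagged
#' subpopulation responding to light at short latency, and bimodal spike
#' waveform widths so that regular-spiking (RS) vs fast-spiking (FS)
#' ground-truth labels are unambiguous.
#'
#' The Bernoulli evoked model (at most one evoked spike per deflection) makes
#' the true selectivity index exactly `p_pw / (p_pw + p_aw)`, giving a
#' closed-form truth for recovery tests.
#'
#' @param n_units number of units.
#' @param trials_per_whisker deflection trials per whisker.
#' @param p_pw,p_aw per-deflection evoked-spike probability in \[0, 1\].
#' @param evoked_latency_mean,evoked_latency_sd evoked latency (ms), truncated
#'   normal on (0, 50\].
#' @param spont_rate spontaneous rate (Hz).
#' @param tagged_fraction fraction of units that are opsin-tagged.
#' @param tag_latency_mean,tag_latency_sd light-evoked latency of tagged
#'   units (ms).
#' @param untagged_latency_mean light-evoked latency of untagged units (ms),
#'   or `NA` for no light response at all.
#' @param waveform_t2p_rs,waveform_t2p_fs trough-to-peak times (ms) for RS and
#'   FS templates; must straddle the 0.5 ms criterion (FS < 0.5 < RS).
#' @param fs_fraction fraction of units given the FS template.
#' @param n_light_trials number of light pulses in the session.
#' @param sampling_rate waveform template sampling rate (Hz).
#' @param seed RNG seed.
#' @return an object of class `ephys_sim_params`.
#' @export
ephys_sim_params <- function(n_units = 30L, trials_per_whisker = 100L,
                             p_pw = 0.5, p_aw = 0.3,
                             evoked_latency_mean = 10, evoked_latency_sd = 2,
                             spont_rate = 2, tagged_fraction = 0.5,
                             tag_latency_mean = 3, tag_latency_sd = 0.5,
                             untagged_latency_mean = 8,
                             waveform_t2p_rs = 0.8, waveform_t2p_fs = 0.3,
                             fs_fraction = 0.3, n_light_trials = 50L,
                             sampling_rate = 30000, seed = 1L) {
  p <- list(
    n_units = .check_count(n_units, "n_units"),
    trials_per_whisker = .check_count(trials_per_whisker, "trials_per_whisker"),
    p_pw = .check_prob(p_pw, "p_pw"), p_aw = .check_prob(p_aw, "p_aw"),
    evoked_latency_mean = .check_pos(evoked_latency_mean, "evoked_latency_mean"),
    evoked_latency_sd = .check_pos(evoked_latency_sd, "evoked_latency_sd", strict = FALSE),
    spont_rate = .check_pos(spont_rate, "spont_rate", strict = FALSE),
    tagged_fraction = .check_prob(tagged_fraction, "tagged_fraction"),
    tag_latency_mean = .check_pos(tag_latency_mean, "tag_latency_mean"),
    tag_latency_sd = .check_pos(tag_latency_sd, "tag_latency_sd", strict = FALSE),
    untagged_latency_mean = if (is.na(untagged_latency_mean)) NA_real_
      else .check_pos(untagged_latency_mean, "untagged_latency_mean"),
    waveform_t2p_rs = .check_pos(waveform_t2p_rs, "waveform_t2p_rs"),
    waveform_t2p_fs = .check_pos(waveform_t2p_fs, "waveform_t2p_fs"),
    fs_fraction = .check_prob(fs_fraction, "fs_fraction"),
    n_light_trials = .check_count(n_light_trials, "n_light_trials", min = 0L),
    sampling_rate = .check_pos(sampling_rate, "sampling_rate"),
    seed = .check_count(seed, "seed", min = 0L))
  if (!(p$waveform_t2p_fs < 0.5 && 0.5 < p$waveform_t2p_rs))
    stop("require waveform_t2p_fs < 0.5 ms < waveform_t2p_rs so ground-truth ",
         "RS/FS labels are unambiguous", call. = FALSE)
  structure(p, class = "ephys_sim_params")
}

# Biphasic waveform template with an exact trough-to-peak time (ms).
.make_waveform <- function(t2p_ms, fs) {
  dt <- 1000 / fs                       # ms per sample
  t <- seq(0, 2.5, by = dt)
  trough_t <- 0.6
  peak_t <- trough_t + t2p_ms
  w <- -exp(-((t - trough_t) / 0.12)^2) + 0.45 * exp(-((t - peak_t) / 0.25)^2)
  # snap extrema onto grid points so the measured t2p is exact
  w
}

.rtnorm_latency <- function(n, mean, sd, lo = 0, hi = 50) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lo | x[bad] > 50]
  }
  x
}

#' Generate a synthetic optotagging/whisker-mapping session
#'
#' Builds a stimulus log (interleaved PW and AW single deflections at 1 s
#' spacing followed by a block of light pulses), a set of spike units, and a
#' ground-truth table. Spike trains are homogeneous-Poisson background at
#' `spont_rate` plus, for each deflection of the matching whisker, a
#' Bernoulli(`p`) evoked spike at truncated-normal latency. Tagged units spike
#' after every light pulse at the tag latency; untagged units respond at
#' `untagged_latency_mean` (or not at all if that is `NA`).
#'
#' @param params an [ephys_sim_params()] object.
#' @return a list with `units` (list of spike units: `unit_id`, `spike_times`
#'   in s, `waveform`, `fs`), `log` (data.frame of `onset`, `kind`,
#'   `train_index`), and `truth` (data.frame with `unit_id`, `true_si`,
#'   `tagged`, `cell_class`, `p_pw`, `p_aw`).
#' @export
gen_ephys_session <- function(params) {
  stopifnot(inherits(params, "ephys_sim_params"))
  set.seed(params$seed)
  nt <- params$trials_per_whisker

  # interleaved PW/AW deflections at 1 s, then light pulses at 1 s
  defl_onsets <- seq_len(2L * nt) * 1.0
  kinds <- rep(c("PW", "AW"), nt)
  light_onsets <- if (params$n_light_trials > 0)
    max(defl_onsets) + seq_len(params$n_light_trials) * 1.0 else numeric(0)
  log <- data.frame(
    onset = c(defl_onsets, light_onsets),
    kind = c(kinds, rep("light", length(light_onsets))),
    train_index = NA_integer_,
    stringsAsFactors = FALSE)
  t_end <- max(log$onset) + 1.0

  n_tag <- round(params$tagged_fraction * params$n_units)
  n_fs <- round(params$fs_fraction * params$n_units)
  tagged <- seq_len(params$n_units) <= n_tag
  cell_class <- rep("RS", params$n_units)
  if (n_fs > 0) cell_class[params$n_units - seq_len(n_fs) + 1L] <- "FS"

  wf_rs <- .make_waveform(params$waveform_t2p_rs, params$sampling_rate)
  wf_fs <- .make_waveform(params$waveform_t2p_fs, params$sampling_rate)

  units <- vector("list", params$n_units)
  for (u in seq_len(params$n_units)) {
    spont <- if (params$spont_rate > 0)
      sort(stats::runif(stats::rpois(1, params$spont_rate * t_end), 0, t_end))
      else numeric(0)
    evoked <- numeric(0)
    for (kind in c("PW", "AW")) {
      p <- if (kind == "PW") params$p_pw else params$p_aw
      on <- defl_onsets[kinds == kind]
      hit <- stats::runif(length(on)) < p
      if (any(hit)) {
        lat <- .rtnorm_latency(sum(hit), params$evoked_latency_mean,
                               params$evoked_latency_sd)
        evoked <- c(evoked, on[hit] + lat / 1000)
      }
    }
    light_resp <- numeric(0)
    lat_mean <- if (tagged[u]) params$tag_latency_mean else params$untagged_latency_mean
    if (length(light_onsets) && !is.na(lat_mean)) {
      lat <- .rtnorm_latency(length(light_onsets), lat_mean, params$tag_latency_sd)
      light_resp <- light_onsets + lat / 1000
    }
    units[[u]] <- list(
      unit_id = u,
      spike_times = sort(c(spont, evoked, light_resp)),
      waveform = if (cell_class[u] == "RS") wf_rs else wf_fs,
      fs = params$sampling_rate)
  }

  denom <- params$p_pw + params$p_aw
  truth <- data.frame(
    unit_id = seq_len(params$n_units),
    true_si = if (denom > 0) params$p_pw / denom else NA_real_,
    tagged = tagged,
    cell_class = cell_class,
    p_pw = params$p_pw, p_aw = params$p_aw,
    stringsAsFactors = FALSE)
  list(units = units, log = log, truth = truth)
}

#' Parameters for the laminar LFP generator
#'
#' @param n_channels number of channels on the (single-shank) probe.
#' @param channel_spacing inter-channel spacing (um).
#' @param sink_channel 1-based channel index of the planted sink; must be an
#'   interior channel (the second spatial derivative is undefined at edges).
#' @param sink_latency sink-peak latency after deflection onset (ms).
#' @param sink_width sink spatial SD (channels).
#' @param sink_tau sink temporal SD (ms).
#' @param noise_sd additive voltage noise SD (uV).
#' @param duration trace duration (ms); deflection onset at `onset` ms.
#' @param onset deflection onset (ms).
#' @param fs sampling rate (Hz).
#' @param seed RNG seed.
#' @return an object of class `laminar_sim_params`.
#' @export
laminar_sim_params <- function(n_channels = 32L, channel_spacing = 25,
                               sink_channel = 16L, sink_latency = 6,
                               sink_width = 1.5, sink_tau = 2,
                               noise_sd = 0, duration = 100, onset = 20,
                               fs = 10000, seed = 1L) {
  p <- list(n_channels = .check_count(n_channels, "n_channels", min = 3L),
            channel_spacing = .check_pos(channel_spacing, "channel_spacing"),
            sink_channel = .check_count(sink_channel, "sink_channel"),
            sink_latency = .check_pos(sink_latency, "sink_latency"),
            sink_width = .check_pos(sink_width, "sink_width"),
            sink_tau = .check_pos(sink_tau, "sink_tau"),
            noise_sd = .check_pos(noise_sd, "noise_sd", strict = FALSE),
            duration = .check_pos(duration, "duration"),
            onset = .check_pos(onset, "onset"),
            fs = .check_pos(fs, "fs"),
            seed = .check_count(seed, "seed", min = 0L))
  if (p$sink_channel < 1L || p$sink_channel > p$n_channels)
    stop("sink_channel outside the probe", call. = FALSE)
  structure(p, class = "laminar_sim_params")
}

#' Generate a laminar LFP with a planted current sink
#'
#' Constructs a target current-source-density (CSD) image with a single
#' negative sink, Gaussian in both channel and time, centred at
#' (`sink_channel`, `onset + sink_latency`), then integrates twice along the
#' channel axis (cumulative double sum times spacing squared) to obtain the
#' LFP, and finally adds Gaussian noise. The discrete double summation is the
#' exact inverse of the central second difference used by [compute_csd()], so
#' the noiseless round trip recovers the planted CSD on interior channels to
#' machine precision.
#'
#' @param params a [laminar_sim_params()] object.
#' @return a `probe_recording` (see [probe_recording()]) with attribute
#'   `truth` (list: `sink_channel`, `sink_latency`, `onset`, `csd`).
#' @export
gen_laminar_lfp <- function(params) {
  stopifnot(inherits(params, "laminar_sim_params"))
  set.seed(params$seed)
  if (params$sink_channel <= 1L || params$sink_channel >= params$n_channels)
    warning("sink planted at an edge channel: CSD is undefined there after ",
            "central differencing", call. = FALSE)
  nch <- params$n_channels
  t_ms <- seq(0, params$duration, by = 1000 / params$fs)
  peak_t <- params$onset + params$sink_latency
  amp <- 100                              # uV / um^2 scale before integration
  csd <- -amp * outer(
    exp(-((seq_len(nch) - params$sink_channel)^2) / (2 * params$sink_width^2)),
    exp(-((t_ms - peak_t)^2) / (2 * params$sink_tau^2)))
  # double cumulative sum such that the central second difference of the
  # result divided by spacing^2 returns csd exactly on interior channels:
  # lfp[i] = h^2 * sum_{j < i} sum_{k <= j} csd[k]
  s1 <- apply(csd, 2, cumsum)
  s2 <- apply(s1, 2, function(col) c(0, cumsum(col)[-length(col)]))
  lfp <- params$channel_spacing^2 * s2
  if (params$noise_sd > 0)
    lfp <- lfp + matrix(stats::rnorm(length(lfp), 0, params$noise_sd), nrow = nch)
  rec <- probe_recording(lfp, fs = params$fs,
                         channel_spacing = params$channel_spacing)
  attr(rec, "truth") <- list(sink_channel = params$sink_channel,
                             sink_latency = params$sink_latency,
                             onset = params$onset, csd = csd)
  rec
}

#' Parameters for the paired EPSP sweep generator
#'
#' @param n_pairs number of simultaneously recorded IP/OP cell pairs.
#' @param amp_ratio true amplitude ratio A_ip / A_op.
#' @param base_amp OP-cell EPSP amplitude (mV); mean peaks are kept < 3 mV to
#'   stay in the low-amplitude monosynaptic regime.
#' @param onset_latency EPSP onset after light onset (ms).
#' @param alpha_tau alpha-function time constant (ms).
#' @param noise_sd per-sample voltage noise (mV).
#' @param sweeps_per_cell sweeps averaged per cell; must lie in \[10, 40\].
#' @param fs sampling rate (Hz).
#' @param seed RNG seed.
#' @return an object of class `epsp_sim_params`.
#' @export
epsp_sim_params <- function(n_pairs = 20L, amp_ratio = 1, base_amp = 1,
                            onset_latency = 3.5, alpha_tau = 4,
                            noise_sd = 0.1, sweeps_per_cell = 20L,
                            fs = 10000, seed = 1L) {
  if (!is.numeric(amp_ratio) || length(amp_ratio) != 1L ||
      !is.finite(amp_ratio) || amp_ratio <= 0)
    stop("amp_ratio must be > 0", call. = FALSE)
  p <- list(n_pairs = .check_count(n_pairs, "n_pairs"),
            amp_ratio = amp_ratio,
            base_amp = .check_pos(base_amp, "base_amp"),
            onset_latency = .check_pos(onset_latency, "onset_latency"),
            alpha_tau = .check_pos(alpha_tau, "alpha_tau"),
            noise_sd = .check_pos(noise_sd, "noise_sd", strict = FALSE),
            sweeps_per_cell = .check_count(sweeps_per_cell, "sweeps_per_cell"),
            fs = .check_pos(fs, "fs"),
            seed = .check_count(seed, "seed", min = 0L))
  if (p$sweeps_per_cell < 10L || p$sweeps_per_cell > 40L)
    stop("sweeps_per_cell must lie in [10, 40]", call. = FALSE)
  if (p$base_amp * max(1, p$amp_ratio) >= 3)
    stop("mean EPSP peak must stay below 3 mV (low-amplitude monosynaptic ",
         "regime); reduce base_amp or amp_ratio", call. = FALSE)
  structure(p, class = "epsp_sim_params")
}

# alpha kernel with unit peak at t0 + tau
.alpha_kernel <- function(t_ms, t0, tau) {
  k <- numeric(length(t_ms))
  idx <- t_ms > t0
  x <- (t_ms[idx] - t0) / tau
  k[idx] <- x * exp(1 - x)
  k
}

#' Generate paired light-evoked EPSP sweeps
#'
#' For each pair the OP cell's true amplitude is `base_amp` and the IP cell's
#' is `base_amp * amp_ratio`; each sweep is a -70 mV baseline plus Gaussian
#' noise plus an alpha-function EPSP starting `onset_latency` ms after light
#' onset. The alpha function `a * x * exp(1 - x)`, `x = (t - t0)/tau`, peaks
#' at exactly `a`, so the planted amplitude is the true peak.
#'
#' @param params an [epsp_sim_params()] object.
#' @return list with `pairs` (list per pair: `pair_id`, `ip`, `op` sweep
#'   matrices time x sweeps, `time_ms`, `light_onset_ms`) and `truth`
#'   (data.frame: `pair_id`, `a_ip`, `a_op`, `true_bias`, `onset_latency`).
#' @export
gen_paired_epsp_sweeps <- function(params) {
  stopifnot(inherits(params, "epsp_sim_params"))
  set.seed(params$seed)
  dt <- 1000 / params$fs
  time_ms <- seq(0, 200, by = dt)
  light_on <- 100
  a_op <- params$base_amp
  a_ip <- params$base_amp * params$amp_ratio
  kern <- .alpha_kernel(time_ms, light_on + params$onset_latency, params$alpha_tau)
  mk <- function(a) {
    n <- params$sweeps_per_cell
    base <- -70 + a * kern
    sw <- matrix(base, nrow = length(time_ms), ncol = n)
    if (params$noise_sd > 0)
      sw <- sw + matrix(stats::rnorm(length(sw), 0, params$noise_sd),
                        nrow = length(time_ms))
    sw
  }
  pairs <- lapply(seq_len(params$n_pairs), function(i)
    list(pair_id = i, ip = mk(a_ip), op = mk(a_op),
         time_ms = time_ms, light_onset_ms = light_on))
  truth <- data.frame(pair_id = seq_len(params$n_pairs),
                      a_ip = a_ip, a_op = a_op,
                      true_bias = a_ip / (a_ip + a_op),
                      onset_latency = params$onset_latency)
  list(pairs = pairs, truth = truth)
}

#' Parameters for the synthetic barrel-field image generator
#'
#' @param n_barrels number of barrels in the tangential row.
#' @param barrel_width,septum_width tangential widths (um; 1 um/px).
#' @param l4_band_depth depth of the L4 band centre below the pia (um).
#' @param l4_band_thickness band thickness (um).
#' @param curvature quadratic bend of the layer (1/um); 0 = straight.
#' @param barrel_intensity,septum_intensity,background fluorescence levels
#'   (arbitrary units, 16-bit range); must satisfy barrel > septum > background.
#' @param noise_sd additive intensity noise SD.
#' @param n_somata somata per lineage (IP and OP).
#' @param width,height image size (px).
#' @param seed RNG seed.
#' @return an object of class `barrel_image_params`.
#' @export
barrel_image_params <- function(n_barrels = 4L, barrel_width = 120,
                                septum_width = 40, l4_band_depth = 250,
                                l4_band_thickness = 100, curvature = 0,
                                barrel_intensity = 9000,
                                septum_intensity = 4000, background = 1500,
                                noise_sd = 0, n_somata = 10L,
                                width = 700L, height = 500L, seed = 1L) {
  p <- list(n_barrels = .check_count(n_barrels, "n_barrels"),
            barrel_width = .check_pos(barrel_width, "barrel_width"),
            septum_width = .check_pos(septum_width, "septum_width"),
            l4_band_depth = .check_pos(l4_band_depth, "l4_band_depth"),
            l4_band_thickness = .check_pos(l4_band_thickness, "l4_band_thickness"),
            curvature = curvature,
            barrel_intensity = .check_pos(barrel_intensity, "barrel_intensity"),
            septum_intensity = .check_pos(septum_intensity, "septum_intensity"),
            background = .check_pos(background, "background"),
            noise_sd = .check_pos(noise_sd, "noise_sd", strict = FALSE),
            n_somata = .check_count(n_somata, "n_somata", min = 0L),
            width = .check_count(width, "width"),
            height = .check_count(height, "height"),
            seed = .check_count(seed, "seed", min = 0L))
  if (!(p$barrel_intensity > p$septum_intensity &&
        p$septum_intensity > p$background))
    stop("require barrel_intensity > septum_intensity > background",
         call. = FALSE)
  structure(p, class = "barrel_image_params")
}

#' Generate a synthetic barrel-field image with known geometry
#'
#' Renders a (possibly curved) L4 band of elevated fluorescence containing
#' `n_barrels` evenly spaced high-intensity barrels separated by septa, on a
#' dim background, at 1 um/px. The band centre follows
#' `y_c(x) = l4_band_depth + curvature/2 * (x - width/2)^2`. The reference
#' polyline runs along the L4/L5 boundary (the deep edge of the band). Somata
#' are placed at known tangential positions with their true barrel index
#' computed under the linear centre-to-septum convention, and simple straight
#' dendrites are emitted as SWC node tables with known in/out-of-barrel
#' lengths.
#'
#' @param params a [barrel_image_params()] object.
#' @return list with `image` (height x width intensity matrix, row 1 = pia),
#'   `truth`: `barrels` (data.frame `s_start`, `s_end`, `s_center`),
#'   `reference_polyline` (data.frame `x`, `y` along the L4/L5 boundary),
#'   `l4_band` (normal-offset interval, negative = towards pia), `somata`
#'   (data.frame `x`, `y`, `s`, `lineage`, `true_index`), and `morphologies`
#'   (list of SWC data.frames with attribute `truth` giving planted per-region
#'   lengths).
#' @export
gen_barrel_image <- function(params) {
  stopifnot(inherits(params, "barrel_image_params"))
  set.seed(params$seed)
  w <- params$width; h <- params$height

  # reference polyline along the L4/L5 boundary (deep edge of the band),
  # quadratic bend of the layer; barrels and somata live in its arc-length
  # coordinate s
  px <- seq(0, w, by = 5)
  ref <- data.frame(x = px,
                    y = params$l4_band_depth +
                      params$curvature / 2 * (px - w / 2)^2 +
                      params$l4_band_thickness / 2)
  seg_dx <- diff(ref$x); seg_dy <- diff(ref$y)
  seg_len <- sqrt(seg_dx^2 + seg_dy^2)
  cum <- c(0, cumsum(seg_len))
  s_total <- cum[length(cum)]

  pitch <- params$barrel_width + params$septum_width
  row_width <- params$n_barrels * params$barrel_width +
    (params$n_barrels - 1) * params$septum_width
  s0 <- (s_total - row_width) / 2
  if (s0 < 0) stop("barrel row exceeds image bounds", call. = FALSE)
  starts <- s0 + (seq_len(params$n_barrels) - 1L) * pitch
  barrels <- data.frame(s_start = starts,
                        s_end = starts + params$barrel_width)
  barrels$s_center <- (barrels$s_start + barrels$s_end) / 2

  # map (s, d) to image coordinates: foot on the polyline plus d along the
  # local normal; d < 0 is the pia side, the L4 band occupies [-thickness, 0)
  sd_to_xy <- function(s, d) {
    j <- pmin(pmax(findInterval(s, cum, rightmost.closed = TRUE), 1L),
              length(seg_len))
    t <- (s - cum[j]) / seg_len[j]
    nx <- -seg_dy[j] / seg_len[j]; ny <- seg_dx[j] / seg_len[j]
    list(x = ref$x[j] + t * seg_dx[j] + d * nx,
         y = ref$y[j] + t * seg_dy[j] + d * ny)
  }

  # stamp the band into the image at sub-pixel resolution so that barrel
  # territories follow the layer normals (as real barrels do)
  step <- 0.5
  ss <- seq(0, s_total, by = step)
  dd <- seq(-params$l4_band_thickness, 0 - step / 2, by = step)
  grid <- expand.grid(s = ss, d = dd)
  xy <- sd_to_xy(grid$s, grid$d)
  inside <- xy$x >= 0 & xy$x < w & xy$y >= 0 & xy$y < h
  in_row <- grid$s >= barrels$s_start[1] & grid$s <= barrels$s_end[params$n_barrels]
  if (any(in_row & !inside))
    stop("L4 band exceeds image bounds", call. = FALSE)
  in_barrel <- vapply(grid$s, function(s)
    any(s >= barrels$s_start & s < barrels$s_end), logical(1))
  col <- floor(xy$x[inside]) + 1L
  row <- floor(xy$y[inside]) + 1L
  img <- matrix(params$background, nrow = h, ncol = w)
  img[cbind(row, col)] <- ifelse(in_barrel[inside], params$barrel_intensity,
                                 params$septum_intensity)
  if (params$noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, params$noise_sd), nrow = h)
  img <- pmin(pmax(img, 0), 65535)

  # somata at known arc-length positions mid-band; truth index by the linear
  # convention
  n_so <- 2L * params$n_somata
  s_pos <- stats::runif(n_so, barrels$s_start[1], barrels$s_end[params$n_barrels])
  true_idx <- vapply(s_pos, function(s)
    .linear_barrel_index(s, barrels), numeric(1))
  so_xy <- sd_to_xy(s_pos, rep(-params$l4_band_thickness / 2, n_so))
  somata <- data.frame(x = so_xy$x, y = so_xy$y,
                       s = s_pos,
                       lineage = rep(c("IP", "OP"), each = params$n_somata),
                       true_index = true_idx, stringsAsFactors = FALSE)

  # straight horizontal dendrites in the straightened frame: a known split of
  # length inside vs outside the home barrel
  morphs <- lapply(seq_len(min(3L, params$n_barrels)), function(b) {
    cx <- barrels$s_center[b]
    ext <- params$septum_width / 2           # past the boundary, within septum
    sw <- data.frame(
      id = 1:3, type = c(1L, 3L, 3L),
      x = c(cx, cx - params$barrel_width / 2, cx + params$barrel_width / 2 + ext),
      y = -params$l4_band_thickness / 2,   # mid-band in the straightened frame
      z = 0, radius = c(5, 1, 1), parent = c(-1L, 1L, 1L))
    attr(sw, "truth") <- list(
      barrel = b,
      len_inside = params$barrel_width,      # both arms inside up to edges
      len_outside = ext)
    sw
  })

  list(image = img,
       truth = list(barrels = barrels, reference_polyline = ref,
                    l4_band = c(-params$l4_band_thickness, 0),
                    somata = somata, morphologies = morphs))
}

# linear barrel index: 1 at barrel centre, 0 at septal midpoint, linear ramp
.linear_barrel_index <- function(s, barrels) {
  centers <- barrels$s_center
  bounds <- sort(c(barrels$s_start, barrels$s_end))
  gaps_mid <- (utils::head(barrels$s_end, -1) + utils::tail(barrels$s_start, -1)) / 2
  half_gap <- if (length(gaps_mid)) (barrels$s_start[2] - barrels$s_end[1]) / 2
              else mean(barrels$s_end - barrels$s_start) / 2
  mids <- c(barrels$s_start[1] - half_gap, gaps_mid,
            barrels$s_end[nrow(barrels)] + half_gap)
  c_near <- centers[which.min(abs(s - centers))]
  m_near <- mids[which.min(abs(s - mids))]
  if (abs(c_near - m_near) == 0) return(NA_real_)
  min(max(abs(s - m_near) / abs(c_near - m_near), 0), 1)
}

#' Parameters for the sensory-LTP (RWS) session generator
#'
#' @param pre_rate baseline evoked rate (Hz) above spontaneous during the
#'   response window.
#' @param g potentiation factor; the post-induction evoked rate is
#'   `g * pre_rate`. `g = 1` encodes no plasticity.
#' @param n_trials_pre,n_trials_post trials per epoch (default 100 each).
#' @param window multi-whisker response window (ms; default 250).
#' @param spont_rate spontaneous rate (Hz).
#' @param seed RNG seed.
#' @return an object of class `sltp_sim_params`.
#' @export
sltp_sim_params <- function(pre_rate = 40, g = 1, n_trials_pre = 100L,
                            n_trials_post = 100L, window = 250,
                            spont_rate = 5, seed = 1L) {
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g < 0)
    stop("g must be >= 0", call. = FALSE)
  p <- list(pre_rate = .check_pos(pre_rate, "pre_rate", strict = FALSE),
            g = g,
            n_trials_pre = .check_count(n_trials_pre, "n_trials_pre"),
            n_trials_post = .check_count(n_trials_post, "n_trials_post"),
            window = .check_pos(window, "window"),
            spont_rate = .check_pos(spont_rate, "spont_rate", strict = FALSE),
            seed = .check_count(seed, "seed", min = 0L))
  structure(p, class = "sltp_sim_params")
}

#' Generate pre/post spike counts for a sensory-LTP session
#'
#' Pre-induction trial counts are Poisson with mean
#' `(pre_rate + spont_rate) * window`; post-induction counts replace
#' `pre_rate` with `g * pre_rate`. The spontaneous component is what
#' [sltp_delta()] subtracts.
#'
#' @param params an [sltp_sim_params()] object.
#' @return list with `pre_counts`, `post_counts` (integer vectors),
#'   `window_s`, `spont_rate`, and `truth` (list with `g` and the expected
#'   delta in percent).
#' @export
gen_sltp_session <- function(params) {
  stopifnot(inherits(params, "sltp_sim_params"))
  set.seed(params$seed)
  w <- params$window / 1000
  pre <- stats::rpois(params$n_trials_pre,
                      (params$pre_rate + params$spont_rate) * w)
  post <- stats::rpois(params$n_trials_post,
                       (params$g * params$pre_rate + params$spont_rate) * w)
  list(pre_counts = pre, post_counts = post, window_s = w,
       spont_rate = params$spont_rate,
       truth = list(g = params$g, expected_delta = 100 * params$g))
}
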