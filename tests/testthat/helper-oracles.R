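# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (explicit loops over spikes / dense sampling /
# direct rank formulas) so they stay independent of the package's vectorised
# implementations.

# brute-force cumulative spontaneous-subtracted count for one whisker:
# explicit loop over every spike and every trial window
oracle_cum_count <- function(spike_times, onsets, window_s, baseline_s) {
  total_raw <- 0
  total_spont <- 0
  for (on in onsets) {
    raw <- 0
    base <- 0
    for (sp in spike_times) {
      if (sp > on && sp <= on + window_s) raw <- raw + 1
      if (sp >= on - baseline_s && sp < on) base <- base + 1
    }
    total_raw <- total_raw + raw
    total_spont <- total_spont + (base / baseline_s) * window_s
  }
  list(raw = total_raw, corrected = total_raw - total_spont)
}

oracle_si_single <- function(spike_times, log, window_s = 0.05,
                             baseline_s = 0.5) {
  pw <- oracle_cum_count(spike_times, log$onset[log$kind == "PW"],
                         window_s, baseline_s)
  aw <- oracle_cum_count(spike_times, log$onset[log$kind == "AW"],
                         window_s, baseline_s)
  r_pw <- max(0, pw$corrected); r_aw <- max(0, aw$corrected)
  if (r_pw + r_aw <= 0) return(list(si = NA_real_, raw_pw = pw$raw,
                                    raw_aw = aw$raw))
  list(si = r_pw / (r_pw + r_aw), raw_pw = pw$raw, raw_aw = aw$raw)
}

# brute-force Kruskal-Wallis H with tie correction, direct from the rank
# definition
oracle_kw_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 0
  for (g in seq_along(groups)) {
    rg <- r[idx == g]
    h <- h + length(rg) * (mean(rg) - (n + 1) / 2)^2
  }
  h <- 12 / (n * (n + 1)) * h
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# dense point-sampling oracle for dendritic length inside a rectangle
oracle_len_in_rect <- function(x1, y1, x2, y2, sx, dx, n = 200000L) {
  t <- (seq_len(n) - 0.5) / n
  qx <- x1 + t * (x2 - x1)
  qy <- y1 + t * (y2 - y1)
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  len * mean(qx >= sx[1] & qx <= sx[2] & qy >= dx[1] & qy <= dx[2])
}

# simple amplitude spectrum helper for filter checks
power_at <- function(x, fs, freq) {
  n <- length(x)
  sp <- abs(stats::fft(x))[1:(n %/% 2)]
  f <- (0:(n %/% 2 - 1)) * fs / n
  sp[which.min(abs(f - freq))]
}

# a minimal single-train stimulus log: n trials per whisker, 4-deflection
# 10 Hz trains (100 ms inter-deflection interval)
make_train_log <- function(n_trials, iti = 2) {
  rows <- list()
  tr <- 0L
  t0 <- 1
  for (i in seq_len(n_trials)) {
    for (kind in c("PW", "AW")) {
      tr <- tr + 1L
      on <- t0 + (0:3) * 0.1
      rows[[length(rows) + 1L]] <- data.frame(onset = on, kind = kind,
                                              train_index = tr)
      t0 <- t0 + iti
    }
  }
  do.call(rbind, rows)
}
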