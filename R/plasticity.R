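# Sensory-evoked LTP (sLTP) quantification around the rhythmic whisker
# stimulation (RWS) induction.

#' Build the RWS stimulus schedule
#'
#' 100 pre-induction multi-whisker deflections at 0.1 Hz, a 1 min induction
#' of 8 Hz deflections (one 100 Hz-waveform deflection every 125 ms, 480
#' events), and 100 post-induction deflections at 0.1 Hz.
#'
#' @param n_pre,n_post baseline / follow-up trials (default 100 each).
#' @param pre_hz,post_hz baseline deflection rate (Hz, default 0.1).
#' @param induction_hz induction rate (Hz, default 8).
#' @param induction_s induction duration (s, default 60).
#' @param gap_s gap between epochs (s, default 10).
#' @return data.frame with `onset` (s), `kind` ("multi" or "RWS"), `epoch`
#'   ("pre", "induction", "post").
#' @export
build_rws_schedule <- function(n_pre = 100L, n_post = 100L, pre_hz = 0.1,
                               post_hz = 0.1, induction_hz = 8,
                               induction_s = 60, gap_s = 10) {
  pre_on <- (seq_len(n_pre) - 1L) / pre_hz
  ind_start <- max(pre_on) + 1 / pre_hz + gap_s
  n_ind <- round(induction_hz * induction_s)
  ind_on <- ind_start + (seq_len(n_ind) - 1L) / induction_hz
  post_start <- max(ind_on) + 1 / induction_hz + gap_s
  post_on <- post_start + (seq_len(n_post) - 1L) / post_hz
  data.frame(
    onset = c(pre_on, ind_on, post_on),
    kind = c(rep("multi", n_pre), rep("RWS", n_ind), rep("multi", n_post)),
    epoch = c(rep("pre", n_pre), rep("induction", n_ind),
              rep("post", n_post)),
    stringsAsFactors = FALSE)
}

#' Delta spike rate across the RWS induction
#'
#' Per epoch, the evoked rate is the mean over trials of the
#' spontaneous-subtracted spike count in the 250 ms multi-whisker window,
#' divided by the window. The plasticity statistic is
#' `delta = 100 * post_rate / pre_rate` (percent of baseline; 100 = no
#' change), the ratio convention the no-induction control (~106%) implies.
#'
#' @param pre_counts,post_counts spike counts per trial in the window.
#' @param window_s response window (s, default 0.25).
#' @param spont_rate spontaneous rate (Hz) to subtract, scalar or per-trial.
#' @return list of class `plasticity_result`: `pre_rate`, `post_rate` (Hz),
#'   `delta` (percent, NA with `defined = FALSE` when the baseline rate is
#'   not positive).
#' @export
sltp_delta <- function(pre_counts, post_counts, window_s = 0.25,
                       spont_rate = 0) {
  if (!length(pre_counts) || !length(post_counts))
    stop("need at least 1 trial in each epoch", call. = FALSE)
  rate <- function(counts) mean((counts - spont_rate * window_s) / window_s)
  pre <- rate(pre_counts)
  post <- rate(post_counts)
  if (pre <= 0)
    return(structure(list(pre_rate = pre, post_rate = post, delta = NA_real_,
                          defined = FALSE), class = "plasticity_result"))
  structure(list(pre_rate = pre, post_rate = post,
                 delta = 100 * post / pre, defined = TRUE),
            class = "plasticity_result")
}
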