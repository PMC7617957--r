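# Generators: parameter validation, determinism, and ground-truth contracts.

test_that("parameter constructors validate their invariants", {
  expect_error(ephys_sim_params(p_pw = 1.2), "probability")
  expect_error(ephys_sim_params(spont_rate = -1), "non-negative")
  expect_error(ephys_sim_params(waveform_t2p_fs = 0.6), "unambiguous")
  expect_error(laminar_sim_params(sink_channel = 40), "outside the probe")
  expect_error(laminar_sim_params(noise_sd = -1), "non-negative")
  expect_error(epsp_sim_params(amp_ratio = 0), "amp_ratio")
  expect_error(epsp_sim_params(sweeps_per_cell = 5), "\\[10, 40\\]")
  expect_error(epsp_sim_params(base_amp = 3.5), "below 3 mV")
  expect_error(barrel_image_params(septum_intensity = 10000),
               "barrel_intensity > septum_intensity")
  expect_error(sltp_sim_params(g = -1), "g must be")
  expect_error(sltp_sim_params(n_trials_pre = 0), "integer >= 1")
})

test_that("identical params and seed give identical output for every generator", {
  p1 <- gen_ephys_session(ephys_sim_params(n_units = 5, trials_per_whisker = 20,
                                           seed = 11))
  p2 <- gen_ephys_session(ephys_sim_params(n_units = 5, trials_per_whisker = 20,
                                           seed = 11))
  expect_identical(p1, p2)
  expect_identical(gen_laminar_lfp(laminar_sim_params(noise_sd = 5, seed = 3)),
                   gen_laminar_lfp(laminar_sim_params(noise_sd = 5, seed = 3)))
  expect_identical(gen_paired_epsp_sweeps(epsp_sim_params(n_pairs = 2, seed = 3)),
                   gen_paired_epsp_sweeps(epsp_sim_params(n_pairs = 2, seed = 3)))
  expect_identical(
    gen_barrel_image(barrel_image_params(noise_sd = 100, seed = 5)),
    gen_barrel_image(barrel_image_params(noise_sd = 100, seed = 5)))
  expect_identical(gen_sltp_session(sltp_sim_params(seed = 9)),
                   gen_sltp_session(sltp_sim_params(seed = 9)))
})

test_that("ephys ground-truth SI follows the closed form", {
  t1 <- gen_ephys_session(ephys_sim_params(n_units = 4, trials_per_whisker = 10,
                                           p_pw = 0.5, p_aw = 0.5))$truth
  expect_true(all(t1$true_si == 0.5))
  t2 <- gen_ephys_session(ephys_sim_params(n_units = 4, trials_per_whisker = 10,
                                           p_pw = 0.4, p_aw = 0))$truth
  expect_true(all(t2$true_si == 1))
  t3 <- gen_ephys_session(ephys_sim_params(n_units = 4, trials_per_whisker = 10,
                                           p_pw = 0.6, p_aw = 0.3))$truth
  expect_equal(unique(t3$true_si), 0.6 / 0.9)
})

test_that("realized spontaneous rate is within 3 SE of the target", {
  p <- ephys_sim_params(n_units = 1, trials_per_whisker = 200, p_pw = 0,
                        p_aw = 0, spont_rate = 10, tagged_fraction = 0,
                        untagged_latency_mean = NA, n_light_trials = 0L,
                        seed = 21)
  s <- gen_ephys_session(p)
  t_end <- max(s$log$onset) + 1
  n <- length(s$units[[1]]$spike_times)
  se <- sqrt(10 * t_end)
  expect_lt(abs(n - 10 * t_end), 3 * se)
})

test_that("laminar generator round-trips through compute_csd exactly", {
  p <- laminar_sim_params(sink_channel = 12, sink_latency = 6, noise_sd = 0)
  rec <- gen_laminar_lfp(p)
  tr <- attr(rec, "truth")
  csd <- compute_csd(rec)
  expect_lt(max(abs(csd$values - tr$csd[csd$channels, ])), 1e-9)
  m <- which(csd$values == min(csd$values), arr.ind = TRUE)
  expect_equal(csd$channels[m[1]], 12)
  t_ms <- (m[2] - 1) / p$fs * 1000
  expect_equal(t_ms, p$onset + p$sink_latency, tolerance = 0.2)
})

test_that("a linear-in-depth drift leaves the interior CSD unchanged", {
  p <- laminar_sim_params(noise_sd = 0)
  rec <- gen_laminar_lfp(p)
  drift <- outer(seq_len(p$n_channels), rep(7.3, ncol(rec$samples)))
  rec2 <- probe_recording(rec$samples + 5 + drift, rec$fs, rec$channel_spacing)
  expect_equal(compute_csd(rec2)$values, compute_csd(rec)$values,
               tolerance = 1e-9)
})

test_that("edge sinks warn that the CSD is undefined there", {
  expect_warning(gen_laminar_lfp(laminar_sim_params(sink_channel = 1)),
                 "edge channel")
})

test_that("noiseless EPSP pairs recover the planted bias exactly", {
  for (r in c(1, 2)) {
    sws <- gen_paired_epsp_sweeps(epsp_sim_params(n_pairs = 2, amp_ratio = r,
                                                  noise_sd = 0))
    sc <- score_pairs(sws)
    expect_equal(sc$bias, rep(r / (r + 1), 2), tolerance = 1e-6)
  }
})

test_that("barrel image truth matches its stated geometry", {
  b <- gen_barrel_image(barrel_image_params(n_barrels = 3, curvature = 0,
                                            noise_sd = 0, seed = 2))
  tr <- b$truth
  expect_equal(nrow(tr$barrels), 3)
  expect_equal(unique(round(tr$barrels$s_end - tr$barrels$s_start, 9)), 120)
  # soma at a barrel centre has truth index 1; at a septal midpoint, 0
  expect_equal(soma_position_index(tr$barrels$s_center[2], tr$barrels)$index, 1)
  mid <- (tr$barrels$s_end[1] + tr$barrels$s_start[2]) / 2
  expect_equal(soma_position_index(mid, tr$barrels)$index, 0)
  # morphology truth: planted in/out lengths by construction
  m <- tr$morphologies[[1]]
  mt <- attr(m, "truth")
  expect_equal(mt$len_inside, 120)
  expect_equal(mt$len_outside, 20)
  # band exceeding bounds errors
  expect_error(gen_barrel_image(barrel_image_params(l4_band_depth = 480)),
               "bounds")
})

test_that("sLTP generator honours its contracts", {
  s <- gen_sltp_session(sltp_sim_params(g = 1, pre_rate = 40, seed = 2))
  expect_equal(s$truth$expected_delta, 100)
  expect_length(s$pre_counts, 100)
  expect_length(s$post_counts, 100)
  s3 <- gen_sltp_session(sltp_sim_params(g = 3, spont_rate = 0, seed = 5))
  d <- sltp_delta(s3$pre_counts, s3$post_counts, s3$window_s, 0)
  expect_lt(abs(d$delta - 300), 30)
})
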