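# Spontaneous rate, evoked counts, latency, the selectivity index, and
# PW/AW identification.

test_that("spontaneous rate recovers a homogeneous Poisson rate", {
  set.seed(31)
  dur <- 200
  spikes <- sort(runif(rpois(1, 10 * dur), 0, dur))
  onsets <- seq(1, dur - 1, by = 2)
  sr <- spontaneous_rate(spikes, onsets, 0.5)
  se <- sqrt(10 / (0.5 * length(onsets)))
  expect_lt(abs(sr$mean - 10), 3 * se)
  expect_equal(spontaneous_rate(numeric(0), onsets, 0.5)$mean, 0)
  expect_error(spontaneous_rate(spikes, onsets, 0), "positive length")
})

test_that("evoked_count subtracts the expected spontaneous count", {
  # 3 spikes in the window, 10 Hz spontaneous, 50 ms window: 3 - 0.5 = 2.5
  spikes <- c(1.01, 1.02, 1.04)
  expect_equal(evoked_count(spikes, 1, 0.05, spont_per_trial = 10), 2.5)
  expect_equal(evoked_count(numeric(0), 1, 0.05, 0), 0)
  expect_error(evoked_count(spikes, -5, 0.05, 0), "outside the recording")
})

test_that("response latency is the 1 ms bin of the first spike in 5-20 ms", {
  expect_equal(response_latency(1 + 0.0073, 1)$per_trial, 7)
  expect_true(is.na(response_latency(1 + 0.003, 1)$per_trial))
  expect_equal(response_latency(1 + c(0.0061, 0.0095), 1)$per_trial, 6)
})

test_that("selectivity index honours its closed-form anchors", {
  # symmetric: equal counts for PW and AW, no spontaneous activity
  log <- data.frame(onset = c(1, 2, 3, 4), kind = c("PW", "AW", "PW", "AW"),
                    train_index = NA_integer_)
  spikes <- c(1.01, 2.01, 3.01, 4.01)
  expect_equal(selectivity_index(spikes, log)$si, 0.5)
  # AW silent: SI = 1
  spikes_pw <- c(1.01, 3.01)
  expect_equal(selectivity_index(spikes_pw, log)$si, 1)
  # no response at all: undefined, flagged
  res <- selectivity_index(numeric(0), log)
  expect_false(res$defined)
  expect_true(is.na(res$si))
  expect_error(selectivity_index(spikes, log[log$kind == "PW", ]),
               "no 'AW' trials")
})

test_that("pipeline SI equals the brute-force counting oracle exactly", {
  set.seed(7)
  for (rep in 1:25) {
    p <- ephys_sim_params(n_units = 1, trials_per_whisker = 10,
                          p_pw = runif(1, 0.2, 0.9), p_aw = runif(1, 0, 0.7),
                          spont_rate = runif(1, 0, 8), n_light_trials = 0L,
                          tagged_fraction = 0, untagged_latency_mean = NA,
                          seed = 1000 + rep)
    s <- gen_ephys_session(p)
    u <- s$units[[1]]
    got <- selectivity_index(u$spike_times, s$log)
    want <- oracle_si_single(u$spike_times, s$log)
    if (is.na(want$si)) expect_true(is.na(got$si))
    else expect_equal(got$si, want$si, tolerance = 1e-12)
  }
})

test_that("SI is scale-invariant in the counts", {
  r_pw <- 17; r_aw <- 5
  for (c in c(2, 10, 0.5))
    expect_equal((c * r_pw) / (c * r_pw + c * r_aw), r_pw / (r_pw + r_aw))
  # and via the pipeline: duplicating every trial leaves SI unchanged
  log <- data.frame(onset = c(1, 2), kind = c("PW", "AW"),
                    train_index = NA_integer_)
  log2 <- rbind(log, data.frame(onset = c(11, 12), kind = c("PW", "AW"),
                                train_index = NA_integer_))
  spikes <- c(1.01, 1.02, 2.01, 11.01, 11.02, 12.01)
  expect_equal(selectivity_index(spikes[1:3], log)$si,
               selectivity_index(spikes, log2)$si)
})

test_that("train-mode SI sums four 50 ms windows per train", {
  log <- make_train_log(5)
  # one spike 10 ms after each PW deflection, one per AW train
  pw_on <- log$onset[log$kind == "PW"]
  aw_first <- tapply(log$onset[log$kind == "AW"],
                     log$train_index[log$kind == "AW"], min)
  spikes <- sort(c(pw_on + 0.01, aw_first + 0.01))
  res <- selectivity_index(spikes, log, mode = "train")
  expect_equal(res$r_pw, 20)  # 5 trains x 4 deflections
  expect_equal(res$r_aw, 5)
  expect_equal(res$si, 0.8)
  expect_error(selectivity_index(spikes, log[-1, ], mode = "train"),
               "4-deflection")
})

test_that("expected SI decreases as p_aw rises at fixed p_pw", {
  p_aw_grid <- c(0.1, 0.25, 0.4, 0.55, 0.7)
  truth <- 0.6 / (0.6 + p_aw_grid)
  expect_true(all(diff(truth) < 0))
  est <- vapply(seq_along(p_aw_grid), function(i) {
    p <- ephys_sim_params(n_units = 8, trials_per_whisker = 100, p_pw = 0.6,
                          p_aw = p_aw_grid[i], spont_rate = 1,
                          n_light_trials = 0L, tagged_fraction = 0,
                          untagged_latency_mean = NA, seed = 300 + i)
    mean(score_session(gen_ephys_session(p))$si)
  }, numeric(1))
  expect_true(all(diff(est) < 0))
})

test_that("identify_pw_aw follows rate with a latency consistency check", {
  r <- c(A = 12, B = 4); l <- c(A = 7, B = 11)
  res <- identify_pw_aw(r, l)
  expect_equal(res$pw, "A")
  expect_true(res$consistent)
  # rate tie: shorter latency wins, flagged
  r2 <- c(A = 5, B = 5); l2 <- c(A = 6, B = 10)
  res2 <- identify_pw_aw(r2, l2)
  expect_equal(res2$pw, "A")
  expect_true("rate tie" %in% res2$flags)
  expect_error(identify_pw_aw(c(A = 5, B = 5), c(A = 6, B = 6)), "ambiguous")
})

test_that("planted PW is recovered in seeded replicates", {
  ok <- vapply(1:20, function(i) {
    p <- ephys_sim_params(n_units = 5, trials_per_whisker = 40, p_pw = 0.6,
                          p_aw = 0.25, spont_rate = 2, n_light_trials = 0L,
                          tagged_fraction = 0, untagged_latency_mean = NA,
                          seed = 500 + i)
    s <- gen_ephys_session(p)
    rate <- c(PW = 0, AW = 0); lat <- c(PW = 0, AW = 0)
    for (kind in c("PW", "AW")) {
      on <- s$log$onset[s$log$kind == kind]
      rate[kind] <- mean(vapply(s$units, function(u)
        mean(evoked_count(u$spike_times, on, 0.05, 0)) / 0.05, numeric(1)))
      lat[kind] <- mean(vapply(s$units, function(u)
        response_latency(u$spike_times, on)$mean_ms, numeric(1)), na.rm = TRUE)
    }
    identify_pw_aw(rate, lat)$pw == "PW"
  }, logical(1))
  expect_true(all(ok))
})
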