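test_that("common median reference removes common-mode signal", {
  z <- recording_block(matrix(0, 4, 10), fs = 1000)
  expect_equal(common_median_reference(z)$samples, matrix(0, 4, 10))

  common <- matrix(rep(sin(1:50), each = 4), 4, 50)
  blk <- recording_block(common, fs = 1000)
  expect_equal(common_median_reference(blk)$samples, matrix(0, 4, 50))

  one <- recording_block(matrix(1:16, 16, 1), fs = 1000)
  ref <- common_median_reference(one)
  expect_equal(ref$samples[1, 1], 1 - 8.5)
  expect_equal(ref$samples[16, 1], 16 - 8.5)

  expect_error(common_median_reference(recording_block(matrix(0, 1, 5), 1e3)),
               "single channel")
})

test_that("robust sigma estimation matches its definition", {
  expect_equal(estimate_sigma(rep(0, 100)), 0)
  expect_equal(estimate_sigma(rep(c(-1, 0, 1), 100)), 1 / 0.6745)
  withr::with_seed(1, {
    x <- rnorm(1e6)
    expect_lt(abs(estimate_sigma(x) - 1), 0.01)
  })
})

test_that("threshold detection finds negative peaks and enforces rules", {
  fs <- 24414
  expect_equal(nrow(detect_spikes(rep(0, 100), 1, fs)), 0L)

  ev <- detect_spikes(c(0, 0, -5, 0, 0), 1, fs)
  expect_equal(ev$t_index, 3L)
  expect_equal(ev$peak_amp, -5)

  # a dip to -3.9 sigma stays below the -4 sigma criterion
  expect_equal(nrow(detect_spikes(c(0, -3.9, 0), 1, fs)), 0L)

  # lockout merges events closer than 1 ms
  tr <- rep(0, 200); tr[50] <- -6; tr[55] <- -8; tr[120] <- -7
  ev <- detect_spikes(tr, 1, fs, lockout_ms = 1)
  expect_equal(ev$t_index, c(50L, 120L))

  expect_error(detect_spikes(c(0, -5, 0), 0, fs), "sigma")
})

test_that("over-range rejection is strict beyond 500 uV", {
  ev <- data.frame(t_index = 1:3, peak_amp = c(-520, -499, -500))
  kept <- reject_overrange(ev)
  expect_equal(kept$peak_amp, c(-499, -500))
  expect_equal(nrow(reject_overrange(ev[0, ])), 0L)
})

test_that("coincidence rejection uses distinct channels and >14 rule", {
  fs <- 24414
  ev15 <- data.frame(channel = 1:15, t_index = 1000L,
                     peak_amp = rep(-100, 15))
  expect_equal(nrow(reject_coincident(ev15, fs)), 0L)

  ev14 <- data.frame(channel = 1:14, t_index = 1000L,
                     peak_amp = rep(-100, 14))
  expect_equal(nrow(reject_coincident(ev14, fs)), 14L)

  # 15 events on one channel at distinct times are spikes, not artifacts
  burst <- data.frame(channel = 1L, t_index = seq(1000, 15000, by = 1000),
                      peak_amp = rep(-100, 15))
  expect_equal(nrow(reject_coincident(burst, fs)), 15L)
})

test_that("over-range and coincidence filters commute", {
  fs <- 24414
  withr::with_seed(8, {
    ev <- data.frame(
      channel = sample(1:16, 300, TRUE),
      t_index = sort(sample(1:200000, 300)),
      peak_amp = -runif(300, 50, 700))
  })
  ev <- rbind(ev, data.frame(channel = 1:16, t_index = 50000L,
                             peak_amp = rep(-300, 16)))
  a <- reject_coincident(reject_overrange(ev), fs)
  b <- reject_overrange(reject_coincident(ev, fs))
  expect_equal(a[order(a$channel, a$t_index), ],
               b[order(b$channel, b$t_index), ], ignore_attr = TRUE)
})

test_that("waveform extraction drops edge events and aligns peaks", {
  fs <- 24414
  tr <- rep(0, 1000); tr[500] <- -80
  ev <- data.frame(t_index = c(1L, 500L))
  wf <- extract_waveforms(tr, ev, fs)
  expect_equal(nrow(wf$waveforms), 1L)       # edge event dropped
  expect_equal(wf$t_index, 500L)
  expect_equal(which.min(wf$waveforms[1, ]), wf$peak_sample)
})

test_that("clustering isolates the right number of units", {
  fs <- 24414
  t1 <- spike_template(fs, 200, 1)
  t2 <- spike_template(fs, 80, 3)
  withr::with_seed(21, {
    one <- t(sapply(1:50, function(i) t1 + rnorm(length(t1), sd = 3)))
    u1 <- cluster_units(one, seq_len(50) * 100L, channel = 1L)
    expect_length(u1, 1L)
    expect_lt(abs(u1[[1]]$vpp - (max(t1) - min(t1))), 5)

    two <- rbind(one,
                 t(sapply(1:50, function(i) t2 + rnorm(length(t2), sd = 3))))
    u2 <- cluster_units(two, seq_len(100) * 100L, channel = 1L)
    expect_length(u2, 2L)
    expect_equal(sort(vapply(u2, `[[`, 0L, "n_spikes")), c(50L, 50L))
  })
  u3 <- cluster_units(matrix(rnorm(3 * 59), 3), c(10L, 20L, 30L))
  expect_length(u3, 1L)                       # < 8 snippets forces k = 1
})

test_that("unit validation keeps Vpp >= 40 uV", {
  mk <- function(vpp) structure(list(vpp = vpp), class = "sorted_unit")
  out <- validate_units(list(mk(45), mk(39), mk(40)))
  expect_equal(vapply(out, `[[`, 0, "vpp"), c(45, 40))
  # waveform min -30 / max +15 gives Vpp 45 and survives
  wf <- c(rep(0, 10), -30, rep(0, 5), 15, rep(0, 10))
  expect_equal(max(wf) - min(wf), 45)
})

test_that("noise RMS excises spikes before averaging", {
  fs <- 24414
  expect_equal(noise_rms(rep(0, 100), integer(), fs), 0)
  expect_equal(noise_rms(rep(c(-2, 2), 500), integer(), fs), 2)
  withr::with_seed(5, {
    tr <- rnorm(24414)
    tr[12000] <- -4000
    expect_lt(abs(noise_rms(tr, 12000L, fs) - 1), 0.05)
  })
  expect_error(noise_rms(rep(0, 10), 5L, fs, excision_ms = 1e6), "excised")
})

test_that("spike rate is the inverse median ISI", {
  fs <- 1000
  expect_equal(spike_rate(c(0, 10, 30, 60), fs), 50)   # ISIs 10/20/30 ms
  expect_equal(spike_rate(seq(0, 900, by = 100), fs), 10)
  expect_true(is.na(spike_rate(5L, fs)))
})

test_that("channel metrics divide Vpp by noise", {
  fs <- 24414
  u <- structure(list(channel = 1L, spike_indices = c(1000L, 2000L),
                      mean_waveform = c(0, -100, 50, 0), vpp = 150,
                      n_spikes = 2L, cluster_id = 1L),
                 class = "sorted_unit")
  tr <- rep(c(-25, 25), 2000)
  m <- channel_metrics(list(u), tr, fs, all_spike_indices = integer(),
                       channel = 1L)
  expect_equal(m$snr, 6)
  m0 <- channel_metrics(list(), tr, fs, channel = 1L)
  expect_false(m0$active)
  expect_equal(m0$n_units, 0L)
})

test_that("pipeline output is invariant to a common voltage offset", {
  r <- gen_recording(quiet_recording())
  base <- ephys_pipeline(r$block)
  shifted <- r$block
  shifted$samples <- shifted$samples + 30
  off <- ephys_pipeline(shifted)
  expect_equal(base$units, off$units)
  expect_equal(base$metrics, off$metrics)
})

test_that("detection recovers ground truth and artifacts never survive", {
  r <- gen_recording(recording_config(duration_s = 5, seed = 31))
  out <- ephys_pipeline(r$block, q_rout = NA)
  truth_sp <- r$truth[r$truth$class == "spike", ]
  unit_sp <- do.call(rbind, lapply(out$unit_objects, function(u)
    data.frame(channel = u$channel, t_index = u$spike_indices)))
  tol <- round(0.5e-3 * r$block$fs)
  hit <- vapply(seq_len(nrow(truth_sp)), function(i)
    any(unit_sp$channel == truth_sp$channel[i] &
          abs(unit_sp$t_index - truth_sp$t_index[i]) <= tol), TRUE)
  recall <- mean(hit)
  match_back <- vapply(seq_len(nrow(unit_sp)), function(i)
    any(truth_sp$channel == unit_sp$channel[i] &
          abs(truth_sp$t_index - unit_sp$t_index[i]) <= tol), TRUE)
  precision <- mean(match_back)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)

  art <- r$truth[r$truth$class != "spike", ]
  surv <- vapply(seq_len(nrow(art)), function(i)
    any(out$spikes$channel == art$channel[i] &
          abs(out$spikes$t_index - art$t_index[i]) <= tol), TRUE)
  expect_equal(sum(surv), 0L)
})
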