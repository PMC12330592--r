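test_that("LFP extraction attenuates out-of-band and line components", {
  fs <- 30000
  t <- seq(1 / fs, 2, by = 1 / fs)
  mk <- function(f) recording_session(matrix(sin(2 * pi * f * t), ncol = 1), fs)
  mid <- 500:1500
  l300 <- extract_lfp(mk(300))
  expect_lt(20 * log10(max(abs(l300$signals[mid, 1]))), -20)
  l60 <- extract_lfp(mk(60))
  expect_lt(20 * log10(max(abs(l60$signals[mid, 1]))), -20)
  l10 <- extract_lfp(mk(10))
  expect_equal(max(abs(l10$signals[mid, 1])), 1, tolerance = 0.01)
  expect_equal(l10$sample_rate, 1000)
  expect_error(extract_lfp(recording_session(matrix(rnorm(100)), 1000)),
               "below 2 kHz")
})

test_that("band power follows the sum-of-squares/duration convention", {
  fs <- 1000
  t <- seq(1 / fs, 5, by = 1 / fs)
  expect_equal(band_power(rep(0, 5000), c(4, 8), fs), 0)
  p_in <- band_power(sin(2 * pi * 6 * t), c(4, 8), fs)
  expect_equal(p_in, fs / 2, tolerance = 0.02)
  # duration independence
  p_short <- band_power(sin(2 * pi * 6 * t[1:2000]), c(4, 8), fs)
  expect_equal(p_short, p_in, tolerance = 0.05)
  # out-of-band leakage under 1%
  p_out <- band_power(sin(2 * pi * 25 * t), c(4, 8), fs)
  expect_lt(p_out / p_in, 0.01)
  expect_error(band_power(rep(0, 100), c(4, 8), fs), "3 cycles")
})

test_that("spike detection recovers planted spikes and rejects pure noise", {
  fs <- 30000
  # pure noise at the -6 SD threshold: Gaussian tail gives ~no detections
  set.seed(31)
  noise <- rnorm(20 * fs, 0, 10e-6)
  n_fp <- tryCatch(length(detect_spikes(noise, fs)$times), error = function(e) 0)
  expect_lte(n_fp, 2 * ceiling(20 * fs * pnorm(-6)) + 1)

  g <- generate_spiking(session_config(1, fs, duration = 10, seed = 41),
                        rate = 5, target_snr_db = 20)
  sp <- detect_spikes(g$session)
  planted <- g$truth$spike_times[[1]]
  tp <- count_matches(sp$times, planted)
  expect_gte(tp / length(planted), 0.95)
  expect_gte(tp / length(sp$times), 0.95)
  # no refractory doubles: at most one detection per planted spike
  expect_lte(length(sp$times), length(planted) + 1)
  expect_error(detect_spikes(rep(0, 1000), fs), "degenerate")
})

test_that("K-means sorting separates distinct templates deterministically", {
  fs <- 30000
  tpl_a <- durakit:::default_spike_template(fs)
  tpl_b <- rev(tpl_a); tpl_b <- tpl_b / (max(tpl_b) - min(tpl_b))
  ga <- generate_spiking(session_config(1, fs, duration = 20, seed = 51),
                         rate = 4, target_snr_db = 26)
  gb <- generate_spiking(session_config(1, fs, duration = 20, seed = 52),
                         rate = 4, target_snr_db = 26, template = tpl_b)
  x <- ga$session$signals[, 1] + gb$session$signals[, 1]
  sp <- detect_spikes(x, fs)
  sp <- sort_spikes(sp, k = 2)
  truth <- vapply(sp$times, function(tt) {
    if (min(abs(tt - ga$truth$spike_times[[1]])) < 1e-3) 1L else 2L
  }, integer(1))
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(sp$labels, truth), 0.9)
  # determinism and the degenerate single-cluster case
  sp2 <- sort_spikes(sp, k = 2)
  expect_identical(sp$labels, sp2$labels)
  expect_true(all(sort_spikes(sp, k = 1)$labels == 1L))
  expect_error(sort_spikes(sp, k = nrow(sp$waveforms) + 1), "exceeds")
})

test_that("empirical spike SNR follows the amplitude/SD definition", {
  wf <- matrix(rep(c(rep(0, 5), -80e-6, 20e-6, rep(0, 5)), 10),
               nrow = 10, byrow = TRUE)
  sp <- structure(list(times = 1:10, waveforms = wf, background_sd = 10e-6,
                       sample_rate = 30000), class = "spike_set")
  s <- spike_snr(sp)
  expect_equal(s$ratio, 10)
  expect_equal(s$db, 20)
  # scale invariance: scaling trace scales amplitude and SD together
  sp2 <- sp; sp2$waveforms <- 2 * wf; sp2$background_sd <- 20e-6
  expect_equal(spike_snr(sp2)$db, s$db)
  # generator round trip within 1 dB
  g <- generate_spiking(session_config(1, 30000, duration = 15, seed = 61),
                        rate = 5, target_snr_db = 32)
  snr <- spike_snr(detect_spikes(g$session))
  expect_equal(snr$db, 32, tolerance = 1 / 32)
})

test_that("power-change maps flag planted channels and only those", {
  ev <- trial_schedule(120, period = 1, t0 = 0.5)
  cfg <- session_config(8, 1000, events = ev, seed = 71)
  spec <- evoked_spec(c(2, 5), c(4, 8), power_multiplier = 2,
                      latency = 0.05, duration = 0.4)
  lay <- data.frame(channel = paste0("ch", 1:8),
                    x = rep(1:4, 2), y = rep(1:2, each = 4))
  g <- generate_lfp_session(cfg, evoked = list(spec), layout = lay)
  res <- power_change_map(g$session, task_window = c(0.05, 0.45),
                          baseline_window = c(-0.45, -0.05), band = c(4, 8))
  expect_equal(which(res$significant), c(2, 5))
  expect_false(is.null(attr(res, "map")))
  # self-comparison gives exactly zero change
  res0 <- power_change_map(g$session, task_window = c(0.05, 0.45),
                           baseline_window = c(0.05, 0.45), band = c(4, 8))
  expect_equal(res0$change, rep(0, 8))
  expect_error(power_change_map(g$session, events = c(0.5),
                                task_window = c(0, 0.4),
                                baseline_window = c(-0.4, 0), band = c(4, 8)),
               "2 trials")
})

test_that("multitaper spectrograms z-score against the baseline interval", {
  fs <- 1000
  set.seed(81)
  # stationary noise: no systematic structure
  trials <- matrix(rnorm(1500 * 40), 1500, 40)
  z <- mt_spectrogram_z(trials, fs, window = 0.15, step = 0.02,
                        baseline_interval = c(-0.5, 0), t0 = -0.5)
  expect_lt(abs(mean(z$z)), 0.5)
  # planted post-event gamma gain appears only after the event
  gain <- t(vapply(seq_len(40), function(i) {
    x <- rnorm(1500)
    g <- bandpass_filter(rnorm(1500), fs, c(30, 70)) * 6
    x + c(rep(0, 500), rep(1, 1000)) * g
  }, numeric(1500)))
  z2 <- mt_spectrogram_z(t(gain), fs, window = 0.15, step = 0.02,
                         baseline_interval = c(-0.5, 0), t0 = -0.5)
  gsel <- z2$frequency >= 30 & z2$frequency <= 70
  post <- z2$time > 0.15
  pre <- z2$time < -0.1
  expect_gt(mean(z2$z[gsel, post]), 2)
  expect_lt(abs(mean(z2$z[gsel, pre])), 1)
  expect_error(mt_spectrogram_z(trials, fs, window = 2, step = 0.01,
                                baseline_interval = c(-0.5, 0), t0 = -0.5),
               "longer")
})

test_that("artifact masks cover excursions with the configured guard", {
  set.seed(91)
  x <- rnorm(50000)
  m <- artifact_reject(x, 10)
  expect_length(m, length(x))
  expect_equal(mean(m), 0, tolerance = 1e-6)
  x[25000] <- 50
  m2 <- artifact_reject(x, 10, guard = 5)
  expect_true(m2[25000])
  expect_true(all(m2[24995:25005]))
  expect_error(artifact_reject(rep(1, 100)), "zero-variance")
})

test_that("stimulation-block analysis separates induced from spontaneous", {
  fs <- 1000
  per <- 2            # seconds per period (scaled-down blocks)
  nb <- 12
  mk_session <- function(seed, post_gain) {
    block_len <- 4 * per
    cfg <- session_config(6, fs, duration = nb * block_len + 1, seed = seed)
    g <- generate_lfp_session(cfg, background_sd = 20e-6, line_amplitude = 0)
    sig <- g$session$signals
    if (post_gain != 1) {
      for (b in seq_len(nb)) {
        t0 <- (b - 1) * block_len + 3 * per
        idx <- (floor(t0 * fs) + 1):floor((t0 + per) * fs)
        extra <- vapply(seq_len(ncol(sig)), function(c)
          bandpass_filter(rnorm(length(idx)), fs, c(30, 59)), numeric(length(idx)))
        base_p <- vapply(seq_len(ncol(sig)), function(c)
          sd(bandpass_filter(sig[, c], fs, c(30, 59))), numeric(1))
        sig[idx, ] <- sig[idx, ] +
          sweep(extra, 2, sqrt(post_gain - 1) * base_p / apply(extra, 2, sd), "*")
      }
    }
    recording_session(sig, fs)
  }
  blocks <- data.frame(baseline1 = (0:(nb - 1)) * 4 * per,
                       baseline2 = (0:(nb - 1)) * 4 * per + per,
                       post = (0:(nb - 1)) * 4 * per + 3 * per)
  null_res <- stim_block_analysis(mk_session(5, 1), blocks, c(30, 59),
                                  period_duration = per)
  expect_gt(null_res$network$p_paired, 0.01)
  expect_lt(abs(null_res$network$d_spont_mean), 0.2 * fs)

  stim_res <- stim_block_analysis(mk_session(6, 2), blocks, c(30, 59),
                                  period_duration = per)
  expect_gt(stim_res$network$d_induced_mean, stim_res$network$d_spont_mean)
  expect_lt(stim_res$network$p_paired, 0.01)
  # gain shows up as a positive delta by convention
  expect_gt(stim_res$network$d_induced_mean, 0)
  expect_error(stim_block_analysis(mk_session(5, 1),
                                   blocks[, c("baseline1", "post")],
                                   c(30, 59), per), "missing period")
})

test_that("pre/post window tests flag planted sensory responses", {
  fs <- 1000
  ev <- trial_schedule(30, period = 1.5, t0 = 1, type = "stim_onset")
  cfg <- session_config(6, fs, events = ev, seed = 101)
  spec <- evoked_spec(c(1, 4), c(4, 15), power_multiplier = 3,
                      latency = 0, duration = 0.2, event_type = "stim_onset")
  g <- generate_lfp_session(cfg, evoked = list(spec))
  res <- evoked_window_test(g$session, band = c(4, 15))
  expect_true(all(res$significant[c(1, 4)]))
  expect_false(any(res$significant[c(2, 3, 5, 6)]))
  # windows overlapping adjacent trials are rejected
  ev2 <- trial_schedule(10, period = 0.25, t0 = 1, type = "stim_onset")
  g2 <- generate_lfp_session(session_config(2, fs, events = ev2, seed = 5))
  expect_error(evoked_window_test(g2$session), "overlap")
})

test_that("impedance normalization rescales responses channel-wise", {
  z <- c(ch1 = 2, ch2 = 4, ch3 = 1)
  imp <- c(ch1 = 30e3, ch2 = 30e3, ch3 = 30e3)
  out <- impedance_normalized_response(z, imp)
  expect_equal(order(out), order(z))   # common factor keeps the order
  imp2 <- imp; imp2["ch2"] <- 60e3
  out2 <- impedance_normalized_response(z, imp2)
  expect_equal(out2[["ch2"]], out[["ch2"]] / 2)
  imp3 <- imp; imp3["ch3"] <- NA
  expect_warning(out3 <- impedance_normalized_response(z, imp3), "excluded")
  expect_length(out3, 2)
  # planted response: the maximal normalized value sits on the planted channel
  ev <- trial_schedule(40, period = 1, t0 = 0.5)
  g <- generate_lfp_session(session_config(4, 1000, events = ev, seed = 111),
                            evoked = list(evoked_spec(3, c(4, 40), 3,
                                                      latency = 0.05,
                                                      duration = 0.4)))
  res <- power_change_map(g$session, task_window = c(0.05, 0.45),
                          baseline_window = c(-0.45, -0.05), band = c(4, 40))
  norm <- impedance_normalized_response(
    setNames(res$ratio, res$channel),
    setNames(rep(30e3, 4), res$channel))
  expect_equal(which.max(norm), 3L, ignore_attr = TRUE)
})
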