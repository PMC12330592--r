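#' Named frequency bands for surface LFP analysis
#'
#' The conventional set: theta 4-8, alpha 8-15, beta 15-30, gamma 30-70,
#' low gamma 30-59, high gamma 60-150, plus the low-frequency bands used
#' for tactile (4-15 Hz) and optogenetic (4-40 Hz) response mapping. All
#' configurable.
#'
#' @param ... Named `c(low, high)` overrides or additions, Hz.
#' @return Named list of `c(low, high)` bands.
#' @export
band_set <- function(...) {
  bands <- list(theta = c(4, 8), alpha = c(8, 15), beta = c(15, 30),
                gamma = c(30, 70), low_gamma = c(30, 59),
                high_gamma = c(60, 150), tactile_low = c(4, 15),
                opto_low = c(4, 40))
  over <- list(...)
  for (nm in names(over)) bands[[nm]] <- over[[nm]]
  for (b in bands) stopifnot(b[1] > 0, b[2] > b[1])
  bands
}

# odd-reflection padding + forward-backward filtering (zero phase)
pad_filtfilt <- function(filt, x, pad) {
  n <- length(x)
  p <- min(n - 1, pad)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- signal::filtfilt(filt, xp)
  y[(p + 1):(p + n)]
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward over an
#' odd-reflection-padded copy of the signal.
#'
#' @param x Signal vector.
#' @param sample_rate Sampling rate, Hz.
#' @param band `c(low, high)`, Hz, inside (0, Nyquist).
#' @param order Filter order.
#' @return Filtered signal, same length.
#' @export
bandpass_filter <- function(x, sample_rate, band, order = 4) {
  stopifnot(band[1] > 0, band[2] > band[1], band[2] < sample_rate / 2)
  bf <- signal::butter(order, band / (sample_rate / 2), type = "pass")
  pad_filtfilt(bf, x, pad = round(3 * sample_rate / band[1]))
}

highpass_filter <- function(x, sample_rate, cutoff, order = 4) {
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "high")
  pad_filtfilt(bf, x, pad = round(3 * sample_rate / cutoff))
}

#' Extract the LFP band from a broadband session
#'
#' Zero-phase 8th-order Butterworth low-pass at `cutoff` (default 250 Hz),
#' zero-phase notch filters at the power-line frequencies, then decimation
#' to `target_rate` (default 1 kHz). The decimation factor must be an
#' integer.
#'
#' @param session A [recording_session()] sampled at >= 2 kHz.
#' @param cutoff Low-pass cutoff, Hz.
#' @param notch Notch center frequencies, Hz (width `f/Q`, Q = 30).
#' @param target_rate Output sampling rate, Hz.
#' @return A [recording_session()] at `target_rate` (events preserved).
#' @export
extract_lfp <- function(session, cutoff = 250, notch = c(60, 120, 180),
                        target_rate = 1000) {
  stopifnot(inherits(session, "recording_session"))
  fs <- session$sample_rate
  if (fs < 2000) stop("sample rate below 2 kHz")
  fac <- fs / target_rate
  if (abs(fac - round(fac)) > 1e-9)
    stop("sample_rate must be an integer multiple of target_rate")
  fac <- round(fac)
  lp <- signal::butter(8, cutoff / (fs / 2))
  notches <- lapply(notch[notch < fs / 2], function(f) {
    bw <- f / 30 / 2
    signal::butter(2, c(f - bw, f + bw) / (fs / 2), type = "stop")
  })
  keep <- seq(1, nrow(session$signals), by = fac)
  out <- matrix(0, length(keep), ncol(session$signals))
  for (c in seq_len(ncol(session$signals))) {
    x <- pad_filtfilt(lp, session$signals[, c], pad = round(3 * fs / cutoff))
    for (nf in notches) x <- pad_filtfilt(nf, x, pad = fs %/% 10)
    out[, c] <- x[keep]
  }
  recording_session(out, target_rate, events = session$events,
                    channel_ids = session$channel_ids,
                    layout = session$layout, impedances = session$impedances)
}

#' Band power of a signal segment
#'
#' Band-pass filters the segment and returns the sum of squares divided by
#' the segment duration in seconds (so a unit-amplitude in-band sinusoid
#' gives `sample_rate / 2` regardless of duration).
#'
#' @param x Signal segment.
#' @param band `c(low, high)`, Hz.
#' @param sample_rate Sampling rate, Hz.
#' @param filtered Set `TRUE` if `x` is already band-limited (skips the
#'   filter; used when a whole channel was filtered once).
#' @return Power (V^2 s^-1 scale under the sum/duration convention).
#' @export
band_power <- function(x, band, sample_rate, filtered = FALSE) {
  dur <- length(x) / sample_rate
  if (!filtered) {
    if (dur < 3 / band[1])
      stop("segment shorter than 3 cycles of the band's low edge")
    x <- bandpass_filter(x, sample_rate, band)
  }
  sum(x^2) / dur
}

#' Detect threshold-crossing spikes
#'
#' High-pass filters at 250 Hz, estimates the background SD with the
#' robust estimator `median(|x|) / 0.6745` (insensitive to the spikes
#' themselves), and detects negative threshold crossings at
#' `threshold_sd` SDs with a refractory period. Snippets are aligned to
#' the trough.
#'
#' @param session A [recording_session()] (first channel is used) or a
#'   numeric vector.
#' @param sample_rate Required if `session` is a vector.
#' @param threshold_sd Detection threshold in (robust) SDs; negative.
#' @param refractory Minimum spacing between detections, seconds.
#' @param snippet `c(before, after)` seconds around the trough.
#' @param highpass High-pass cutoff applied before detection, Hz.
#' @return A `spike_set`: list with `times`, `waveforms` (spikes x
#'   samples), `background_sd`, `sample_rate`, `threshold`.
#' @export
detect_spikes <- function(session, sample_rate = NULL, threshold_sd = -6,
                          refractory = 1e-3, snippet = c(0.4e-3, 0.8e-3),
                          highpass = 250) {
  if (inherits(session, "recording_session")) {
    x <- session$signals[, 1]
    sample_rate <- session$sample_rate
  } else {
    x <- session
    stopifnot(!is.null(sample_rate))
  }
  x <- highpass_filter(x, sample_rate, highpass)
  sigma <- stats::median(abs(x)) / 0.6745
  if (sigma == 0) stop("degenerate background (zero SD)")
  thr <- threshold_sd * sigma
  below <- which(x < thr)
  times <- numeric(0)
  troughs <- integer(0)
  if (length(below)) {
    gaps <- which(diff(below) > 1)
    starts <- below[c(1, gaps + 1)]
    ends <- below[c(gaps, length(below))]
    refr <- round(refractory * sample_rate)
    last <- -Inf
    for (g in seq_along(starts)) {
      seg <- starts[g]:ends[g]
      m <- seg[which.min(x[seg])]
      if (m - last >= refr) {
        troughs <- c(troughs, m)
        last <- m
      }
    }
  }
  pre <- round(snippet[1] * sample_rate)
  post <- round(snippet[2] * sample_rate)
  ok <- troughs > pre & troughs + post <= length(x)
  troughs <- troughs[ok]
  wf <- if (length(troughs)) {
    t(vapply(troughs, function(m) x[(m - pre):(m + post)],
             numeric(pre + post + 1)))
  } else {
    matrix(numeric(0), 0, pre + post + 1)
  }
  structure(list(times = (troughs - 1) / sample_rate, waveforms = wf,
                 background_sd = sigma, sample_rate = sample_rate,
                 threshold = thr, labels = NULL),
            class = "spike_set")
}

#' K-means spike sorting on waveform principal components
#'
#' Projects the snippets onto their first `n_pc` principal components and
#' clusters with `stats::kmeans` under a fixed seed, so identical inputs
#' give identical labels.
#'
#' @param spikes A `spike_set` with at least `k` waveforms.
#' @param k Number of clusters.
#' @param n_pc Number of principal components used as features.
#' @param seed RNG seed for the K-means restarts.
#' @return The `spike_set` with integer `labels` added.
#' @export
sort_spikes <- function(spikes, k, n_pc = 3, seed = 1) {
  stopifnot(inherits(spikes, "spike_set"))
  n <- nrow(spikes$waveforms)
  if (k > n) stop("k exceeds the number of waveforms")
  if (k == 1) {
    spikes$labels <- rep(1L, n)
    return(spikes)
  }
  pc <- stats::prcomp(spikes$waveforms, center = TRUE, scale. = FALSE)
  feats <- pc$x[, seq_len(min(n_pc, ncol(pc$x))), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(feats, centers = k, nstart = 10, iter.max = 100)
  spikes$labels <- as.integer(km$cluster)
  spikes
}

#' Empirical spike SNR
#'
#' `SNR = A_spike / sigma_b` with `A_spike` the amplitude of the mean
#' spike waveform (peak-to-trough by default) and `sigma_b` the background
#' SD; also reported as `20 log10(SNR)` dB.
#'
#' @param spikes A non-empty `spike_set` with `background_sd > 0`.
#' @param amplitude `"peak_to_trough"` (default) or `"trough"`.
#' @return List with `ratio` and `db`.
#' @export
spike_snr <- function(spikes, amplitude = c("peak_to_trough", "trough")) {
  stopifnot(inherits(spikes, "spike_set"))
  amplitude <- match.arg(amplitude)
  if (nrow(spikes$waveforms) == 0) stop("empty spike set")
  if (spikes$background_sd <= 0) stop("background SD must be positive")
  mw <- colMeans(spikes$waveforms)
  a <- if (amplitude == "peak_to_trough") max(mw) - min(mw) else abs(min(mw))
  ratio <- a / spikes$background_sd
  list(ratio = ratio, db = 20 * log10(ratio))
}

# inverse-distance-weighted interpolation of channel values onto a grid
interpolate_map <- function(values, positions, n_grid = 64, power = 2) {
  gx <- seq(min(positions$x), max(positions$x), length.out = n_grid)
  gy <- seq(min(positions$y), max(positions$y), length.out = n_grid)
  z <- matrix(NA_real_, n_grid, n_grid)
  for (i in seq_len(n_grid)) {
    dx <- (positions$x - gx[i])^2
    for (j in seq_len(n_grid)) {
      d <- dx + (positions$y - gy[j])^2
      if (any(d < 1e-12)) {
        z[i, j] <- values[which.min(d)]
      } else {
        w <- 1 / d^(power / 2)
        z[i, j] <- sum(w * values) / sum(w)
      }
    }
  }
  list(x = gx, y = gy, z = z)
}

#' Per-channel task-vs-baseline band-power change map
#'
#' For each trial and channel, band power is computed in a task window and
#' a baseline window around the event; per-channel significance of the
#' paired change across trials uses a paired t-test with Bonferroni
#' correction over channels. When the session carries a layout, an
#' interpolated spatial map of the mean change is attached.
#'
#' @param session A [recording_session()].
#' @param events Event times, seconds; defaults to the session events of
#'   type `event_type`.
#' @param task_window,baseline_window `c(start, end)` relative to each
#'   event, seconds (half-open windows).
#' @param band Frequency band `c(low, high)`, Hz.
#' @param alpha Family-wise error rate.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param event_type Event type used when `events` is `NULL`.
#' @return data.frame (one row per channel): `channel`, `baseline_power`,
#'   `task_power`, `change`, `ratio`, `t`, `p`, `p_adj`, `significant`;
#'   the interpolated map (channels with layout positions only) is in
#'   `attr(, "map")`.
#' @export
power_change_map <- function(session, events = NULL, task_window,
                             baseline_window, band, alpha = 0.05,
                             correction = c("bonferroni", "none"),
                             event_type = "trial_start") {
  stopifnot(inherits(session, "recording_session"))
  correction <- match.arg(correction)
  if (is.null(events))
    events <- session$events$time[session$events$type == event_type]
  if (length(events) < 2) stop("need at least 2 trials")
  fs <- session$sample_rate
  nch <- ncol(session$signals)
  n <- nrow(session$signals)
  win_idx <- function(t0, w) {
    a <- floor((t0 + w[1]) * fs) + 1
    b <- floor((t0 + w[2]) * fs)
    if (a < 1 || b > n) return(NULL)
    a:b
  }
  rows <- lapply(seq_len(nch), function(c) {
    xb <- bandpass_filter(session$signals[, c], fs, band)
    tp <- bp <- numeric(0)
    for (t0 in events) {
      ti <- win_idx(t0, task_window)
      bi <- win_idx(t0, baseline_window)
      if (is.null(ti) || is.null(bi)) next
      tp <- c(tp, band_power(xb[ti], band, fs, filtered = TRUE))
      bp <- c(bp, band_power(xb[bi], band, fs, filtered = TRUE))
    }
    if (length(tp) < 2) stop("need at least 2 trials inside the recording")
    d <- tp - bp
    tt <- if (stats::sd(d) == 0) list(statistic = 0, p.value = 1)
          else stats::t.test(tp, bp, paired = TRUE)
    data.frame(channel = session$channel_ids[c],
               baseline_power = mean(bp), task_power = mean(tp),
               change = mean(d), ratio = mean(tp) / mean(bp),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (correction == "bonferroni") pmin(out$p * nch, 1) else out$p
  out$significant <- out$p_adj < alpha
  if (!is.null(session$layout)) {
    pos <- merge(data.frame(channel = out$channel, change = out$change),
                 session$layout, by = "channel")
    if (nrow(pos) >= 3)
      attr(out, "map") <- interpolate_map(pos$change,
                                          pos[, c("x", "y")])
  }
  out
}

# Discrete prolate spheroidal (Slepian) tapers via the symmetric
# tridiagonal formulation; returns an n x k matrix of unit-norm tapers.
dpss_tapers <- function(n, nw = 3, k = 5) {
  w <- nw / n
  t <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off_v <- (t * (n - t) / 2)[-1]
  m <- diag(diag_v)
  for (i in seq_len(n - 1)) {
    m[i, i + 1] <- off_v[i]
    m[i + 1, i] <- off_v[i]
  }
  ev <- eigen(m, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  tap
}

#' Trial-averaged multitaper spectrogram, z-scored to a baseline interval
#'
#' Computes a multitaper spectrogram per trial (sliding window, DPSS
#' tapers, time-bandwidth `nw`, `k` tapers), averages over trials, and
#' z-scores each frequency row against the mean and SD of the spectrogram
#' columns whose centers fall inside the baseline interval.
#'
#' @param trials Matrix of aligned segments, samples x trials (single
#'   channel), or a vector for one trial.
#' @param sample_rate Sampling rate, Hz.
#' @param window Window length, seconds.
#' @param step Step between window starts, seconds.
#' @param baseline_interval `c(start, end)` in segment time, seconds.
#' @param t0 Time of the first sample of the segment, seconds (e.g. -0.5
#'   for segments starting 500 ms before the event).
#' @param nw Time-bandwidth product.
#' @param k Number of tapers.
#' @return List with `time` (window centers), `frequency`, `power`
#'   (freq x time, trial-averaged) and `z` (z-scored power).
#' @export
mt_spectrogram_z <- function(trials, sample_rate, window = 0.15,
                             step = 0.003, baseline_interval, t0 = 0,
                             nw = 3, k = 5) {
  if (is.vector(trials)) trials <- matrix(trials, ncol = 1)
  nsamp <- nrow(trials)
  wlen <- round(window * sample_rate)
  slen <- max(1, round(step * sample_rate))
  if (wlen > nsamp) stop("window longer than the segment")
  starts <- seq(1, nsamp - wlen + 1, by = slen)
  centers <- t0 + (starts + wlen / 2 - 1) / sample_rate
  tap <- dpss_tapers(wlen, nw, k)
  nf <- wlen %/% 2 + 1
  freq <- (seq_len(nf) - 1) * sample_rate / wlen
  pow <- matrix(0, nf, length(starts))
  for (tr in seq_len(ncol(trials))) {
    for (wi in seq_along(starts)) {
      seg <- trials[starts[wi]:(starts[wi] + wlen - 1), tr]
      seg <- seg - mean(seg)
      sp <- 0
      for (j in seq_len(k)) {
        ft <- stats::fft(seg * tap[, j])
        sp <- sp + Mod(ft[seq_len(nf)])^2
      }
      pow[, wi] <- pow[, wi] + sp / k
    }
  }
  pow <- pow / ncol(trials)
  bl <- which(centers >= baseline_interval[1] & centers <= baseline_interval[2])
  if (length(bl) < 2) stop("baseline interval covers fewer than 2 windows")
  mu <- rowMeans(pow[, bl, drop = FALSE])
  sdv <- apply(pow[, bl, drop = FALSE], 1, stats::sd)
  sdv[sdv == 0] <- Inf
  z <- sweep(sweep(pow, 1, mu), 1, sdv, "/")
  list(time = centers, frequency = freq, power = pow, z = z)
}

#' Artifact mask by amplitude excursion
#'
#' Z-normalizes the signal and masks samples whose absolute z-value
#' exceeds the threshold, plus a guard margin around each excursion.
#'
#' @param x Signal vector with positive SD.
#' @param threshold_sd Threshold in SDs (default 10).
#' @param guard Samples masked on each side of an excursion.
#' @return Logical mask, `TRUE` = artifact, same length as `x`.
#' @export
artifact_reject <- function(x, threshold_sd = 10, guard = 0) {
  s <- stats::sd(x)
  if (s == 0) stop("zero-variance input")
  z <- (x - mean(x)) / s
  mask <- abs(z) > threshold_sd
  if (guard > 0 && any(mask)) {
    idx <- which(mask)
    for (d in seq_len(guard)) {
      mask[pmax(idx - d, 1)] <- TRUE
      mask[pmin(idx + d, length(x))] <- TRUE
    }
  }
  mask
}

#' Spontaneous vs stimulation-induced band-power changes across blocks
#'
#' Each block holds two consecutive baseline periods, a stimulation
#' period, and a post-stimulation period. Per channel and block the signal
#' is band-passed, artifact-masked, normalized to the mean/SD of the first
#' baseline, and the power of each period is `sum(x^2)/duration`. The
#' spontaneous change is `P(baseline2) - P(baseline1)`; the induced change
#' is `P(post) - P(baseline1)`. Network-level statistics (channel-averaged,
#' across blocks) are one-sample t-tests of each change against zero and a
#' paired t-test of induced vs spontaneous; per-channel paired t-tests are
#' Bonferroni-corrected over channels.
#'
#' @param session A [recording_session()].
#' @param blocks data.frame with `baseline1`, `baseline2`, `post` period
#'   start times, seconds (one row per block).
#' @param band Frequency band `c(low, high)`, Hz.
#' @param period_duration Duration of each period, seconds.
#' @param artifact_threshold_sd Artifact mask threshold, SDs.
#' @param alpha Family-wise error rate for the per-channel tests.
#' @return List with `per_block` (block x channel matrices `d_spont`,
#'   `d_induced`), `network` (means and the three t-test p-values) and
#'   `per_channel` (data.frame with Bonferroni-corrected significance).
#' @export
stim_block_analysis <- function(session, blocks, band,
                                period_duration = 600,
                                artifact_threshold_sd = 10, alpha = 0.05) {
  stopifnot(inherits(session, "recording_session"))
  need <- c("baseline1", "baseline2", "post")
  if (!all(need %in% names(blocks))) stop("missing period in block table")
  fs <- session$sample_rate
  n <- nrow(session$signals)
  nb <- nrow(blocks)
  nch <- ncol(session$signals)
  idx_of <- function(t0) {
    a <- floor(t0 * fs) + 1
    b <- floor((t0 + period_duration) * fs)
    if (a < 1 || b > n) stop("period outside the recording")
    a:b
  }
  d_spont <- d_ind <- matrix(0, nb, nch)
  for (c in seq_len(nch)) {
    xb <- bandpass_filter(session$signals[, c], fs, band)
    for (b in seq_len(nb)) {
      i1 <- idx_of(blocks$baseline1[b])
      i2 <- idx_of(blocks$baseline2[b])
      i3 <- idx_of(blocks$post[b])
      seg <- xb[c(i1, i2, i3)]
      mask <- artifact_reject(seg, artifact_threshold_sd)
      mu <- mean(xb[i1][!mask[seq_along(i1)]])
      sdv <- stats::sd(xb[i1][!mask[seq_along(i1)]])
      pow <- function(ii, off) {
        m <- mask[off + seq_along(ii)]
        v <- (xb[ii][!m] - mu) / sdv
        sum(v^2) / (length(v) / fs)
      }
      p1 <- pow(i1, 0)
      p2 <- pow(i2, length(i1))
      p3 <- pow(i3, length(i1) + length(i2))
      d_spont[b, c] <- p2 - p1
      d_ind[b, c] <- p3 - p1
    }
  }
  net_sp <- rowMeans(d_spont)
  net_in <- rowMeans(d_ind)
  network <- list(
    d_spont_mean = mean(net_sp), d_induced_mean = mean(net_in),
    p_spont = stats::t.test(net_sp)$p.value,
    p_induced = stats::t.test(net_in)$p.value,
    p_paired = stats::t.test(net_in, net_sp, paired = TRUE)$p.value)
  pc <- vapply(seq_len(nch), function(c) {
    d <- d_ind[, c] - d_spont[, c]
    if (stats::sd(d) == 0) 1 else stats::t.test(d)$p.value
  }, numeric(1))
  per_channel <- data.frame(channel = session$channel_ids,
                            d_spont = colMeans(d_spont),
                            d_induced = colMeans(d_ind),
                            p = pc, p_adj = pmin(pc * nch, 1))
  per_channel$significant <- per_channel$p_adj < alpha
  list(per_block = list(d_spont = d_spont, d_induced = d_ind),
       network = network, per_channel = per_channel)
}

#' Pre/post band-power test around stimulus onsets
#'
#' Band power is computed `pre_window` seconds before and `post_window`
#' seconds after each stimulus onset (each normalized by its own
#' duration), and compared per channel with a two-sample t-test.
#'
#' @param session A [recording_session()].
#' @param stim_onsets Stimulus onset times, seconds.
#' @param pre_window Pre-stimulus window length, seconds (default 100 ms).
#' @param post_window Post-stimulus window length, seconds (default 200 ms).
#' @param band Frequency band, Hz (default the 4-15 Hz tactile band).
#' @param alpha Significance level.
#' @param correction `"none"` (per-channel tests, default) or
#'   `"bonferroni"`.
#' @return data.frame per channel: `channel`, `pre_power`, `post_power`,
#'   `t`, `p`, `p_adj`, `significant`.
#' @export
evoked_window_test <- function(session, stim_onsets = NULL,
                               pre_window = 0.1, post_window = 0.2,
                               band = c(4, 15), alpha = 0.05,
                               correction = c("none", "bonferroni")) {
  stopifnot(inherits(session, "recording_session"))
  correction <- match.arg(correction)
  if (is.null(stim_onsets))
    stim_onsets <- session$events$time[session$events$type == "stim_onset"]
  if (length(stim_onsets) < 2) stop("need at least 2 trials")
  if (length(stim_onsets) > 1 &&
      min(diff(sort(stim_onsets))) < pre_window + post_window)
    stop("windows overlap adjacent trials")
  fs <- session$sample_rate
  n <- nrow(session$signals)
  nch <- ncol(session$signals)
  rows <- lapply(seq_len(nch), function(c) {
    xb <- bandpass_filter(session$signals[, c], fs, band)
    pre <- post <- numeric(0)
    for (t0 in stim_onsets) {
      a1 <- floor((t0 - pre_window) * fs) + 1; b1 <- floor(t0 * fs)
      a2 <- b1 + 1; b2 <- floor((t0 + post_window) * fs)
      if (a1 < 1 || b2 > n) stop("windows outside the recording")
      pre <- c(pre, sum(xb[a1:b1]^2) / (pre_window))
      post <- c(post, sum(xb[a2:b2]^2) / (post_window))
    }
    tt <- stats::t.test(post, pre)
    data.frame(channel = session$channel_ids[c],
               pre_power = mean(pre), post_power = mean(post),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (correction == "bonferroni") pmin(out$p * nch, 1) else out$p
  out$significant <- out$p_adj < alpha
  out
}

#' Impedance-normalized response map
#'
#' Divides each channel's averaged z-band response by that channel's
#' impedance magnitude, removing the gain differences between electrodes.
#' Channels without an impedance are excluded with a warning.
#'
#' @param z_power_map Named numeric vector (or 1-column data.frame) of
#'   per-channel averaged z-scored band power.
#' @param impedances Named numeric vector of impedance magnitudes, ohms.
#' @return Named numeric vector of normalized responses.
#' @export
impedance_normalized_response <- function(z_power_map, impedances) {
  v <- if (is.data.frame(z_power_map)) stats::setNames(z_power_map[[2]],
                                                       z_power_map[[1]])
       else z_power_map
  if (is.null(names(v))) names(v) <- paste0("ch", seq_along(v))
  if (is.null(names(impedances)))
    names(impedances) <- paste0("ch", seq_along(impedances))
  z <- impedances[names(v)]
  missing <- is.na(z) | !is.finite(z)
  if (any(missing)) {
    warning(sprintf("%d channels excluded (missing impedance)", sum(missing)))
    v <- v[!missing]; z <- z[!missing]
  }
  v / abs(z)
}
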